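## Rendering of synthetic fibers into tomogram-like density volumes with
## per-MT label masks and ground-truth connector voxel sets.
##
## Density levels before noise are fixed by convention: background 0,
## MT wall 1, MT lumen 0.2, connector 0.8 -- an arbitrary but fixed contrast
## so that MT-anchored thresholding is exercised nontrivially.

RENDER_BACKGROUND <- 0
RENDER_WALL <- 1
RENDER_LUMEN <- 0.2
RENDER_CONNECTOR <- 0.8

## Voxel-center coordinate vectors for a grid of n voxels at `voxel` nm.
voxel_centers <- function(n, voxel) (seq_len(n) - 0.5) * voxel

## Indices (1-based triples) and center coordinates of all voxels in an
## axis-aligned bbox [lo, hi] (nm), clipped to the grid.
bbox_voxels <- function(lo, hi, dims, voxel) {
  i0 <- pmax(1L, floor(lo / voxel) + 1L)
  i1 <- pmin(dims, ceiling(hi / voxel))
  if (any(i1 < i0)) return(NULL)
  g <- expand.grid(x = i0[1]:i1[1], y = i0[2]:i1[2], z = i0[3]:i1[3])
  idx <- as.matrix(g)
  ctr <- sweep(idx - 0.5, 2, rep(voxel, 3), "*")
  list(idx = idx, ctr = ctr)
}

lin_index <- function(idx, dims) {
  idx[, 1] + dims[1] * (idx[, 2] - 1L) + dims[1] * dims[2] * (idx[, 3] - 1L)
}

## Distance from points (m x 3) to the infinite line through a with unit
## direction d.
dist_to_line <- function(p, a, d) {
  rel <- sweep(p, 2, a)
  t <- rel %*% d
  sqrt(pmax(0, rowSums(rel^2) - t^2))
}

## Distance from points (m x 3) to segment [a, b].
dist_to_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(p, 2, a)
  t <- if (len2 == 0) rep(0, nrow(p)) else pmin(1, pmax(0, (rel %*% ab) / len2))
  foot <- outer(as.vector(t), ab)
  sqrt(rowSums((rel - foot)^2))
}

## 26-neighbourhood test: which labels does this voxel set touch?
touched_set <- function(vox_lin, ref_array, dims) {
  comp <- integer(prod(dims))
  comp[vox_lin] <- 1L
  m <- touched_labels_cpp(comp, as.integer(ref_array), as.integer(dims), 26L)
  sort(unique(m[, 2]))
}

#' Render a synthetic fiber into a tomogram-like volume
#'
#' MTs become hollow tubes (outer diameter from the spec, high-density wall,
#' low-density lumen) on a zero background; every ground-truth connector
#' becomes a strut of ~5 nm thickness linking the surfaces of its member
#' MTs (polarity >= 3 struts meet at the members' centroid). Additive
#' Gaussian noise is applied last. Each planted connector's voxel set is
#' validated before acceptance: it must form a single 26-connected
#' component, touch the surfaces of exactly its declared MTs, and stay
#' non-adjacent to every other connector; a connector failing validation is
#' re-anchored at a different slab depth and dropped (from volume and ground
#' truth) if it cannot be placed.
#'
#' @param fiber A `synthetic_fiber` from [simulate_fiber()], or a
#'   `fiber_model` (then `connectors` must be given).
#' @param connectors A `connector_graph`; defaults to the synthetic fiber's
#'   planted graph.
#' @param voxel_nm Voxel size; must be at most `mt_diameter_nm / 5` so tube
#'   walls are resolvable.
#' @param noise_sd Standard deviation of additive Gaussian noise (density
#'   units; wall density is 1).
#' @param margin_nm Padding around the bundle in x-y.
#' @param seed Seed for anchor depths and noise; defaults to the spec seed.
#' @return A `synthetic_volume`: list with `density` ([density_volume]),
#'   `mt_labels` ([mt_label_mask]), `connector_voxels` (list of linear voxel
#'   index vectors, one per kept connector), `connectors` (the
#'   `connector_graph` restricted to kept connectors), `n_dropped`,
#'   `offset_nm` (world translation applied), `spec`.
#' @export
render_fiber_volume <- function(fiber, connectors = NULL, voxel_nm = 2,
                                noise_sd = 0, margin_nm = 30, seed = NULL) {
  if (inherits(fiber, "synthetic_fiber")) {
    sf <- fiber
    fib <- sf$fiber
    connectors <- connectors %||% sf$connectors
    spec <- sf$spec
  } else {
    fib <- fiber
    if (is.null(connectors)) stop_kf("`connectors` required for a bare fiber_model")
    spec <- NULL
  }
  outer_r <- (spec$mt_diameter_nm %||% fib$mt_diameter_nm %||% 25) / 2
  wall <- spec$wall_thickness_nm %||% 5
  strut_r <- spec$strut_radius_nm %||% 2.5
  inner_r <- outer_r - wall
  if (voxel_nm > 2 * outer_r / 5) {
    stop_kf("voxel_nm (%.2f) too coarse: must be <= mt_diameter / 5", voxel_nm)
  }
  seed <- seed %||% (if (!is.null(spec)) spec$rng_seed else 1L)

  m <- fib$mts
  slab <- fib$slab_thickness_nm
  allx <- c(m$bot_x_nm, m$top_x_nm); ally <- c(m$bot_y_nm, m$top_y_nm)
  offset <- c(min(allx) - margin_nm, min(ally) - margin_nm, 0)
  ext <- c(max(allx) - min(allx) + 2 * margin_nm,
           max(ally) - min(ally) + 2 * margin_nm,
           slab)
  dims <- pmax(2L, as.integer(ceiling(ext / voxel_nm)))

  labels <- array(0L, dims)
  density <- array(RENDER_BACKGROUND, dims)

  ## --- MT tubes ---
  bot <- cbind(m$bot_x_nm, m$bot_y_nm, m$bot_z_nm)
  top <- cbind(m$top_x_nm, m$top_y_nm, m$top_z_nm)
  bot <- sweep(bot, 2, offset); top <- sweep(top, 2, offset)
  dirs <- top - bot
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (i in seq_len(nrow(m))) {
    lo <- pmin(bot[i, ], top[i, ]) - outer_r - voxel_nm
    hi <- pmax(bot[i, ], top[i, ]) + outer_r + voxel_nm
    bb <- bbox_voxels(lo, hi, dims, voxel_nm)
    if (is.null(bb)) next
    dd <- dist_to_line(bb$ctr, bot[i, ], dirs[i, ])
    inside <- dd <= outer_r
    if (!any(inside)) next
    lin <- lin_index(bb$idx[inside, , drop = FALSE], dims)
    clash <- labels[lin] != 0L
    if (any(clash)) {
      stop_kf("MTs %d and %d overlap in voxel space", labels[lin][clash][1],
              m$mt_id[i])
    }
    labels[lin] <- m$mt_id[i]
    density[lin] <- ifelse(dd[inside] >= inner_r, RENDER_WALL, RENDER_LUMEN)
  }

  ## --- connectors ---
  axis_point <- function(i, z) bot[i, ] + dirs[i, ] * ((z - bot[i, 3]) / dirs[i, 3])
  conn_occ <- array(0L, dims)          # voxels claimed by placed connectors
  kept_vox <- list()
  kept_edge <- integer(0)
  n_dropped <- 0L
  edges <- connectors$edges

  with_seed(derive_seed(seed, "render"), {
    for (e in seq_len(nrow(edges))) {
      members <- edges$members[[e]]
      rows <- match(members, m$mt_id)
      placed <- FALSE
      for (attempt in seq_len(8L)) {
        zc <- stats::runif(1, 0.25, 0.75) * slab
        pts <- t(vapply(rows, axis_point, numeric(3), z = zc))
        junction <- colMeans(pts)
        segs <- lapply(seq_along(rows), function(j) {
          u <- junction - pts[j, ]
          un <- sqrt(sum(u^2))
          if (un < 1e-9) return(NULL)
          start <- pts[j, ] + u / un * min(outer_r - 1, un)
          list(a = start, b = junction)
        })
        segs <- Filter(Negate(is.null), segs)
        if (length(segs) == 0) break

        lo <- do.call(pmin, lapply(segs, function(s) pmin(s$a, s$b))) - strut_r - voxel_nm
        hi <- do.call(pmax, lapply(segs, function(s) pmax(s$a, s$b))) + strut_r + voxel_nm
        bb <- bbox_voxels(lo, hi, dims, voxel_nm)
        if (is.null(bb)) next
        dmin <- rep(Inf, nrow(bb$ctr))
        for (s in segs) dmin <- pmin(dmin, dist_to_segment(bb$ctr, s$a, s$b))
        cand <- dmin <= strut_r
        if (!any(cand)) next
        lin <- lin_index(bb$idx[cand, , drop = FALSE], dims)
        lin <- lin[labels[lin] == 0L & conn_occ[lin] == 0L]
        if (length(lin) == 0) next

        ## validation: one 26-component, exact MT contact, isolation
        sel <- array(FALSE, dims); sel[lin] <- TRUE
        comp <- label_components(sel, 26)
        if (max(comp) != 1L) next
        if (!identical(touched_set(lin, labels, dims), as.integer(members))) next
        if (length(touched_set(lin, conn_occ, dims)) > 0) next

        conn_occ[lin] <- length(kept_vox) + 1L
        density[lin] <- RENDER_CONNECTOR
        kept_vox[[length(kept_vox) + 1L]] <- lin
        kept_edge <- c(kept_edge, e)
        placed <- TRUE
        break
      }
      if (!placed) n_dropped <- n_dropped + 1L
    }
    if (noise_sd > 0) {
      density <- density + array(stats::rnorm(length(density), 0, noise_sd), dims)
    }
  })

  kept_graph <- connector_graph(
    fiber_id = connectors$fiber_id,
    nodes = connectors$nodes,
    members = edges$members[kept_edge],
    volume_nm3 = vapply(kept_vox, length, numeric(1)) * voxel_nm^3
  )
  structure(list(
    density = density_volume(density, voxel_nm),
    mt_labels = mt_label_mask(labels, voxel_nm),
    connector_voxels = kept_vox,
    connectors = kept_graph,
    n_dropped = n_dropped,
    offset_nm = offset,
    spec = spec
  ), class = "synthetic_volume")
}

#' @export
print.synthetic_volume <- function(x, ...) {
  cat(sprintf("<synthetic_volume> %d x %d x %d voxels at %.2f nm, %d planted connectors (%d dropped)\n",
              x$density$dims[1], x$density$dims[2], x$density$dims[3],
              x$density$voxel_nm, length(x$connector_voxels), x$n_dropped))
  invisible(x)
}
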