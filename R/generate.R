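## Synthetic K-fiber generator: cross-sections, 3D trajectories, connector
## hypergraphs. All coordinates in nm; z runs along the slab depth.

## Unit vector from spherical (polar theta from +z, azimuthal phi in x-y).
sph_to_cart <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

## Orthonormal tangent basis (e1, e2) perpendicular to unit axis `a`.
tangent_basis <- function(a) {
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

## Hexagonal lattice sites with spacing s, ordered by distance from origin
## (ties by angle), enough for `n_sites` sites.
hex_lattice <- function(s, n_sites) {
  rings <- 1L
  while (1 + 3 * rings * (rings + 1) < n_sites) rings <- rings + 1L
  idx <- expand.grid(i = -rings:rings, j = -rings:rings)
  x <- s * (idx$i + idx$j / 2)
  y <- s * idx$j * sqrt(3) / 2
  r <- sqrt(x^2 + y^2)
  keep <- r <= rings * s + 1e-9
  x <- x[keep]; y <- y[keep]; r <- r[keep]
  ang <- atan2(y, x)
  ord <- order(round(r, 9), round(ang, 9))
  cbind(x = x[ord], y = y[ord])
}

#' Generate a K-fiber cross-section
#'
#' Places `n_mts` MT centers by sequential dart-throwing on a jittered
#' hexagonal lattice scaled to the requested nearest-neighbour spacing. This
#' reproduces both the near-regular packing of real K-fibers and, with
#' jitter, the occasional doublet/triplet clusters, without a physics
#' simulation. Centers are recentred on their centroid. No two centers come
#' closer than one MT diameter.
#'
#' @param spec A [fiber_spec()].
#' @return A [tibble::tibble] with columns `mt_id`, `x_nm`, `y_nm`.
#' @export
generate_cross_section <- function(spec) {
  stopifnot(inherits(spec, "fiber_spec"))
  n <- spec$n_mts
  s <- spec$mean_nn_spacing_nm
  sigma <- spec$spacing_jitter_nm
  d_min <- spec$mt_diameter_nm

  ## Positional jitter shrinks the median nearest-neighbour distance below
  ## the lattice constant (the nearest of ~6 jittered neighbours is a
  ## minimum statistic); the shrinkage is ~1.6 sigma for sigma << spacing,
  ## so the lattice is scaled up to compensate and the empirical median
  ## lands on the requested spacing.
  s_lat <- s + 1.6 * sigma

  with_seed(derive_seed(spec$rng_seed, "cross_section"), {
    sites <- hex_lattice(s_lat, max(4L * n, 16L))
    placed <- matrix(numeric(0), ncol = 2)
    site_i <- 0L
    max_sites <- nrow(sites)
    while (nrow(placed) < n) {
      site_i <- site_i + 1L
      if (site_i > max_sites) {
        stop_kf(paste0("could not place %d MTs at spacing %.1f nm with jitter ",
                       "%.1f nm without overlap: packing over-dense"),
                n, s, sigma)
      }
      for (try in seq_len(12L)) {
        cand <- sites[site_i, ] + if (sigma > 0) stats::rnorm(2, 0, sigma) else c(0, 0)
        ok <- nrow(placed) == 0 ||
          min(sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2)) >= d_min
        if (ok) {
          placed <- rbind(placed, cand)
          break
        }
        if (sigma == 0) break  # re-jittering a fixed site is pointless
      }
    }
    placed <- sweep(placed, 2, colMeans(placed))
    tibble::tibble(mt_id = seq_len(n),
                   x_nm = unname(placed[, 1]),
                   y_nm = unname(placed[, 2]))
  })
}

#' Generate 3D MT trajectories through the tomogram slab
#'
#' Each MT runs from the bottom (z = 0) to the top (z = slab thickness) of
#' the slab, passing through its cross-section position at the slab midplane.
#' Directions are the bundle tilt axis, perturbed by the spec's angular
#' wobble, with a planted extra polar deviation for a `deviant_fraction`
#' subset (exactly `ceiling(deviant_fraction * n_mts)` MTs).
#'
#' @param cross_section Output of [generate_cross_section()].
#' @param spec The [fiber_spec()].
#' @return A tibble with per-MT midpoint, bottom/top coordinates, unit
#'   direction components and an `is_deviant` flag.
#' @export
generate_mt_vectors <- function(cross_section, spec) {
  stopifnot(inherits(spec, "fiber_spec"))
  n <- nrow(cross_section)
  axis <- sph_to_cart(spec$fiber_tilt[1], spec$fiber_tilt[2])
  half <- spec$slab_thickness_nm / 2

  with_seed(derive_seed(spec$rng_seed, "mt_vectors"), {
    n_dev <- ceiling(spec$deviant_fraction * n)
    deviant <- rep(FALSE, n)
    if (n_dev > 0) deviant[sample.int(n, n_dev)] <- TRUE

    dirs <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d <- axis
      if (spec$wobble_polar_sd > 0) {
        tb <- tangent_basis(d)
        t_vec <- spec$wobble_polar_sd * (stats::rnorm(1) * tb$e1 + stats::rnorm(1) * tb$e2)
        d <- d + t_vec
        d <- d / sqrt(sum(d^2))
      }
      if (deviant[i]) {
        delta <- stats::runif(1, 0, spec$deviant_polar_max_rad)
        if (delta == 0) delta <- spec$deviant_polar_max_rad  # open lower bound
        psi <- stats::runif(1, 0, 2 * pi)
        tb <- tangent_basis(d)
        d <- cos(delta) * d + sin(delta) * (cos(psi) * tb$e1 + sin(psi) * tb$e2)
      }
      dirs[i, ] <- d
    }
    if (any(dirs[, 3] <= 0.05)) {
      stop_kf("MT direction nearly in-plane (z-component <= 0.05): reduce tilt/deviation")
    }

    mid <- cbind(cross_section$x_nm, cross_section$y_nm, half)
    scale_bot <- -half / dirs[, 3]
    scale_top <- half / dirs[, 3]
    bot <- mid + dirs * scale_bot
    top <- mid + dirs * scale_top
    tibble::tibble(
      mt_id = cross_section$mt_id,
      mid_x_nm = cross_section$x_nm, mid_y_nm = cross_section$y_nm,
      bot_x_nm = bot[, 1], bot_y_nm = bot[, 2], bot_z_nm = bot[, 3],
      top_x_nm = top[, 1], top_y_nm = top[, 2], top_z_nm = top[, 3],
      dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
      is_deviant = deviant
    )
  })
}

#' Assemble a fiber model from generated coordinates
#'
#' @param vectors Output of [generate_mt_vectors()].
#' @param spec The generating [fiber_spec()].
#' @param fiber_id Identifier string.
#' @param condition_label Free-text condition (e.g. "control").
#' @return A `fiber_model` object.
#' @export
fiber_model <- function(vectors, spec, fiber_id = "fiber1",
                        condition_label = "control") {
  structure(list(
    fiber_id = fiber_id,
    mts = vectors[, c("mt_id", "mid_x_nm", "mid_y_nm",
                      "bot_x_nm", "bot_y_nm", "bot_z_nm",
                      "top_x_nm", "top_y_nm", "top_z_nm")],
    slab_thickness_nm = spec$slab_thickness_nm,
    condition_label = condition_label,
    mt_diameter_nm = spec$mt_diameter_nm,
    voxel_nm = NULL
  ), class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat(sprintf("<fiber_model> %s (%s): %d MTs, slab %.1f nm\n",
              x$fiber_id, x$condition_label, nrow(x$mts), x$slab_thickness_nm))
  invisible(x)
}

## All k-subsets of mt ids whose pairwise center distances are <= bound.
proximal_subsets <- function(xy, ids, k, bound) {
  n <- length(ids)
  if (n < k) return(list())
  if (!is.finite(bound)) {
    return(utils::combn(ids, k, simplify = FALSE))
  }
  dm <- dist_matrix(xy)
  adj <- dm <= bound
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::cliques(g, min = k, max = k)
  lapply(cl, function(v) sort(ids[as.integer(v)]))
}

#' Generate a ground-truth connector hypergraph
#'
#' Draws mesh connectors (hyperedges over MTs) with polarity k in {2, 3, 4}
#' sampled from the spec's polarity mix. Member sets are sampled uniformly
#' from the sets of k MTs that are mutually within the proximity bound
#' (default 105 nm center-to-center, the longest bridges seen in 2D EM);
#' each distinct member set is used at most once. The number of hyperedges
#' approximates `connectors_per_mt * n_mts`, truncated when candidate sets
#' run out.
#'
#' @param fiber A `fiber_model`.
#' @param spec The [fiber_spec()].
#' @return A `connector_graph` object.
#' @export
generate_connector_graph <- function(fiber, spec) {
  stopifnot(inherits(fiber, "fiber_model"), inherits(spec, "fiber_spec"))
  ids <- fiber$mts$mt_id
  if (length(ids) < 2) stop_kf("connector generation needs >= 2 MTs")
  xy <- cbind(fiber$mts$mid_x_nm, fiber$mts$mid_y_nm)

  mix <- spec$connector_polarity_mix
  pools <- list("2" = list(), "3" = list(), "4" = list())
  for (k in c(2L, 3L, 4L)) {
    if (mix[[as.character(k)]] > 0 || k == 2L) {
      pools[[as.character(k)]] <- proximal_subsets(xy, ids, k, spec$proximity_bound_nm)
    }
  }
  if (length(pools[["2"]]) == 0) {
    stop_kf("no MT pair within %.0f nm: no connectable geometry",
            spec$proximity_bound_nm)
  }

  m_target <- round(spec$connectors_per_mt * length(ids))

  edges <- with_seed(derive_seed(spec$rng_seed, "connectors"), {
    out <- list()
    for (e in seq_len(m_target)) {
      ks <- sample(names(mix), 3L, prob = pmax(mix, 1e-12))
      picked <- NULL
      for (k in ks) {
        if (length(pools[[k]]) > 0) {
          j <- sample.int(length(pools[[k]]), 1L)
          picked <- pools[[k]][[j]]
          pools[[k]] <- pools[[k]][-j]
          break
        }
      }
      if (is.null(picked)) break  # all candidate sets used up
      out[[length(out) + 1L]] <- picked
    }
    out
  })

  connector_graph(
    fiber_id = fiber$fiber_id,
    nodes = ids,
    members = edges,
    volume_nm3 = rep(NA_real_, length(edges))
  )
}

#' Construct a connector hypergraph
#'
#' @param fiber_id Fiber identifier.
#' @param nodes All MT ids in the fiber (including unconnected MTs).
#' @param members List of integer vectors, each the MT ids joined by one
#'   uninterrupted mesh density (length >= 2).
#' @param volume_nm3 Optional per-connector volumes.
#' @return A `connector_graph`.
#' @export
connector_graph <- function(fiber_id, nodes, members,
                            volume_nm3 = rep(NA_real_, length(members))) {
  if (length(members) != length(volume_nm3)) {
    stop_kf("`members` and `volume_nm3` lengths differ")
  }
  for (m in members) {
    if (length(m) < 2) stop_kf("every connector must join >= 2 MTs")
    if (!all(m %in% nodes)) stop_kf("connector references MT id not in `nodes`")
    if (anyDuplicated(m)) stop_kf("connector lists an MT id twice")
  }
  structure(list(
    fiber_id = fiber_id,
    nodes = as.integer(nodes),
    edges = tibble::tibble(
      connector_id = seq_along(members),
      members = lapply(members, function(m) as.integer(sort(m))),
      polarity = vapply(members, length, integer(1)),
      volume_nm3 = as.numeric(volume_nm3)
    )
  ), class = "connector_graph")
}

#' @export
print.connector_graph <- function(x, ...) {
  tab <- table(factor(x$edges$polarity, levels = 2:4))
  cat(sprintf("<connector_graph> %s: %d MTs, %d connectors (bi %d / tri %d / quad %d)\n",
              x$fiber_id, length(x$nodes), nrow(x$edges),
              tab[["2"]], tab[["3"]], tab[["4"]]))
  invisible(x)
}

#' Simulate a complete synthetic K-fiber
#'
#' Runs cross-section placement, trajectory generation and connector
#' generation for one spec and bundles the results with their ground truth
#' (planted deviant flags and the chain partition implied by the planted
#' connectors).
#'
#' @param spec A [fiber_spec()].
#' @param fiber_id,condition_label Passed to [fiber_model()].
#' @return A `synthetic_fiber`: list with elements `fiber` (`fiber_model`),
#'   `connectors` (`connector_graph`), `chain_partition` (ground-truth
#'   [chains_from_connectors()] result), `is_deviant` (logical per MT) and
#'   `spec`.
#' @export
simulate_fiber <- function(spec, fiber_id = "fiber1", condition_label = "control") {
  cs <- generate_cross_section(spec)
  vec <- generate_mt_vectors(cs, spec)
  fib <- fiber_model(vec, spec, fiber_id = fiber_id, condition_label = condition_label)
  graph <- generate_connector_graph(fib, spec)
  structure(list(
    fiber = fib,
    connectors = graph,
    chain_partition = chains_from_connectors(graph),
    is_deviant = vec$is_deviant,
    spec = spec
  ), class = "synthetic_fiber")
}

#' @export
print.synthetic_fiber <- function(x, ...) {
  print(x$fiber)
  print(x$connectors)
  invisible(x)
}
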