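## Mesh segmentation: MT-anchored thresholding of the density volume,
## connector classification by polarity, and volume-ratio statistics.

## Separable 3D Gaussian smoothing with edge replication (optional
## pre-filter for noisy volumes; off by default).
gaussian_smooth_3d <- function(a, sd_voxels) {
  if (sd_voxels <= 0) return(a)
  rad <- max(1L, ceiling(3 * sd_voxels))
  k <- stats::dnorm(-rad:rad, sd = sd_voxels)
  k <- k / sum(k)
  smooth_axis1 <- function(x) {
    d <- dim(x)
    m <- matrix(x, nrow = d[1])
    pad <- rbind(m[rep(1L, rad), , drop = FALSE], m,
                 m[rep(d[1], rad), , drop = FALSE])
    f <- stats::filter(pad, k, sides = 2)
    array(f[(rad + 1):(rad + d[1]), , drop = FALSE], dim = d)
  }
  a <- smooth_axis1(a)
  a <- aperm(smooth_axis1(aperm(a, c(2, 3, 1))), c(3, 1, 2))
  aperm(smooth_axis1(aperm(a, c(3, 1, 2))), c(2, 3, 1))
}

#' Segment the inter-MT mesh from a density volume
#'
#' Implements MT-anchored thresholding: the threshold is the mean gray value
#' over MT-labeled voxels (scaled by `threshold_factor`), and mesh voxels
#' are those at or above threshold, outside the MT masks, belonging to
#' 26-connected components that touch at least one MT surface. Components
#' attached to no MT are discarded (they are cytoplasmic density, not mesh),
#' as are components smaller than `min_voxels` (noise; default ~one
#' 5 nm strut element).
#'
#' @param volume A [density_volume()].
#' @param mask An [mt_label_mask()] with the same dimensions.
#' @param threshold_factor Multiplier on the mean MT gray value (default 1).
#' @param min_voxels Minimum component size retained.
#' @param connectivity Voxel connectivity for components and surface contact
#'   (26 by default; thin struts break under 6-connectivity).
#' @param smooth_sd_voxels Optional Gaussian pre-smoothing (s.d. in voxels).
#' @return A `mesh_mask`: list with `mask` (3D logical), `voxel_nm`,
#'   `threshold`, `connectivity`.
#' @export
segment_mesh <- function(volume, mask, threshold_factor = 1, min_voxels = 8L,
                         connectivity = 26, smooth_sd_voxels = 0) {
  stopifnot(inherits(volume, "density_volume"), inherits(mask, "mt_label_mask"))
  if (!identical(volume$dims, mask$dims)) {
    stop_kf("density and label volumes have different dimensions")
  }
  labels <- mask$labels
  if (!any(labels > 0)) stop_kf("MT label mask is empty")

  values <- gaussian_smooth_3d(volume$values, smooth_sd_voxels)
  threshold <- mean(values[labels > 0]) * threshold_factor
  empty <- structure(list(mask = array(FALSE, volume$dims),
                          voxel_nm = volume$voxel_nm,
                          threshold = threshold, connectivity = connectivity),
                     class = "mesh_mask")
  if (threshold > max(values)) {
    warning("threshold above volume maximum: empty mesh")
    return(empty)
  }
  if (max(values) == min(values)) {
    warning("volume has constant density: empty mesh")
    return(empty)
  }
  cand <- values >= threshold & labels == 0L
  if (!any(cand)) return(empty)

  comp <- label_components(cand, connectivity)
  pairs <- touched_labels_cpp(as.integer(comp), as.integer(labels),
                              as.integer(volume$dims), as.integer(connectivity))
  attached <- unique(pairs[, 1])
  sizes <- tabulate(comp[comp > 0])
  keep_ids <- intersect(attached, which(sizes >= min_voxels))
  out <- empty
  out$mask <- array(comp %in% keep_ids, volume$dims)
  out
}

#' @export
print.mesh_mask <- function(x, ...) {
  cat(sprintf("<mesh_mask> %d mesh voxels (threshold %.3f, %d-connectivity)\n",
              sum(x$mask), x$threshold, x$connectivity))
  invisible(x)
}

#' Classify mesh components into connectors by polarity
#'
#' Each 26-connected mesh component is one uninterrupted density; its
#' polarity is the number of distinct MTs whose surfaces it touches.
#' Components touching two or more MTs are connectors (bipolar, tripolar,
#' quadrupolar, ...); components touching exactly one MT are reported
#' separately as pendants, and detached components (possible when a raw
#' mask, not the output of [segment_mesh()], is supplied) as detached.
#'
#' @param mesh A `mesh_mask` (or 3D logical array plus `voxel_nm`).
#' @param mask The [mt_label_mask()].
#' @param voxel_nm Required when `mesh` is a bare array.
#' @return List with tibbles `connectors` and `pendants` (columns
#'   `connector_id`, `polarity`, `n_voxels`, `volume_nm3`, `touched_mts`
#'   list-column) plus `component_labels` (3D integer array) and
#'   `detached_volume_nm3`.
#' @export
classify_connectors <- function(mesh, mask, voxel_nm = NULL) {
  if (inherits(mesh, "mesh_mask")) {
    mm <- mesh$mask
    voxel_nm <- mesh$voxel_nm
    connectivity <- mesh$connectivity
  } else {
    mm <- mesh
    if (is.null(voxel_nm)) stop_kf("`voxel_nm` required for a bare mesh array")
    connectivity <- 26
  }
  stopifnot(inherits(mask, "mt_label_mask"))
  comp <- label_components(mm, connectivity)
  n_comp <- max(comp)
  empty <- tibble::tibble(connector_id = integer(0), polarity = integer(0),
                          n_voxels = integer(0), volume_nm3 = numeric(0),
                          touched_mts = list())
  if (n_comp == 0) {
    return(list(connectors = empty, pendants = empty,
                component_labels = comp, detached_volume_nm3 = 0))
  }
  pairs <- touched_labels_cpp(as.integer(comp), as.integer(mask$labels),
                              as.integer(dim(mm)), as.integer(connectivity))
  touched <- split(pairs[, 2], pairs[, 1])
  sizes <- tabulate(comp[comp > 0], nbins = n_comp)

  rows <- tibble::tibble(
    connector_id = seq_len(n_comp),
    polarity = vapply(as.character(seq_len(n_comp)),
                      function(k) length(touched[[k]] %||% integer(0)), integer(1)),
    n_voxels = sizes,
    volume_nm3 = sizes * voxel_nm^3,
    touched_mts = lapply(as.character(seq_len(n_comp)),
                         function(k) sort(touched[[k]] %||% integer(0)))
  )
  list(connectors = rows[rows$polarity >= 2, ],
       pendants = rows[rows$polarity == 1, ],
       component_labels = comp,
       detached_volume_nm3 = sum(rows$volume_nm3[rows$polarity == 0]))
}

## Convex hull area and perimeter of 2D points (for dilated fiber volume).
hull_metrics <- function(xy) {
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  list(area = area, perimeter = per)
}

#' Mesh volume statistics relative to MT and fiber volume
#'
#' Computes the total mesh volume and its ratios to (a) MT walls only, (b)
#' "filled-in" MTs (walls + lumens), and (c) the fiber volume, reported as a
#' percentage. Wall and filled MT volumes are analytic hollow/solid
#' cylinders (outer diameter from `mt_diameter_nm`, wall thickness
#' `wall_nm`) over the slab thickness. The fiber volume -- never defined in
#' the source imaging literature -- is taken as the convex hull of MT
#' centers dilated by `fiber_margin_nm` (one MT radius), times the slab
#' thickness; the choice is recorded in the returned object.
#'
#' @param connectors Output of [classify_connectors()].
#' @param mesh The `mesh_mask`.
#' @param points Cross-section MT centers (`mt_id`, `x_nm`, `y_nm`) used for
#'   the fiber hull; if omitted, per-label voxel centroids of `mask` are
#'   used.
#' @param mask The [mt_label_mask()] (used for centroids and MT count).
#' @param slab_thickness_nm Slab depth in nm.
#' @param mt_diameter_nm,wall_nm MT outer diameter and wall thickness.
#' @param fiber_margin_nm Hull dilation radius for the fiber volume.
#' @return Object of class `segmentation_stats`.
#' @export
mesh_volume_ratios <- function(connectors, mesh, mask, slab_thickness_nm,
                               points = NULL, mt_diameter_nm = 25, wall_nm = 5,
                               fiber_margin_nm = mt_diameter_nm / 2) {
  stopifnot(inherits(mask, "mt_label_mask"))
  voxel_nm <- mesh$voxel_nm
  mesh_vol <- sum(mesh$mask) * voxel_nm^3

  mt_ids <- setdiff(sort(unique(as.vector(mask$labels))), 0L)
  n_mts <- length(mt_ids)
  if (n_mts == 0) stop_kf("zero MT volume: label mask is empty")

  if (is.null(points)) {
    idx <- which(mask$labels > 0, arr.ind = TRUE)
    lab <- mask$labels[mask$labels > 0]
    cx <- tapply((idx[, 1] - 0.5) * voxel_nm, lab, mean)
    cy <- tapply((idx[, 2] - 0.5) * voxel_nm, lab, mean)
    xy <- cbind(cx, cy)
  } else {
    xy <- as_xy(points)
  }

  ro <- mt_diameter_nm / 2
  ri <- ro - wall_nm
  wall_vol <- n_mts * pi * (ro^2 - ri^2) * slab_thickness_nm
  filled_vol <- n_mts * pi * ro^2 * slab_thickness_nm
  fiber_vol <- if (nrow(xy) >= 3) {
    hm <- hull_metrics(xy)
    (hm$area + hm$perimeter * fiber_margin_nm + pi * fiber_margin_nm^2) *
      slab_thickness_nm
  } else {
    NA_real_
  }

  pol <- polarity_proportions_from_table(connectors$connectors)
  structure(list(
    total_mesh_volume_nm3 = mesh_vol,
    mesh_to_mt_wall_ratio = mesh_vol / wall_vol,
    mesh_to_filled_mt_ratio = mesh_vol / filled_vol,
    mesh_percent_of_fiber_volume = if (is.na(fiber_vol)) NA_real_ else
      100 * mesh_vol / fiber_vol,
    fiber_volume_nm3 = fiber_vol,
    mt_wall_volume_nm3 = wall_vol,
    mt_filled_volume_nm3 = filled_vol,
    polarity = pol,
    connector_volumes_nm3 = connectors$connectors$volume_nm3,
    connector_polarities = connectors$connectors$polarity,
    pendant_volume_nm3 = sum(connectors$pendants$volume_nm3),
    n_mts = n_mts,
    fiber_margin_nm = fiber_margin_nm
  ), class = "segmentation_stats")
}

polarity_proportions_from_table <- function(conn_tbl) {
  if (nrow(conn_tbl) == 0) {
    return(tibble::tibble(polarity = integer(0), count = integer(0),
                          proportion = numeric(0)))
  }
  tab <- table(conn_tbl$polarity)
  tibble::tibble(polarity = as.integer(names(tab)),
                 count = as.integer(tab),
                 proportion = as.integer(tab) / nrow(conn_tbl))
}

#' @export
print.segmentation_stats <- function(x, ...) {
  cat(sprintf("<segmentation_stats> mesh %.3g nm^3: %.2f x walls, %.2f x filled MTs, %.1f%% of fiber volume\n",
              x$total_mesh_volume_nm3, x$mesh_to_mt_wall_ratio,
              x$mesh_to_filled_mt_ratio, x$mesh_percent_of_fiber_volume))
  invisible(x)
}
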