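## Cross-sectional MT packing statistics: bundle membership, convex-hull
## area and density, nearest-neighbour spacing, local neighbour counts and
## Voronoi heat maps. Distance thresholds are closed (<=) throughout.

as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    return(unname(points))
  }
  cols <- intersect(c("x_nm", "y_nm"), names(points))
  if (length(cols) == 2) return(cbind(points$x_nm, points$y_nm))
  if (all(c("mid_x_nm", "mid_y_nm") %in% names(points))) {
    return(cbind(points$mid_x_nm, points$mid_y_nm))
  }
  stop_kf("`points` must have x_nm/y_nm (or mid_x_nm/mid_y_nm) columns")
}

#' Partition MTs into proximity bundles and flag K-fibers
#'
#' Bundles are connected components of the graph joining MT centers within
#' `radius_nm` (default 105 nm: an 80 nm edge-to-edge boundary around each
#' 25 nm MT). Components with 10 or more MTs are flagged as K-fibers.
#'
#' @param points Cross-section table (`mt_id`, `x_nm`, `y_nm`) or 2-column
#'   matrix.
#' @param radius_nm Center-to-center bundle radius.
#' @param min_kfiber Minimum component size to qualify as a K-fiber.
#' @return Tibble (`mt_id`, `bundle_id`, `bundle_size`, `is_kfiber`).
#' @export
define_bundles <- function(points, radius_nm = 105, min_kfiber = 10L) {
  xy <- as_xy(points)
  ids <- if (is.data.frame(points) && "mt_id" %in% names(points)) {
    points$mt_id
  } else {
    seq_len(nrow(xy))
  }
  n <- nrow(xy)
  adj <- dist_matrix(xy) <= radius_nm
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  bundle_id <- as.integer(factor(comp, levels = unique(comp)))
  size <- as.integer(table(bundle_id))[bundle_id]
  tibble::tibble(mt_id = ids, bundle_id = bundle_id,
                 bundle_size = size, is_kfiber = size >= min_kfiber)
}

#' Convex-hull area of MT centers
#'
#' Area (nm^2) of the 2D convex hull enclosing the MT center coordinates.
#' Fewer than 3 points, or collinear points, give area 0 with a warning
#' (density is then undefined).
#'
#' @param points Cross-section table or 2-column matrix (nm).
#' @return Area in nm^2.
#' @export
hull_area <- function(points) {
  xy <- as_xy(points)
  if (nrow(xy) < 3) {
    warning("fewer than 3 points: hull area 0, density undefined")
    return(0)
  }
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  ## shoelace formula over hull vertices in order
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (a == 0) warning("collinear points: hull area 0, density undefined")
  a
}

#' Nearest-neighbour spacing statistics
#'
#' Per-MT Euclidean distance to the nearest other MT center, the median
#' thereof, and the median edge-to-edge spacing (center distance minus one
#' MT diameter).
#'
#' @param points Cross-section table or matrix.
#' @param mt_diameter_nm MT outer diameter (25 nm).
#' @return List with `nn_nm` (per-MT), `median_nn_nm`,
#'   `median_edge_to_edge_nm`. A single point yields empty stats.
#' @export
nearest_neighbor_stats <- function(points, mt_diameter_nm = 25) {
  xy <- as_xy(points)
  if (nrow(xy) < 2) {
    return(list(nn_nm = numeric(0), median_nn_nm = NA_real_,
                median_edge_to_edge_nm = NA_real_))
  }
  dm <- dist_matrix(xy)
  diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  med <- stats::median(nn)
  list(nn_nm = unname(nn),
       median_nn_nm = med,
       median_edge_to_edge_nm = med - mt_diameter_nm)
}

#' Count neighbouring MTs within a search radius
#'
#' Number of other MTs whose center lies within `radius_nm`
#' (center-to-center, closed threshold) of each MT; self excluded.
#'
#' @param points Cross-section table or matrix.
#' @param radius_nm Search radius (> 0).
#' @return Tibble (`mt_id`, `count`).
#' @export
neighbor_counts <- function(points, radius_nm) {
  assert_scalar_num(radius_nm, "radius_nm", positive = TRUE)
  xy <- as_xy(points)
  ids <- if (is.data.frame(points) && "mt_id" %in% names(points)) {
    points$mt_id
  } else {
    seq_len(nrow(xy))
  }
  if (nrow(xy) == 1) return(tibble::tibble(mt_id = ids, count = 0L))
  dm <- dist_matrix(xy)
  diag(dm) <- Inf
  tibble::tibble(mt_id = ids, count = as.integer(rowSums(dm <= radius_nm)))
}

#' Voronoi-interpolated heat map of local neighbour counts
#'
#' Nearest-seed (Voronoi) interpolation of each MT's neighbour count over a
#' regular grid covering the bounding box of the point set padded by the
#' search radius: every grid node takes the count of its nearest MT center.
#'
#' @param points Cross-section table or matrix.
#' @param radius_nm Neighbour-count search radius.
#' @param grid_nm Grid spacing in nm.
#' @return List with `x`, `y` (grid node coordinates) and `z` (matrix of
#'   interpolated counts, `length(x)` x `length(y)`).
#' @export
packing_heatmap <- function(points, radius_nm = 105, grid_nm = 5) {
  xy <- as_xy(points)
  counts <- neighbor_counts(points, radius_nm)$count
  xr <- range(xy[, 1]) + c(-radius_nm, radius_nm)
  yr <- range(xy[, 2]) + c(-radius_nm, radius_nm)
  gx <- seq(xr[1], xr[2], by = grid_nm)
  gy <- seq(yr[1], yr[2], by = grid_nm)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  d2 <- outer(grid[, 1], xy[, 1], "-")^2 + outer(grid[, 2], xy[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  z <- matrix(counts[nearest], nrow = length(gx))
  list(x = gx, y = gy, z = z)
}

#' Per-fiber packing summary
#'
#' Combines bundle size, convex-hull area, MT density (converted to
#' MTs/um^2), nearest-neighbour and neighbour-count summaries into one
#' record.
#'
#' @param points Cross-section table (`mt_id`, `x_nm`, `y_nm`).
#' @param mt_diameter_nm MT diameter.
#' @param radius_nm Neighbour-count radius.
#' @return List of class `packing_stats`.
#' @export
packing_stats <- function(points, mt_diameter_nm = 25, radius_nm = 105) {
  xy <- as_xy(points)
  n <- nrow(xy)
  area <- if (n >= 3) hull_area(points) else 0
  nn <- nearest_neighbor_stats(points, mt_diameter_nm)
  cnt <- neighbor_counts(points, radius_nm)
  structure(list(
    n_mts = n,
    hull_area_nm2 = area,
    density_mts_per_um2 = if (area > 0) n / (area * 1e-6) else NA_real_,
    nn_distances_nm = nn$nn_nm,
    median_nn_nm = nn$median_nn_nm,
    median_edge_to_edge_nm = nn$median_edge_to_edge_nm,
    neighbor_counts = cnt,
    neighbor_radius_nm = radius_nm
  ), class = "packing_stats")
}

#' @export
print.packing_stats <- function(x, ...) {
  cat(sprintf("<packing_stats> %d MTs, hull %.0f nm^2 (%.1f MTs/um^2), median nn %.1f nm\n",
              x$n_mts, x$hull_area_nm2, x$density_mts_per_um2, x$median_nn_nm))
  invisible(x)
}
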