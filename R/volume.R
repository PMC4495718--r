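## Voxel-grid containers and 3D connected-component labelling.
##
## Coordinate convention (used everywhere): right-handed, nm units, z along
## the slab depth, voxel origin at the grid corner; a world coordinate maps
## to 0-based voxel index floor(coord / voxel_nm) (half-open voxels) and a
## voxel's center sits at (index + 0.5) * voxel_nm.

#' Construct a density volume
#'
#' @param values 3D numeric array of densities (x, y, z order).
#' @param voxel_nm Isotropic voxel edge length in nm (> 0).
#' @return Object of class `density_volume` with fields `values`,
#'   `voxel_nm`, `dims`.
#' @export
density_volume <- function(values, voxel_nm) {
  assert_scalar_num(voxel_nm, "voxel_nm", positive = TRUE)
  if (length(dim(values)) != 3) stop_kf("`values` must be a 3D array")
  structure(list(values = values, voxel_nm = voxel_nm, dims = dim(values)),
            class = "density_volume")
}

#' Construct an MT label mask
#'
#' @param labels 3D integer array: 0 = background, k = voxel of MT `k`.
#' @param voxel_nm Voxel edge length in nm.
#' @return Object of class `mt_label_mask`.
#' @export
mt_label_mask <- function(labels, voxel_nm) {
  assert_scalar_num(voxel_nm, "voxel_nm", positive = TRUE)
  if (length(dim(labels)) != 3) stop_kf("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_nm = voxel_nm, dims = dim(labels)),
            class = "mt_label_mask")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf("<density_volume> %d x %d x %d voxels at %.2f nm\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_nm))
  invisible(x)
}

#' @export
print.mt_label_mask <- function(x, ...) {
  cat(sprintf("<mt_label_mask> %d x %d x %d voxels, %d labels\n",
              x$dims[1], x$dims[2], x$dims[3],
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Label connected components of a 3D logical mask
#'
#' Flood-fill labelling under 6-, 18- or 26-connectivity (26 is the package
#' default for mesh work: thin ~5 nm struts break apart under
#' 6-connectivity at realistic voxel sizes).
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return 3D integer array of component labels (0 = background), numbered
#'   in first-voxel order.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (length(dim(mask)) != 3) stop_kf("`mask` must be a 3D array")
  lab <- label_components_3d_cpp(as.logical(mask), as.integer(dim(mask)),
                                 as.integer(connectivity))
  array(lab, dim = dim(mask))
}
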