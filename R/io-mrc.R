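## Minimal MRC2014 volume I/O (modes 0 = int8, 1 = int16, 2 = float32),
## little-endian, 1024-byte header, no extended header on write. Voxel size
## is carried in the cella header in Angstrom per the MRC convention and
## exposed in nm throughout the package.

#' Write a 3D volume to an MRC file
#'
#' @param x A [density_volume()], [mt_label_mask()] or 3D numeric array.
#' @param path Output file path.
#' @param voxel_nm Voxel size in nm (taken from `x` when it carries one).
#' @param mode MRC data mode: 0 (int8), 1 (int16) or 2 (float32). Label
#'   masks default to mode 1, densities to mode 2.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, voxel_nm = NULL, mode = NULL) {
  if (inherits(x, "density_volume")) {
    arr <- x$values; voxel_nm <- voxel_nm %||% x$voxel_nm; mode <- mode %||% 2L
  } else if (inherits(x, "mt_label_mask")) {
    arr <- x$labels; voxel_nm <- voxel_nm %||% x$voxel_nm; mode <- mode %||% 1L
  } else {
    arr <- x; mode <- mode %||% 2L
  }
  if (is.null(voxel_nm)) stop_kf("`voxel_nm` required")
  if (length(dim(arr)) != 3) stop_kf("volume must be a 3D array")
  if (!mode %in% c(0L, 1L, 2L)) stop_kf("unsupported MRC mode %d", mode)
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))

  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                               # nx ny nz
  wi(mode)                            # mode
  wi(c(0, 0, 0))                      # nxstart nystart nzstart
  wi(d)                               # mx my mz
  wf(d * voxel_nm * 10)               # cella (Angstrom)
  wf(c(90, 90, 90))                   # cellb
  wi(c(1, 2, 3))                      # mapc mapr maps
  v <- as.vector(arr)
  wf(c(min(v), max(v), mean(v)))      # dmin dmax dmean
  wi(1)                               # ispg (volume)
  wi(0)                               # nsymbt
  wi(rep(0, 25))                      # extra
  wf(c(0, 0, 0))                      # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(v))                    # rms
  wi(0)                               # nlabl
  writeBin(raw(800), con)             # labels

  if (mode == 2L) {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else if (mode == 1L) {
    if (any(v != round(v)) || any(abs(v) > 32767)) {
      stop_kf("mode 1 (int16) cannot represent these values")
    }
    writeBin(as.integer(v), con, size = 2, endian = "little")
  } else {
    if (any(v != round(v)) || any(v < -128 | v > 127)) {
      stop_kf("mode 0 (int8) cannot represent these values")
    }
    writeBin(as.integer(v), con, size = 1, endian = "little")
  }
  invisible(path)
}

#' Read an MRC volume
#'
#' Reads modes 0, 1 and 2. The voxel size is recovered from the cella
#' header; a zero cella (no voxel size recorded) is an error unless
#' `voxel_nm` is supplied explicitly.
#'
#' @param path MRC file path.
#' @param voxel_nm Optional explicit voxel size override (nm).
#' @param as Return a `"density"` ([density_volume]) or `"labels"`
#'   ([mt_label_mask]) object.
#' @return A [density_volume()] or [mt_label_mask()].
#' @export
read_mrc <- function(path, voxel_nm = NULL, as = c("density", "labels")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop_kf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3); mx <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3); ri(1)
  nsymbt <- ri(1)
  ri(25); rf(3)
  map <- readChar(con, 4, useBytes = TRUE)
  if (!identical(map, "MAP ")) stop_kf("not an MRC2014 file (missing MAP id): %s", path)
  readBin(con, "raw", 4); rf(1); ri(1)
  readBin(con, "raw", 800)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)

  if (any(d <= 0)) stop_kf("invalid MRC dimensions")
  vx <- cella / ifelse(mx > 0, mx, d) / 10   # Angstrom -> nm
  if (is.null(voxel_nm)) {
    if (any(vx <= 0) || any(is.na(vx))) {
      stop_kf("MRC file has no voxel size in header: pass `voxel_nm` explicitly")
    }
    if (max(vx) - min(vx) > 1e-6 * max(vx)) {
      stop_kf("anisotropic voxels not supported (%.3f/%.3f/%.3f nm)",
              vx[1], vx[2], vx[3])
    }
    voxel_nm <- vx[1]
  }

  n <- prod(d)
  v <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1, endian = "little"),
    "1" = readBin(con, "integer", n, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop_kf("unsupported MRC mode %d", mode)
  )
  if (length(v) != n) stop_kf("truncated MRC data in %s", path)
  arr <- array(v, dim = d)
  if (as == "labels") mt_label_mask(arr, voxel_nm) else density_volume(arr, voxel_nm)
}

#' Read a density volume with an optional companion label volume
#'
#' @param path MRC density file.
#' @param labels_path Optional MRC label file; must match the density
#'   dimensions exactly.
#' @param voxel_nm Optional explicit voxel size (nm) when headers carry none.
#' @return List with `density` and (possibly `NULL`) `labels`.
#' @export
read_volume <- function(path, labels_path = NULL, voxel_nm = NULL) {
  density <- read_mrc(path, voxel_nm = voxel_nm, as = "density")
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- read_mrc(labels_path, voxel_nm = voxel_nm, as = "labels")
    if (!identical(labels$dims, density$dims)) {
      stop_kf("label volume dimensions (%s) do not match density (%s)",
              paste(labels$dims, collapse = "x"),
              paste(density$dims, collapse = "x"))
    }
  }
  list(density = density, labels = labels)
}
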