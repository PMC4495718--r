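#' Read a fiber-spec configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration whose keys mirror the
#' arguments of [fiber_spec()] and validates it through the constructor.
#' `rng_seed` is mandatory in the file: configurations without an explicit
#' seed are not reproducible and are rejected.
#'
#' @param path Configuration file path.
#' @return A validated `fiber_spec`.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("n_mts: 12", "mean_nn_spacing_nm: 56.1", "rng_seed: 3"), cfg)
#' read_fiber_spec(cfg)
#' @export
read_fiber_spec <- function(path) {
  if (!file.exists(path)) stop_kf("no such file: %s", path)
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(fields$rng_seed)) {
    stop_kf("config %s must set `rng_seed` explicitly", path)
  }
  unknown <- setdiff(names(fields), names(formals(fiber_spec)))
  if (length(unknown) > 0) {
    stop_kf("config %s has unknown field(s): %s", path,
            paste(unknown, collapse = ", "))
  }
  if (!is.null(fields$connector_polarity_mix)) {
    fields$connector_polarity_mix <- unlist(fields$connector_polarity_mix)
  }
  if (!is.null(fields$fiber_tilt)) {
    fields$fiber_tilt <- as.numeric(unlist(fields$fiber_tilt))
  }
  do.call(fiber_spec, fields)
}
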