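#' Specification of a synthetic K-fiber
#'
#' A `fiber_spec` collects every parameter of the synthetic K-fiber generator:
#' bundle size and packing, slab geometry, whole-bundle tilt, the trajectory
#' noise model, and the connector (mesh) model. All lengths are in nm, all
#' angles in radians.
#'
#' The trajectory model has two parts. Every microtubule (MT) direction is the
#' bundle axis perturbed by an isotropic angular wobble (`wobble_polar_sd`,
#' the per-component s.d. of a tangent-plane Gaussian, so polar deviations are
#' approximately Rayleigh distributed); a `deviant_fraction` subset
#' additionally receives a planted polar deviation drawn uniformly from
#' `(0, deviant_polar_max_rad]` at a uniform azimuth. With
#' `deviant_fraction = 0` and `wobble_polar_sd = 0` the fiber is perfectly
#' parallel.
#'
#' @param n_mts Number of MTs in the bundle (>= 1).
#' @param mt_diameter_nm MT outer diameter; 25 nm for mammalian MTs.
#' @param mean_nn_spacing_nm Target center-to-center nearest-neighbour
#'   spacing of the underlying packing lattice.
#' @param spacing_jitter_nm Per-axis s.d. of positional jitter applied to
#'   lattice sites (models imperfect packing).
#' @param slab_thickness_nm Depth of the tomogram slab spanned by every MT.
#' @param fiber_tilt Length-2 numeric `(polar, azimuthal)` tilt of the whole
#'   bundle axis relative to the slab normal, radians.
#' @param deviant_fraction Proportion of MTs planted as trajectory-deviant.
#' @param deviant_polar_max_rad Maximum planted polar deviation of a deviant MT.
#' @param wobble_polar_sd Baseline angular wobble applied to all MTs (radians;
#'   0 disables).
#' @param connector_polarity_mix Named numeric proportions over polarities
#'   `c("2" = ..., "3" = ..., "4" = ...)`; must sum to 1.
#' @param connectors_per_mt Expected number of mesh connectors per MT.
#' @param proximity_bound_nm Connector members must be mutually within this
#'   center-to-center distance (105 nm, the longest inter-MT bridges seen in
#'   2D EM). `Inf` disables the proximity preference, giving the
#'   no-association regime used for type-I error checks.
#' @param strut_radius_nm Radius of rendered connector struts (~5 nm thick).
#' @param wall_thickness_nm Thickness of the rendered MT wall.
#' @param rng_seed Integer seed; mandatory, all generator randomness flows
#'   from it.
#' @return An object of class `fiber_spec`.
#' @seealso [fiber_regime()] for the calibrated control / TACC3-overexpression
#'   presets, [simulate_fiber()].
#' @export
fiber_spec <- function(n_mts,
                       mt_diameter_nm = 25,
                       mean_nn_spacing_nm = 56.1,
                       spacing_jitter_nm = 4,
                       slab_thickness_nm = 45.6,
                       fiber_tilt = c(0, 0),
                       deviant_fraction = 0,
                       deviant_polar_max_rad = 0.15,
                       wobble_polar_sd = 0,
                       connector_polarity_mix = c("2" = 0.8, "3" = 0.15, "4" = 0.05),
                       connectors_per_mt = 0.6,
                       proximity_bound_nm = 105,
                       strut_radius_nm = 2.5,
                       wall_thickness_nm = 5,
                       rng_seed = 1L) {
  assert_scalar_num(n_mts, "n_mts", positive = TRUE)
  if (n_mts != round(n_mts)) stop_kf("`n_mts` must be an integer count")
  for (nm in c("mt_diameter_nm", "mean_nn_spacing_nm", "slab_thickness_nm",
               "strut_radius_nm", "wall_thickness_nm")) {
    assert_scalar_num(get(nm), nm, positive = TRUE)
  }
  assert_scalar_num(spacing_jitter_nm, "spacing_jitter_nm")
  if (spacing_jitter_nm < 0) stop_kf("`spacing_jitter_nm` must be >= 0")
  assert_scalar_num(deviant_fraction, "deviant_fraction")
  if (deviant_fraction < 0 || deviant_fraction > 1) {
    stop_kf("`deviant_fraction` must lie in [0, 1]")
  }
  assert_scalar_num(deviant_polar_max_rad, "deviant_polar_max_rad")
  assert_scalar_num(wobble_polar_sd, "wobble_polar_sd")
  if (wobble_polar_sd < 0) stop_kf("`wobble_polar_sd` must be >= 0")
  if (length(fiber_tilt) != 2L || !is.numeric(fiber_tilt)) {
    stop_kf("`fiber_tilt` must be numeric (polar, azimuthal)")
  }
  if (fiber_tilt[1] < 0 || fiber_tilt[1] >= pi / 2) {
    stop_kf("bundle polar tilt must lie in [0, pi/2)")
  }
  if (mean_nn_spacing_nm < mt_diameter_nm) {
    stop_kf("mean_nn_spacing_nm (%.1f) below mt_diameter_nm (%.1f): MTs would overlap",
            mean_nn_spacing_nm, mt_diameter_nm)
  }
  mix <- connector_polarity_mix
  if (is.null(names(mix)) || !all(names(mix) %in% c("2", "3", "4"))) {
    stop_kf("`connector_polarity_mix` must be named with polarities \"2\", \"3\", \"4\"")
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop_kf("`connector_polarity_mix` proportions must be >= 0 and sum to 1")
  }
  assert_scalar_num(connectors_per_mt, "connectors_per_mt")
  if (connectors_per_mt < 0) stop_kf("`connectors_per_mt` must be >= 0")
  assert_scalar_num(proximity_bound_nm, "proximity_bound_nm",
                    positive = TRUE, finite = FALSE)
  assert_scalar_num(rng_seed, "rng_seed")

  structure(list(
    n_mts = as.integer(n_mts),
    mt_diameter_nm = mt_diameter_nm,
    mean_nn_spacing_nm = mean_nn_spacing_nm,
    spacing_jitter_nm = spacing_jitter_nm,
    slab_thickness_nm = slab_thickness_nm,
    fiber_tilt = as.numeric(fiber_tilt),
    deviant_fraction = deviant_fraction,
    deviant_polar_max_rad = deviant_polar_max_rad,
    wobble_polar_sd = wobble_polar_sd,
    connector_polarity_mix = mix[order(names(mix))],
    connectors_per_mt = connectors_per_mt,
    proximity_bound_nm = proximity_bound_nm,
    strut_radius_nm = strut_radius_nm,
    wall_thickness_nm = wall_thickness_nm,
    rng_seed = as.integer(rng_seed)
  ), class = "fiber_spec")
}

#' Calibrated generator regimes for the two study conditions
#'
#' Presets emulating K-fibers from control cells and from cells
#' overexpressing TACC3 (a mesh component whose overexpression tightens MT
#' packing, enlarges mesh chains and skews MT trajectories). Packing spacing
#' (56.1 vs 48.1 nm median nearest neighbour), deviant-MT parameters, angular
#' wobble and connector rate are calibrated against the published contrasts;
#' see the methods vignette for the calibration rationale.
#'
#' @param condition `"control"` or `"tacc3_oe"`.
#' @param n_mts Bundle size; defaults to a typical size for the condition
#'   (24 control, 32 OE).
#' @param rng_seed Integer seed.
#' @param ... Further overrides passed to [fiber_spec()].
#' @return A `fiber_spec`.
#' @export
fiber_regime <- function(condition = c("control", "tacc3_oe"),
                         n_mts = NULL, rng_seed = 1L, ...) {
  condition <- match.arg(condition)
  base <- switch(condition,
    control = list(
      n_mts = n_mts %||% 24L,
      mean_nn_spacing_nm = 56.1,
      deviant_fraction = 0.10,
      deviant_polar_max_rad = 0.15,
      wobble_polar_sd = 0.096,
      connectors_per_mt = 0.28
    ),
    tacc3_oe = list(
      n_mts = n_mts %||% 32L,
      mean_nn_spacing_nm = 48.1,
      deviant_fraction = 0.40,
      deviant_polar_max_rad = 0.35,
      wobble_polar_sd = 0.118,
      connectors_per_mt = 0.50
    )
  )
  args <- utils::modifyList(c(base, list(rng_seed = rng_seed)), list(...))
  do.call(fiber_spec, args)
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf("<fiber_spec> %d MTs, nn spacing %.1f nm, slab %.1f nm\n",
              x$n_mts, x$mean_nn_spacing_nm, x$slab_thickness_nm))
  cat(sprintf("  tilt (polar %.3f, azim %.3f) rad; deviants %.0f%% (max %.2f rad); wobble sd %.3f\n",
              x$fiber_tilt[1], x$fiber_tilt[2], 100 * x$deviant_fraction,
              x$deviant_polar_max_rad, x$wobble_polar_sd))
  cat(sprintf("  connectors/MT %.2f, polarity mix %s, proximity bound %s nm, seed %d\n",
              x$connectors_per_mt,
              paste(sprintf("%s:%.2f", names(x$connector_polarity_mix),
                            x$connector_polarity_mix), collapse = " "),
              format(x$proximity_bound_nm), x$rng_seed))
  invisible(x)
}
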