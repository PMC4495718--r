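## End-to-end orchestration: generate (or load) fibers per condition, run
## packing, chain-connectivity, trajectory and (optionally) segmentation
## stages, assemble a report with provenance, and compare conditions.

#' Build a pipeline configuration
#'
#' @param conditions Named list; each element describes one condition with
#'   fields `regime` (`"control"` or `"tacc3_oe"`, see [fiber_regime()]),
#'   `n_fibers`, optional `n_mts_range` (length-2 integer range sampled per
#'   fiber) and optional named `overrides` passed to [fiber_spec()].
#' @param seed Master seed (mandatory: every stochastic stage derives
#'   sub-seeds from it).
#' @param segment Run the volume rendering + segmentation stage (slower).
#' @param radii_nm Search radii for the chained-vs-single proximity test.
#' @param neighbor_radius_nm Radius for packing neighbour counts.
#' @param z_plane_nm,threshold_nm Trajectory plane height and radial cutoff.
#' @param step_rad Rotation-search grid step.
#' @param n_permutations Membership randomization count.
#' @param voxel_nm,noise_sd Rendering parameters (segmentation stage only).
#' @param threshold_factor,min_voxels Segmentation parameters.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(conditions, seed,
                            segment = FALSE,
                            radii_nm = seq(20, 120, by = 10),
                            neighbor_radius_nm = 105,
                            z_plane_nm = 100, threshold_nm = 10,
                            step_rad = pi / 180,
                            n_permutations = 200,
                            voxel_nm = 1, noise_sd = 0.1,
                            threshold_factor = 1, min_voxels = 8L) {
  if (missing(seed)) stop_kf("`seed` is mandatory")
  assert_scalar_num(seed, "seed")
  if (length(conditions) == 0 || is.null(names(conditions)) ||
      any(names(conditions) == "")) {
    stop_kf("`conditions` must be a non-empty named list")
  }
  for (lab in names(conditions)) {
    cc <- conditions[[lab]]
    if (is.null(cc$n_fibers) || cc$n_fibers < 1) {
      stop_kf("condition %s: `n_fibers` must be >= 1", lab)
    }
  }
  assert_scalar_num(n_permutations, "n_permutations", positive = TRUE)
  structure(list(
    conditions = conditions, seed = as.integer(seed), segment = segment,
    radii_nm = radii_nm, neighbor_radius_nm = neighbor_radius_nm,
    z_plane_nm = z_plane_nm, threshold_nm = threshold_nm,
    step_rad = step_rad, n_permutations = n_permutations,
    voxel_nm = voxel_nm, noise_sd = noise_sd,
    threshold_factor = threshold_factor, min_voxels = min_voxels
  ), class = "pipeline_config")
}

spec_for_fiber <- function(cond, label, i, master_seed) {
  sub <- derive_seed(master_seed, c(label, i, "spec"))
  n_mts <- if (!is.null(cond$n_mts_range)) {
    with_seed(sub, sample(cond$n_mts_range[1]:cond$n_mts_range[2], 1))
  } else {
    NULL
  }
  args <- c(list(condition = cond$regime %||% "control",
                 n_mts = n_mts,
                 rng_seed = derive_seed(master_seed, c(label, i, "fiber"))),
            cond$overrides %||% list())
  do.call(fiber_regime, args)
}

analyse_one_fiber <- function(sf, config) {
  fib <- sf$fiber
  pts <- tibble::tibble(mt_id = fib$mts$mt_id,
                        x_nm = fib$mts$mid_x_nm, y_nm = fib$mts$mid_y_nm)
  pk <- packing_stats(pts, mt_diameter_nm = fib$mt_diameter_nm,
                      radius_nm = config$neighbor_radius_nm)
  part <- sf$chain_partition
  traj <- trajectory_stats(fib, step_rad = config$step_rad,
                           z_plane_nm = config$z_plane_nm,
                           threshold_nm = config$threshold_nm)
  seg <- NULL
  if (isTRUE(config$segment)) {
    vol <- render_fiber_volume(sf, voxel_nm = config$voxel_nm,
                               noise_sd = config$noise_sd)
    mesh <- segment_mesh(vol$density, vol$mt_labels,
                         threshold_factor = config$threshold_factor,
                         min_voxels = config$min_voxels)
    cls <- classify_connectors(mesh, vol$mt_labels)
    seg <- mesh_volume_ratios(cls, mesh, vol$mt_labels,
                              slab_thickness_nm = fib$slab_thickness_nm,
                              points = pts,
                              mt_diameter_nm = fib$mt_diameter_nm)
  }
  list(points = pts, packing = pk, partition = part, trajectory = traj,
       segmentation = seg)
}

fiber_summary_row <- function(label, fib, res) {
  pk <- res$packing; traj <- res$trajectory; part <- res$partition
  row <- tibble::tibble(
    condition = label, fiber_id = fib$fiber_id, n_mts = pk$n_mts,
    hull_area_nm2 = pk$hull_area_nm2,
    density_mts_per_um2 = pk$density_mts_per_um2,
    median_nn_nm = pk$median_nn_nm,
    median_edge_to_edge_nm = pk$median_edge_to_edge_nm,
    n_chains = length(part$sizes), max_chain = max(part$sizes),
    n_singles = length(part$singles),
    alpha_star = traj$alpha, beta_star = traj$beta,
    objective = traj$objective,
    median_theta_rad = traj$median_theta_rad,
    fraction_within = traj$fraction_within,
    r2_theta = traj$reg_theta$r_squared,
    r2_phi = traj$reg_phi$r_squared
  )
  if (!is.null(res$segmentation)) {
    s <- res$segmentation
    row$mesh_volume_nm3 <- s$total_mesh_volume_nm3
    row$mesh_to_mt_wall_ratio <- s$mesh_to_mt_wall_ratio
    row$mesh_to_filled_mt_ratio <- s$mesh_to_filled_mt_ratio
    row$mesh_percent_of_fiber_volume <- s$mesh_percent_of_fiber_volume
  }
  row
}

#' Run the full analysis pipeline
#'
#' Generates `n_fibers` synthetic fibers per condition from per-fiber
#' sub-seeds, runs packing, chain and trajectory analyses on each (plus
#' rendering and segmentation when enabled), pools MTs per condition for
#' the chained-vs-single proximity test with membership randomization, and
#' assembles everything into an `analysis_report`. A failure in one fiber
#' is logged in the report's `errors` field and does not abort the others.
#'
#' @param config A [pipeline_config()].
#' @return An `analysis_report`: list with `provenance`, `per_fiber`,
#'   `per_mt`, `polarity`, `chain_histogram`, `proximity`, `comparisons`,
#'   `errors`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  per_fiber <- list(); per_mt <- list(); errors <- list()
  pooled_points <- list(); pooled_chained <- list()
  graphs <- list(); partitions <- list()

  for (label in names(config$conditions)) {
    cond <- config$conditions[[label]]
    pooled_points[[label]] <- list()
    pooled_chained[[label]] <- list()
    graphs[[label]] <- list(); partitions[[label]] <- list()
    for (i in seq_len(cond$n_fibers)) {
      fiber_id <- sprintf("%s_%02d", label, i)
      res <- tryCatch({
        spec <- spec_for_fiber(cond, label, i, config$seed)
        sf <- simulate_fiber(spec, fiber_id = fiber_id, condition_label = label)
        analysis <- analyse_one_fiber(sf, config)
        list(sf = sf, analysis = analysis)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- list(fiber_id = fiber_id,
                                              message = conditionMessage(res))
        next
      }
      sf <- res$sf; analysis <- res$analysis
      per_fiber[[fiber_id]] <- fiber_summary_row(label, sf$fiber, analysis)
      chained <- analysis$partition$table$chain_size >= 2
      nn <- nearest_neighbor_stats(analysis$points, sf$fiber$mt_diameter_nm)
      per_mt[[fiber_id]] <- tibble::tibble(
        condition = label, fiber_id = fiber_id,
        mt_id = analysis$points$mt_id,
        x_nm = analysis$points$x_nm, y_nm = analysis$points$y_nm,
        nn_nm = nn$nn_nm,
        neighbor_count = analysis$packing$neighbor_counts$count,
        chain_id = analysis$partition$table$chain_id,
        chain_size = analysis$partition$table$chain_size,
        theta_rad = analysis$trajectory$per_mt$theta_rad,
        phi_rad = analysis$trajectory$per_mt$phi_rad,
        dist_center_nm = analysis$trajectory$per_mt$dist_center_nm,
        ix_nm = analysis$trajectory$per_mt$ix_nm,
        iy_nm = analysis$trajectory$per_mt$iy_nm,
        within_threshold = analysis$trajectory$per_mt$within_threshold
      )
      pooled_points[[label]][[i]] <- analysis$points
      pooled_chained[[label]][[i]] <- chained
      graphs[[label]][[i]] <- sf$connectors
      partitions[[label]][[i]] <- analysis$partition
    }
  }

  proximity <- list()
  polarity <- list()
  chain_hist <- list()
  for (label in names(config$conditions)) {
    pts <- Filter(Negate(is.null), pooled_points[[label]])
    ch <- Filter(Negate(is.null), pooled_chained[[label]])
    if (length(pts) > 0) {
      obs <- chained_vs_single_test(pts, ch, config$radii_nm)
      rnd <- randomize_membership(pts, ch, config$radii_nm,
                                  n_permutations = config$n_permutations,
                                  seed = derive_seed(config$seed, c(label, "perm")))
      obs$p_randomized_median <- unname(rnd$median_p)
      proximity[[label]] <- obs
      polarity[[label]] <- polarity_proportions(Filter(Negate(is.null), graphs[[label]]))
      chain_hist[[label]] <- chain_size_histogram(Filter(Negate(is.null), partitions[[label]]))
    }
  }

  report <- structure(list(
    provenance = list(
      seed = config$seed,
      config_hash = config_hash(unclass(config)),
      package_version = as.character(utils::packageVersion("kfibermesh"))
    ),
    per_fiber = do.call(rbind, per_fiber),
    per_mt = do.call(rbind, per_mt),
    polarity = polarity,
    chain_histogram = chain_hist,
    proximity = proximity,
    comparisons = NULL,
    errors = errors
  ), class = "analysis_report")
  report$comparisons <- tryCatch(compare_conditions(report),
                                 error = function(e) NULL)
  report
}

#' Compare per-fiber medians across conditions
#'
#' For each metric (median polar angle, median nearest-neighbour distance,
#' fraction of near-parallel MTs, MT count, hull area) the per-fiber values
#' of the two conditions are compared with the two-sample rank-sum test.
#'
#' @param report An `analysis_report` with at least two conditions.
#' @return Tibble (`metric`, condition medians, `statistic`, `p_value`); with
#'   fewer than two conditions an empty tibble carrying a `note` attribute.
#' @export
compare_conditions <- function(report) {
  pf <- report$per_fiber
  labs <- unique(pf$condition)
  if (length(labs) < 2) {
    out <- tibble::tibble()
    attr(out, "note") <- "single condition: comparison skipped"
    return(out)
  }
  a <- labs[1]; b <- labs[2]
  metrics <- c("median_theta_rad", "median_nn_nm", "fraction_within",
               "n_mts", "hull_area_nm2")
  rows <- lapply(metrics, function(mt) {
    va <- pf[[mt]][pf$condition == a]
    vb <- pf[[mt]][pf$condition == b]
    ts <- rank_sum_test(va, vb)
    tibble::tibble(metric = mt,
                   condition_a = a, median_a = stats::median(va, na.rm = TRUE),
                   condition_b = b, median_b = stats::median(vb, na.rm = TRUE),
                   statistic = ts$statistic, p_value = ts$p_value,
                   method = ts$method)
  })
  do.call(rbind, rows)
}

#' Write an analysis report to disk
#'
#' Emits a machine-readable JSON (canonical key order, no timestamps, so a
#' re-run with the same config and seed is byte-identical) plus TSV summary
#' tables (per fiber, per MT, proximity tests, condition comparisons).
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    provenance = report$provenance,
    per_fiber = report$per_fiber,
    polarity = report$polarity,
    chain_histogram = report$chain_histogram,
    proximity = report$proximity,
    comparisons = report$comparisons,
    errors = report$errors
  )
  write_json_canonical(json, file.path(dir, "report.json"))
  wt <- function(x, f) {
    if (!is.null(x) && nrow(x) > 0) {
      utils::write.table(as.data.frame(x), file.path(dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(report$per_fiber, "per_fiber.tsv")
  wt(report$per_mt, "per_mt.tsv")
  wt(report$comparisons, "comparisons.tsv")
  for (label in names(report$proximity)) {
    wt(report$proximity[[label]], sprintf("proximity_%s.tsv", label))
  }
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d fibers, %d MTs, %d condition(s), %d error(s)\n",
              if (is.null(x$per_fiber)) 0 else nrow(x$per_fiber),
              if (is.null(x$per_mt)) 0 else nrow(x$per_mt),
              length(unique(x$per_fiber$condition)), length(x$errors)))
  invisible(x)
}
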