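#!/usr/bin/env Rscript
## 05 -- MT trajectory deviation after rotational normalization.
##
## Reads the fiber tables from 01_simulate.R, zenith-normalizes each
## fiber's orientation by the exhaustive Euler-rotation search, and writes
## per-MT spherical angles, plane intersections (z = 100 nm), the
## near-parallel fraction and the angle-vs-distance regressions to
## results/trajectory/. If ggplot2 is available, a plane-intersection
## scatter is rendered per condition.

library(kfibermesh)

data_dir <- "results/data"
out_dir <- "results/trajectory"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
manifest <- read.delim(file.path(data_dir, "manifest.tsv"))

per_mt <- list(); per_fiber <- list()
for (fid in manifest$fiber_id) {
  fib <- read_fiber_table(file.path(data_dir, paste0(fid, ".tsv")))
  tr <- trajectory_stats(fib)
  per_mt[[fid]] <- data.frame(fiber_id = fid, condition = fib$condition_label,
                              tr$per_mt)
  per_fiber[[fid]] <- data.frame(
    fiber_id = fid, condition = fib$condition_label,
    alpha_star = tr$alpha, beta_star = tr$beta, objective = tr$objective,
    median_theta_rad = tr$median_theta_rad,
    fraction_within_10nm = tr$fraction_within,
    r2_theta = tr$reg_theta$r_squared, r2_phi = tr$reg_phi$r_squared)
}
pm <- do.call(rbind, per_mt)
pf <- do.call(rbind, per_fiber)
write.table(pm, file.path(out_dir, "per_mt.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pf, file.path(out_dir, "per_fiber.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (cond in unique(pf$condition)) {
  sub <- pm[pm$condition == cond, ]
  cat(sprintf("%s: median theta %.3f rad, fraction within 10 nm = %.2f (n = %d MTs)\n",
              cond, median(sub$theta_rad), mean(sub$within_threshold),
              nrow(sub)))
}

## per-fiber median polar angles compared across conditions
conds <- unique(pf$condition)
if (length(conds) == 2) {
  ts <- rank_sum_test(pf$median_theta_rad[pf$condition == conds[1]],
                      pf$median_theta_rad[pf$condition == conds[2]])
  cat(sprintf("rank-sum test of per-fiber median theta (%s vs %s): p = %.4g\n",
              conds[1], conds[2], ts$p_value))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(pm, aes(ix_nm, iy_nm)) +
    geom_point(alpha = 0.5, size = 0.8, na.rm = TRUE) +
    coord_equal(xlim = c(-60, 60), ylim = c(-60, 60)) +
    facet_wrap(~condition) +
    labs(x = "x (nm)", y = "y (nm)",
         title = "MT vector intersections with the plane z = 100 nm") +
    theme_minimal()
  ggsave(file.path(out_dir, "plane_intersections.png"), p,
         width = 7, height = 3.8, dpi = 150)
}
cat("wrote", out_dir, "\n")
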