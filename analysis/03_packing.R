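#!/usr/bin/env Rscript
## 03 -- Cross-sectional MT packing analysis.
##
## Reads the fiber tables written by 01_simulate.R, computes per-fiber
## packing statistics (hull area, MT density, nearest-neighbour spacing,
## local neighbour counts) and a Voronoi heat map per condition, and writes
## results/packing/.

library(kfibermesh)

data_dir <- "results/data"
out_dir <- "results/packing"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(file.path(data_dir, "manifest.tsv"))) {
  stop("run analysis/01_simulate.R first")
}
manifest <- read.delim(file.path(data_dir, "manifest.tsv"))

per_fiber <- list(); per_mt <- list()
for (fid in manifest$fiber_id) {
  fib <- read_fiber_table(file.path(data_dir, paste0(fid, ".tsv")))
  pts <- tibble::tibble(mt_id = fib$mts$mt_id,
                        x_nm = fib$mts$mid_x_nm, y_nm = fib$mts$mid_y_nm)
  ps <- packing_stats(pts, radius_nm = 105)
  per_fiber[[fid]] <- data.frame(
    fiber_id = fid, condition = fib$condition_label,
    n_mts = ps$n_mts, hull_area_nm2 = ps$hull_area_nm2,
    density_mts_per_um2 = ps$density_mts_per_um2,
    median_nn_nm = ps$median_nn_nm,
    median_edge_to_edge_nm = ps$median_edge_to_edge_nm)
  per_mt[[fid]] <- data.frame(
    fiber_id = fid, condition = fib$condition_label, mt_id = pts$mt_id,
    nn_nm = ps$nn_distances_nm, count_r105 = ps$neighbor_counts$count)

  ## heat map for the first fiber of each condition
  if (fid %in% manifest$fiber_id[!duplicated(manifest$condition)]) {
    hm <- packing_heatmap(pts, radius_nm = 105, grid_nm = 5)
    write.table(hm$z, file.path(out_dir, paste0(fid, "_heatmap.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
}
pf <- do.call(rbind, per_fiber)
write.table(pf, file.path(out_dir, "per_fiber.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, per_mt), file.path(out_dir, "per_mt.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (cond in unique(pf$condition)) {
  sub <- pf[pf$condition == cond, ]
  cat(sprintf("%s: %d fibers, median nn %.1f nm (edge-to-edge %.1f nm), density %.0f MTs/um^2\n",
              cond, nrow(sub), median(sub$median_nn_nm),
              median(sub$median_edge_to_edge_nm),
              median(sub$density_mts_per_um2)))
}
cat("wrote", out_dir, "\n")
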