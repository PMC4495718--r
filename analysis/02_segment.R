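#!/usr/bin/env Rscript
## 02 -- Render tomogram-like volumes and segment the inter-MT mesh.
##
## Two fibers per condition are rendered at 1 nm voxels with additive noise
## at 10% of the MT wall density, written out as MRC (density + label
## volumes), read back, and segmented with the MT-anchored threshold. The
## detected connector table and the mesh volume statistics go to
## results/segmentation/.

library(kfibermesh)

seed <- 42
out_dir <- "results/segmentation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

conn_rows <- list(); stat_rows <- list()
for (cond in c("control", "tacc3_oe")) {
  for (i in 1:2) {
    fiber_id <- sprintf("%s_%02d", cond, i)
    ## smaller bundles keep volumes at desk scale (~2e6 voxels)
    sp <- fiber_regime(cond, n_mts = 10,
                       rng_seed = derive_seed(seed, c("seg", cond, i)),
                       slab_thickness_nm = 40)
    sf <- simulate_fiber(sp, fiber_id = fiber_id, condition_label = cond)
    vol <- render_fiber_volume(sf, voxel_nm = 1, noise_sd = 0.1)

    dens_path <- file.path(out_dir, paste0(fiber_id, "_density.mrc"))
    lab_path <- file.path(out_dir, paste0(fiber_id, "_labels.mrc"))
    write_mrc(vol$density, dens_path)
    write_mrc(vol$mt_labels, lab_path)
    loaded <- read_volume(dens_path, labels_path = lab_path)

    mesh <- segment_mesh(loaded$density, loaded$labels)
    cls <- classify_connectors(mesh, loaded$labels)
    st <- mesh_volume_ratios(cls, mesh, loaded$labels,
                             slab_thickness_nm = sp$slab_thickness_nm,
                             points = tibble::tibble(
                               mt_id = sf$fiber$mts$mt_id,
                               x_nm = sf$fiber$mts$mid_x_nm,
                               y_nm = sf$fiber$mts$mid_y_nm))

    ct <- cls$connectors
    conn_rows[[fiber_id]] <- data.frame(
      fiber_id = fiber_id, condition = cond,
      connector_id = ct$connector_id, polarity = ct$polarity,
      volume_nm3 = ct$volume_nm3,
      touched_mts = vapply(ct$touched_mts, paste, collapse = ",",
                           FUN.VALUE = character(1)))
    stat_rows[[fiber_id]] <- data.frame(
      fiber_id = fiber_id, condition = cond,
      n_planted = nrow(vol$connectors$edges),
      n_detected = nrow(ct),
      mesh_volume_nm3 = st$total_mesh_volume_nm3,
      mesh_to_mt_wall_ratio = st$mesh_to_mt_wall_ratio,
      mesh_to_filled_mt_ratio = st$mesh_to_filled_mt_ratio,
      mesh_percent_of_fiber_volume = st$mesh_percent_of_fiber_volume)
    cat(sprintf("%s: planted %d connectors, detected %d (mesh %.2f%% of fiber volume)\n",
                fiber_id, nrow(vol$connectors$edges), nrow(ct),
                st$mesh_percent_of_fiber_volume))
  }
}
write.table(do.call(rbind, conn_rows), file.path(out_dir, "connectors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, stat_rows), file.path(out_dir, "mesh_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out_dir, "\n")
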