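#!/usr/bin/env Rscript
## 01 -- Simulate the two-condition K-fiber dataset.
##
## Generates synthetic K-fibers under the calibrated control and
## TACC3-overexpression regimes and writes their coordinate tables (TSV)
## and ground-truth connector graphs (JSON) under results/data/, so that
## the later stages read their inputs from disk exactly as a tomogram-
## derived dataset would be read.

library(kfibermesh)

seed <- 42
n_fibers <- 6
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- list()
for (cond in c("control", "tacc3_oe")) {
  for (i in seq_len(n_fibers)) {
    sp <- fiber_regime(cond, rng_seed = derive_seed(seed, c(cond, i)))
    sf <- simulate_fiber(sp, fiber_id = sprintf("%s_%02d", cond, i),
                         condition_label = cond)
    write_fiber_table(sf$fiber, file.path(out_dir, paste0(sf$fiber$fiber_id, ".tsv")))
    write_connector_graph(sf$connectors,
                          file.path(out_dir, paste0(sf$fiber$fiber_id, "_connectors.json")))
    manifest[[length(manifest) + 1L]] <- data.frame(
      fiber_id = sf$fiber$fiber_id, condition = cond,
      n_mts = nrow(sf$fiber$mts),
      n_connectors = nrow(sf$connectors$edges),
      max_chain = max(sf$chain_partition$sizes))
  }
}
manifest <- do.call(rbind, manifest)
write.table(manifest, file.path(out_dir, "manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d fibers (%d per condition), seed %d\n",
            nrow(manifest), n_fibers, seed))
cat(sprintf("MTs per fiber: %d-%d; connectors per fiber: %d-%d; largest chain: %d MTs\n",
            min(manifest$n_mts), max(manifest$n_mts),
            min(manifest$n_connectors), max(manifest$n_connectors),
            max(manifest$max_chain)))
cat("wrote", out_dir, "\n")
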