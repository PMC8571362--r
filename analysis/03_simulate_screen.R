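#!/usr/bin/env Rscript

# Step 3 -- generate the synthetic combinatorial-knockdown screen.
#
# A 10-gene panel (45 pairs) on dense arrays, 8 biological replicates,
# 14% planted image-QC failures. Planted structure covers the full taxonomy:
#   * single effects of both signs (G01 +2, G02 +1.5, G03 -2, G04 -1.6),
#   * an aggravating interaction (G01__G02 +1.5: joint 5.0 beyond the
#     additive expectation 3.5),
#   * an alleviating interaction (G03__G04 +1.6: joint -2.0, right at the
#     most severe single phenotype),
#   * a suppressive interaction (G03__G05 +1.2: joint -0.8, milder than the
#     severe single -2),
#   * an interaction between two null singles (G06__G07 +2, emergent).
# A second, independently seeded replicate acts as the validation screen.

suppressMessages(library(pairscan))

seed <- 20260927L
out_dir <- "results/screen"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- screen_sim_config(
  genes = paste0("G", sprintf("%02d", 1:10)),
  spots_per_array = 130,
  n_replicates = 8L,
  gene_effects = c(G01 = 2, G02 = 1.5, G03 = -2, G04 = -1.6),
  interaction_effects = c(G01__G02 = 1.5, G03__G04 = 1.6,
                          G03__G05 = 1.2, G06__G07 = 2),
  qc_fail_rate = 0.14,
  seed = seed)

primary <- simulate_screen(cfg)
write_table(primary$layout, file.path(out_dir, "layout.tsv"))
write_table(primary$measurements, file.path(out_dir, "measurements.tsv"))
write_table(primary$truth, file.path(out_dir, "screen_truth.tsv"))

cfg_val <- cfg
cfg_val$seed <- seed + 1L
validation <- simulate_screen(cfg_val)
write_table(validation$measurements,
            file.path(out_dir, "validation_measurements.tsv"))

write_manifest(file.path(out_dir, "manifest.json"),
               command = "simulate-screen", config = cfg, seed = seed,
               outputs = file.path(out_dir, c(
                 "layout.tsv", "measurements.tsv", "screen_truth.tsv",
                 "validation_measurements.tsv")))

cat(sprintf(
  "simulated %d spots x %d replicates (%d images); %d pairs, %d planted GIs\n",
  nrow(primary$layout), cfg$n_replicates, nrow(primary$measurements),
  sum(primary$truth$pair != ""), sum(primary$truth$true_label == "GI")))
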