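#!/usr/bin/env Rscript

# Step 4 -- the functional arm.
#
# QC-filters the per-image measurements, computes per-array robust Z-scores
# against the negative controls, runs the five-model battery for all 45
# pairs with one 3 x 45 FDR family, labels significant interactions with the
# GI taxonomy, and confirms primary calls against the independent
# validation screen (adjusted p < 0.01 and matching interaction-value sign).
# Reads results/screen/, writes the scan and validation tables back there.

suppressMessages(library(pairscan))

in_dir <- "results/screen"
suppressMessages({
  layout <- read_table(file.path(in_dir, "layout.tsv"),
                       schema = "screen_layout")
  meas <- read_table(file.path(in_dir, "measurements.tsv"),
                     schema = "screen_measurements")
  meas_val <- read_table(file.path(in_dir, "validation_measurements.tsv"),
                         schema = "screen_measurements")
  truth <- read_table(file.path(in_dir, "screen_truth.tsv"))
})

qc <- qc_filter_images(meas, layout = layout)
cat(sprintf("image QC: %d of %d images pass (%.1f%%)\n",
            nrow(qc$measurements), nrow(meas),
            100 * nrow(qc$measurements) / nrow(meas)))

z <- robust_z_scores(qc$measurements, layout)
write_table(as.data.frame(z), file.path(in_dir, "robust_z.tsv"))
write_table(attr(z, "medians"), file.path(in_dir, "median_z.tsv"))

primary <- suppressWarnings(screen_scan(z))
write_table(primary, file.path(in_dir, "screen_results.tsv"))

qc_val <- qc_filter_images(meas_val, layout = layout)
z_val <- robust_z_scores(qc_val$measurements, layout)
validation_scan <- suppressWarnings(
  screen_scan(z_val, pairs = do.call(
    rbind, lapply(strsplit(primary$pair[primary$classification == "GI"],
                           "__"),
                  function(p) data.frame(id1 = p[1], id2 = p[2])))))
validated <- validate_gi_calls(primary, validation_scan)
write_table(validated, file.path(in_dir, "validation_results.tsv"))

write_manifest(file.path(in_dir, "scan_manifest.json"),
               command = "screen-scan",
               inputs = file.path(in_dir, c("layout.tsv", "measurements.tsv",
                                            "validation_measurements.tsv")),
               outputs = file.path(in_dir, c(
                 "robust_z.tsv", "median_z.tsv", "screen_results.tsv",
                 "validation_results.tsv")))

gi <- primary[primary$classification == "GI", ]
cat(sprintf("screen scan: %d pairs, family m = %d; %d GI, %d AE\n",
            nrow(primary), attr(primary, "family_size"), nrow(gi),
            sum(primary$classification == "AE")))
for (i in seq_len(nrow(gi))) {
  tr <- truth[truth$pair == gi$pair[i], ]
  cat(sprintf("  %-10s IV = %+.2f (planted %+.1f)  %-22s evidence: %s\n",
              gi$pair[i], gi$interaction_value[i],
              if (nrow(tr)) tr$beta_ab else NA, gi$gi_type[i],
              gi$evidence[i]))
}
cat(sprintf("validation: %d of %d primary GI calls confirmed\n",
            sum(validated$validated), nrow(validated)))
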