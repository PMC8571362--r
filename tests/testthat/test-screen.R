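small_screen <- function(seed = 71, genes = paste0("G", 1:4),
                         gene_effects = NULL, interaction_effects = NULL,
                         n_replicates = 8L, qc_fail_rate = 0) {
  simulate_screen(screen_sim_config(
    genes = genes, spots_per_array = 40, n_replicates = n_replicates,
    gene_effects = gene_effects, interaction_effects = interaction_effects,
    qc_fail_rate = qc_fail_rate, seed = seed))
}

test_that("QC filtering removes exactly the failing images", {
  ss <- small_screen(seed = 72, qc_fail_rate = 0)
  # with fixed permissive thresholds, a clean screen passes untouched
  q0 <- qc_filter_images(ss$measurements, min_cells = 1,
                         min_sharpness = 0, max_background = 1e9)
  expect_identical(q0$measurements, ss$measurements)
  expect_true(all(q0$report$pass_rate == 1))

  m <- ss$measurements
  m$cell_count[5] <- 0
  q2 <- qc_filter_images(m, min_sharpness = 0, max_background = 1e9)
  expect_equal(nrow(q2$measurements), nrow(m) - 1)

  # control-derived quantile thresholds trim only the distribution tails
  q3 <- qc_filter_images(ss$measurements, layout = ss$layout)
  expect_gte(min(q3$report$pass_rate), 0.8)
})

test_that("planted QC failures drive the pass rate to its planted value", {
  ss <- small_screen(seed = 73, qc_fail_rate = 0.14)
  q <- qc_filter_images(ss$measurements, layout = ss$layout)
  planted <- attr(ss$measurements, "planted_fail")
  rate <- nrow(q$measurements) / nrow(ss$measurements)
  # pass rate ~ (1 - planted rate) minus the small control-quantile loss
  expect_equal(rate, 1 - mean(planted), tolerance = 0.08)
  expect_gt(rate, 0.75)
  expect_lt(rate, 0.95)
})

test_that("robust Z-scores implement the control-median/MAD definition", {
  layout <- data.frame(array = "A1", spot = 1:7,
                       gene_a = c(rep("CTRL", 5), "GX", "GX"),
                       gene_b = c(rep("CTRL", 5), "CTRL", "GY"),
                       role = c(rep("negative-control", 5), "treatment",
                                "treatment"))
  meas <- data.frame(array = "A1", spot = c(1:5, 6, 7), image = 1,
                     replicate = 1,
                     mean_cell_intensity = c(10, 12, 11, 13, 14, 20, 12),
                     cell_count = 50, sharpness = 1, background = 100)
  z <- robust_z_scores(meas, layout)
  # hand evaluation: median = 12, scaled MAD = 1.4826 * median(|c - 12|) = 1.4826
  expect_equal(z$z[z$treatment == "GX__CTRL"], (20 - 12) / 1.4826,
               tolerance = 1e-12)
  # treated value at the control median scores zero
  expect_equal(z$z[z$treatment == "GX__GY"], 0, tolerance = 1e-12)
  # raw-MAD mode drops the 1.4826 scaling
  z_raw <- robust_z_scores(meas, layout, mad_scale = FALSE)
  expect_equal(z_raw$z[z_raw$treatment == "GX__CTRL"], 8, tolerance = 1e-12)
  # one scaled-MAD unit above the median scores exactly 1
  meas2 <- meas
  meas2$mean_cell_intensity[6] <- 12 + 1.4826
  z1 <- robust_z_scores(meas2, layout)
  expect_equal(z1$z[z1$treatment == "GX__CTRL"], 1, tolerance = 1e-12)
})

test_that("robust Z-scores are invariant to affine rescaling of an array", {
  ss <- small_screen(seed = 74)
  z0 <- robust_z_scores(ss$measurements, ss$layout)
  shifted <- ss$measurements
  shifted$mean_cell_intensity <- shifted$mean_cell_intensity + 500
  expect_equal(robust_z_scores(shifted, ss$layout)$z, z0$z,
               tolerance = 1e-10)
  scaled <- ss$measurements
  scaled$mean_cell_intensity <- scaled$mean_cell_intensity * 3.7
  expect_equal(robust_z_scores(scaled, ss$layout)$z, z0$z, tolerance = 1e-10)
})

test_that("a zero control MAD excludes the array with an error record", {
  layout <- data.frame(array = "A1", spot = 1:4,
                       gene_a = c(rep("CTRL", 3), "GX"),
                       gene_b = c(rep("CTRL", 3), "CTRL"),
                       role = c(rep("negative-control", 3), "treatment"))
  meas <- data.frame(array = "A1", spot = 1:4, image = 1, replicate = 1,
                     mean_cell_intensity = c(10, 10, 10, 20),
                     cell_count = 50, sharpness = 1, background = 100)
  expect_error(robust_z_scores(meas, layout), "no array")
})

test_that("an exactly additive double knockdown yields a null interaction value", {
  set.seed(75)
  best <- character(20)
  for (i in seq_along(best)) {
    fit <- fit_screen_models(zgroup(8, 1.2, 0.01), zgroup(8, 0.7, 0.01),
                             zgroup(8, 1.9, 0.01), zgroup(8, 0, 0.01))
    expect_lt(abs(fit$beta_ab), 0.05)
    best[i] <- fit$best_model
  }
  # the additive model wins in the clear majority of replicate draws
  expect_gte(mean(best == "M3"), 0.75)
})

test_that("flat screens select the intercept-only model", {
  set.seed(76)
  best <- replicate(20, fit_screen_models(zgroup(8, 0), zgroup(8, 0),
                                          zgroup(8, 0),
                                          zgroup(8, 0))$best_model)
  expect_gte(mean(best == "M0"), 0.7)
  expect_lte(mean(best == "M4"), 0.15)
})

test_that("a planted interaction is recovered within 3 SE and selects the interaction model", {
  set.seed(77)
  fit <- fit_screen_models(zgroup(8, 1), zgroup(8, 0.8),
                           zgroup(8, 1 + 0.8 + 2), zgroup(8, 0))
  expect_equal(fit$best_model, "M4")
  expect_lt(abs(fit$beta_ab - 2), 3 * fit$se_ab)
  expect_equal(fit$evidence, "strong")
})

test_that("the balanced-fit identity beta_ab = mean contrast of the four cells holds", {
  set.seed(78)
  # bimodal bounded noise keeps all Huber weights at 1: the identity is exact
  bi <- function(n, mean) mean + sample(c(-1, 1), n, TRUE) * runif(n, 0.1, 0.2)
  z_a <- bi(10, 0.9); z_b <- bi(10, -0.4)
  z_ab <- bi(10, 1.4); z_c <- bi(10, 0)
  fit <- fit_screen_models(z_a, z_b, z_ab, z_c)
  contrast <- mean(z_ab) - mean(z_a) - mean(z_b) + mean(z_c)
  expect_equal(fit$beta_ab, contrast, tolerance = 1e-6)
})

test_that("too few replicates make a pair inestimable, not an error", {
  fit <- fit_screen_models(zgroup(2, 1), zgroup(8, 1), zgroup(8, 1),
                           zgroup(8, 0))
  expect_false(fit$estimable)
  expect_equal(fit$missing, "A")
})

test_that("the taxonomy reproduces the three forced decisions", {
  expect_equal(classify_gi_type(tau = 0.5, beta0 = 0, beta_a = 1.0,
                                beta_b = 0.8, beta_ab = 1.0),
               "negative-aggravating")
  expect_equal(classify_gi_type(tau = 0.5, beta0 = 0, beta_a = -2.4,
                                beta_b = 0.5, beta_ab = -0.59),
               "positive-alleviating")
  expect_equal(classify_gi_type(tau = 0.5, beta0 = 0, beta_a = -2.0,
                                beta_b = -0.2, beta_ab = 1.2),
               "positive-suppressive")
})

test_that("the taxonomy is a partition and symmetric under gene relabeling", {
  set.seed(79)
  labels <- c("negative-aggravating", "positive-alleviating",
              "positive-suppressive", "emergent")
  for (i in 1:50) {
    ba <- runif(1, -3, 3); bb <- runif(1, -3, 3); bab <- runif(1, -3, 3)
    l1 <- classify_gi_type(tau = 0.4, beta0 = 0, beta_a = ba, beta_b = bb,
                           beta_ab = bab)
    l2 <- classify_gi_type(tau = 0.4, beta0 = 0, beta_a = bb, beta_b = ba,
                           beta_ab = bab)
    expect_true(l1 %in% labels)
    expect_identical(l1, l2)
  }
  expect_equal(classify_gi_type(tau = 0.5, beta0 = 0, beta_a = 0.1,
                                beta_b = -0.2, beta_ab = 2), "emergent")
})

test_that("a screen scan pools one FDR family of 3 slots per pair", {
  ss <- small_screen(seed = 80, genes = paste0("G", 1:5),
                     gene_effects = c(G1 = 1.5),
                     interaction_effects = c(G1__G2 = 2.5))
  z <- robust_z_scores(ss$measurements, ss$layout)
  res <- screen_scan(z)
  expect_equal(nrow(res), choose(5, 2))
  expect_equal(attr(res, "family_size"), 3 * choose(5, 2))
  gi <- res[res$pair == "G1__G2", ]
  expect_equal(gi$classification, "GI")
  expect_false(is.na(gi$gi_type))
  expect_true(all(is.na(res$gi_type[res$classification != "GI"])))
})

test_that("validation requires both significance and matching directionality", {
  primary <- data.frame(pair = c("APOB__HMGCR", "X__Y", "P__Q"),
                        interaction_value = c(2.18, -1.5, 1.0),
                        gi_type = c("negative-aggravating", NA, NA))
  validation <- data.frame(
    pair = c("APOB__HMGCR", "X__Y", "P__Q", "NOT__SEEN"),
    interaction_value = c(0.97, 1.5, 1.0, 0.5),
    p_ab_fdr = c(1.27e-3, 1e-5, 0.02, 1e-4))
  expect_warning(v <- validate_gi_calls(primary, validation), "NOT__SEEN")
  # same-sign significant interaction: validated (the headline pattern)
  expect_true(v$validated[v$pair == "APOB__HMGCR"])
  # sign flip: never validated, however significant
  expect_false(v$validated[v$pair == "X__Y"])
  # adjusted p above 0.01: not validated
  expect_false(v$validated[v$pair == "P__Q"])
})
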