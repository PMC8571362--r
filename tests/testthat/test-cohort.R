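make_cohort_fixture <- function(n = 400, seed = 51) {
  cfg <- cohort_sim_config(n_samples = n, seed = seed)
  simulate_cohort(cfg)
}

test_that("residualization leaves residuals orthogonal to every covariate", {
  sim <- make_cohort_fixture()
  res <- residualize_phenotypes(sim$cohort)
  covs <- res$covariates_used
  for (tr in names(res$residuals)) {
    r <- res$residuals[[tr]]
    d <- sim$cohort[match(names(r), sim$cohort$sample), covs]
    for (cv in covs) expect_lt(abs(cor(r, d[[cv]])), 1e-8)
    expect_lt(abs(mean(r)), 1e-10)
  }
})

test_that("residual variance approaches the generating noise variance", {
  set.seed(52)
  cfg <- cohort_sim_config(n_samples = 4000, seed = 52)
  sim <- simulate_cohort(cfg)
  res <- residualize_phenotypes(sim$cohort, traits = "LDLc")
  # trait = covariate signal + noise; residualization strips the signal
  expect_equal(sd(res$residuals$LDLc), cfg$noise_sd[["LDLc"]],
               tolerance = 0.05)
})

test_that("zero-variance covariates collapse residuals to the centred trait", {
  d <- data.frame(sample = paste0("s", 1:50), age = 50, sex = 1,
                  LDLc = rnorm(50, 130, 30))
  expect_warning(res <- residualize_phenotypes(d, traits = "LDLc",
                                               covariates = c("age", "sex")),
                 "zero-variance")
  expect_equal(unname(res$residuals$LDLc), d$LDLc - mean(d$LDLc))
})

test_that("burden encoding collapses variants, supports counts and exclusions", {
  calls <- data.frame(sample = c("s1", "s1", "s2", "s3"),
                      gene = c("GA", "GA", "GA", "GB"),
                      variant = c("v1", "v2", "v1", "v9"))
  samples <- paste0("s", 1:4)
  ind <- encode_ptv_burden(calls, samples, genes = c("GA", "GB"))
  expect_equal(unname(ind[, "GA"]), c(1, 1, 0, 0))
  expect_equal(unname(ind[, "GB"]), c(0, 0, 1, 0))
  cnt <- encode_ptv_burden(calls, samples, genes = c("GA", "GB"),
                           mode = "count")
  expect_equal(unname(cnt["s1", "GA"]), 2)
  # excluding a carrier's only variant zeroes the burden
  excl <- encode_ptv_burden(calls, samples, genes = c("GA", "GB"),
                            exclude_variants = "v1")
  expect_equal(unname(excl[, "GA"]), c(1, 0, 0, 0))
  expect_true(all(excl <= ind))  # exclusion never increases burden
  expect_warning(
    encode_ptv_burden(calls, samples, exclude_variants = "nope"),
    "not present")
})

test_that("simulated carrier counts land in the binomial interval", {
  cfg <- cohort_sim_config(n_samples = 10000, genes = "G01",
                           carrier_freq = 0.01, seed = 53)
  sim <- simulate_cohort(cfg)
  b <- encode_ptv_burden(sim$ptv_calls, sim$cohort$sample, genes = "G01")
  ci <- qbinom(c(0.005, 0.995), 10000, 0.01)
  expect_gte(sum(b), ci[1])
  expect_lte(sum(b), ci[2])
})

test_that("polygenic scores are exact weighted dosage sums with region exclusion", {
  dos <- matrix(c(2, 1, 0, 0, 2, 1), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("r1", "r2", "r3")))
  w <- data.frame(snp = c("r1", "r2", "r3"), chrom = c("chr1", "chr2", "chr2"),
                  pos = c(100, 200, 300), weight = c(0.5, -0.2, 0.1))
  expect_equal(unname(compute_prs(dos, w)), c(0.8, -0.3),
               ignore_attr = TRUE)
  expect_equal(unname(compute_prs(dos, transform(w, weight = 0))), c(0, 0),
               ignore_attr = TRUE)
  excl <- compute_prs(dos, w, exclude_region = list(chrom = "chr1",
                                                    start = 1, end = 1000))
  expect_equal(unname(excl["s1"]), -0.2 * 1 + 0.1 * 0)
  expect_error(compute_prs(dos, w[1, ],
                           exclude_region = list(chrom = "chr1",
                                                 start = 1, end = 1000)),
               "no SNPs left")
})

test_that("testability requires double-exposed samples and a non-collinear product", {
  x <- c(rep(1, 5), rep(0, 95))
  z <- c(rep(0, 5), rep(1, 5), rep(0, 90))
  expect_false(assess_testability(x, z)$testable)  # no double carriers
  expect_false(assess_testability(x, x)$testable)  # perfect collinearity
  set.seed(54)
  a <- rbinom(200, 1, 0.3)
  b <- rbinom(200, 1, 0.3)
  t3 <- assess_testability(a, b)
  expect_true(t3$testable)
  expect_equal(t3$joint_exposed, sum(a & b))
  # one double-exposed sample suffices at the default threshold
  x1 <- c(1, 1, 0, 0, rep(0, 20), 1)
  x2 <- c(1, 0, 1, 0, rep(c(0, 1), 10), 0)
  expect_true(assess_testability(x1, x2)$testable)
  expect_equal(assess_testability(x1, x2)$joint_exposed, 1)
})

test_that("the battery finds no structure under the null and the planted model otherwise", {
  set.seed(55)
  null_d <- make_two_snp_data(2000)
  bat <- fit_pair_battery(null_d$y, null_d$x1, null_d$x2)
  expect_false(bat$best_model %in% "M4" && bat$p_ab < 0.005)
  expect_true(all(is.finite(bat$bic[c("M1", "M2", "M3")])))

  add_d <- make_two_snp_data(5000, beta_a = 0.3, beta_b = 0.3)
  bat_add <- fit_pair_battery(add_d$y, add_d$x1, add_d$x2)
  expect_equal(bat_add$best_model, "M3")
  expect_lt(abs(bat_add$beta_a - 0.3), 0.06)

  int_d <- make_two_snp_data(5000, beta_a = 0.3, beta_b = 0.3, beta_ab = 0.3)
  bat_int <- fit_pair_battery(int_d$y, int_d$x1, int_d$x2)
  expect_equal(bat_int$best_model, "M4")
  expect_lt(abs(bat_int$beta_ab - 0.3), 3 * bat_int$se_ab)
  expect_equal(bat_int$p_source_model, "M4")
})

test_that("the two-step classifier reproduces the worked decisions", {
  # interaction significant and interaction model best -> GI
  expect_equal(classify_pair(1e-8, 1e-8, 0.001, "M4", TRUE), "GI")
  # interaction clearly null, both singles significant, additive model best -> AE
  expect_equal(classify_pair(1e-6, 1e-4, 0.5, "M3", TRUE), "AE")
  # the 0.005..0.01 band can satisfy neither branch
  expect_equal(classify_pair(1e-8, 1e-8, 0.007, "M4", TRUE), "none")
  expect_equal(classify_pair(1e-8, 1e-8, 0.007, "M3", TRUE), "none")
  # untestable pairs can still be AEs
  expect_equal(classify_pair(1e-6, 1e-6, NA, "M3", FALSE), "AE")
  # GI requires the interaction model to win
  expect_equal(classify_pair(1e-8, 1e-8, 0.001, "M3", TRUE), "none")
})

test_that("classification is a partition over every (pair, trait) unit", {
  set.seed(56)
  p <- function(n) runif(n)
  n <- 200
  cls <- classify_pair(p(n), p(n), ifelse(runif(n) < 0.2, NA, p(n)),
                       sample(c("M1", "M2", "M3", "M4"), n, TRUE),
                       sample(c(TRUE, FALSE), n, TRUE))
  expect_true(all(cls %in% c("GI", "AE", "none")))
  expect_length(cls, n)
})

test_that("a pairwise scan produces the full unit grid and one pooled family", {
  set.seed(57)
  cfg <- cohort_sim_config(n_samples = 600, genes = paste0("G0", 1:3),
                           carrier_freq = 0.2, seed = 57)
  sim <- simulate_cohort(cfg)
  res <- residualize_phenotypes(sim$cohort)
  burden <- encode_ptv_burden(sim$ptv_calls, sim$cohort$sample,
                              genes = cfg$genes)
  scan <- run_pairwise_scan(res, list(burden = burden), design = "PTV-PTV")
  expect_equal(nrow(scan), choose(3, 2) * 4)  # pairs x traits
  expect_lte(attr(scan, "family_size"), 3 * nrow(scan))
  expect_identical(names(scan)[1:2], c("pair", "trait"))
  expect_true(all(scan$p_ab_fdr >= scan$p_ab, na.rm = TRUE))
  expect_true(all(scan$classification %in% c("GI", "AE", "none")))
})

test_that("pair enumeration respects each design's rules", {
  genes <- paste0("G", 1:5)
  snps <- paste0("rs", 1:4)
  expect_equal(nrow(enumerate_pairs("PTV-PTV", genes = genes)), 10)
  expect_equal(nrow(enumerate_pairs("SNP-SNP", snps = snps)), 6)
  map <- data.frame(snp = c("rs1", "rs2"), gene = c("G1", "G2"))
  ps <- enumerate_pairs("PTV-SNP", genes = genes, snps = snps,
                        gene_snp_map = map)
  expect_equal(nrow(ps), 4 * 5 - 2)
  expect_false(any(ps$id1 == "rs1" & ps$id2 == "G1"))
  expect_equal(nrow(enumerate_pairs("PTV-PRS", genes = genes)), 5)
})

test_that("the SNP scan accepts a logistic disease trait in the same family", {
  set.seed(58)
  n <- 800
  samples <- sprintf("S%03d", 1:n)
  dos <- sapply(1:3, function(i) rbinom(n, 2, 0.3))
  dimnames(dos) <- list(samples, paste0("rs", 1:3))
  res <- list(LDLc = setNames(rnorm(n), samples))
  covs <- matrix(rnorm(n), n, 1, dimnames = list(samples, "age"))
  cad <- list(y = setNames(rbinom(n, 1, 0.2), samples), covariates = covs)
  scan <- run_pairwise_scan(res, list(dosage = dos), design = "SNP-SNP",
                            cad = cad)
  expect_setequal(unique(scan$trait), c("LDLc", "CAD"))
  expect_equal(nrow(scan), 3 * 2)
  expect_error(run_pairwise_scan(res, list(dosage = dos),
                                 design = "PTV-PTV", cad = cad))
})

test_that("conditioning on the driving variant abrogates the planted signal", {
  set.seed(59)
  n <- 3000
  samples <- sprintf("S%04d", 1:n)
  # gene GA: two variants; only v1 carries the effect
  carA_v1 <- rbinom(n, 1, 0.08)
  carA_v2 <- rbinom(n, 1, 0.04) * (1 - carA_v1)
  carB <- rbinom(n, 1, 0.1)
  calls <- rbind(
    data.frame(sample = samples[carA_v1 == 1], gene = "GA", variant = "v1"),
    data.frame(sample = samples[carA_v2 == 1], gene = "GA", variant = "v2"),
    data.frame(sample = samples[carB == 1], gene = "GB", variant = "w1"))
  y <- -2 * carA_v1 + rnorm(n)
  phen <- list(LDLc = setNames(y, samples))
  cond <- condition_on_variant(phen, calls, samples, "v1")
  row_b <- cond$before[cond$before$pair == "GA__GB", ]
  row_a <- cond$after[cond$after$pair == "GA__GB", ]
  expect_lt(row_b$p_a, 1e-6)      # burden signal present before
  expect_gt(row_a$p_a, 0.005)     # gone once v1 is excluded
  expect_error(condition_on_variant(phen, calls, samples, "absent"),
               "not present")
})

test_that("conditioning on a carrier-free variant changes nothing", {
  set.seed(60)
  n <- 500
  samples <- sprintf("S%03d", 1:n)
  calls <- data.frame(
    sample = samples[rbinom(n, 1, 0.1) == 1], gene = "GA", variant = "v1")
  calls <- rbind(calls, data.frame(
    sample = samples[rbinom(n, 1, 0.1) == 1], gene = "GB", variant = "w1"),
    data.frame(sample = samples[1], gene = "GC", variant = "dead"))
  phen <- list(LDLc = setNames(rnorm(n), samples))
  # "dead" has one carrier in gene GC only; GA/GB burdens are untouched
  cond <- condition_on_variant(phen, calls, samples, "dead")
  keep <- cond$before$pair == "GA__GB"
  expect_equal(cond$before$p_a[keep], cond$after$p_a[keep])
  # removing a variant drops exactly the samples whose only call it was
  b0 <- encode_ptv_burden(calls, samples)
  b1 <- encode_ptv_burden(calls, samples, exclude_variants = "dead")
  expect_equal(sum(b0) - sum(b1), 1)
})
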