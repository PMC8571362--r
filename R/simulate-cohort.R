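#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a biobank-style cohort: rare gene-disrupting
#' carriers (per-gene carrier frequency defaulting to 1e-2; population
#' carrier frequencies for truncating variants run ~1e-4..1e-2), common
#' biallelic dosages (default MAF 0.2, within the 0.03-0.35 range typical of
#' GWAS lead SNPs), covariate-confounded Gaussian lipid traits in mg/dl, and
#' a binary disease status from a logistic link. Planted single and pairwise
#' effects are specified in trait-SD units and converted through the trait's
#' noise SD, so planted and recovered effect sizes share a scale.
#'
#' Covariates: age ~ Uniform(40, 69) (a recruitment-window spread),
#' sex/smoking/alcohol/medication ~ Bernoulli, BMI ~ Normal(27, 4),
#' PC1..PC10 ~ Normal(0, 1). Their effects are removed by residualization, so
#' their exact distributions do not drive correctness.
#'
#' @param n_samples cohort size.
#' @param genes gene panel (names used for burden columns).
#' @param snps SNP panel.
#' @param carrier_freq per-gene carrier frequency (recycled).
#' @param maf per-SNP minor allele frequency (recycled).
#' @param variants_per_gene size of each gene's PTV pool; carriers draw one
#'   variant from a skewed frequency series, so a gene's burden can be
#'   dominated by its first variant (conditioning analyses need that).
#' @param traits trait names.
#' @param trait_mean,noise_sd per-trait location and residual SD, mg/dl
#'   (defaults: LDLc 138.3/33, HDLc 55/14, TG 150/80, TC 220/40; the LDLc
#'   location is the non-carrier mean the burden analyses are read against).
#' @param effects data frame of planted genetic effects with columns
#'   `predictor1`, `predictor2` (`NA` for single effects, `"PRS"` allowed),
#'   `trait`, `beta` (trait-SD units; interaction rows give `beta_ab`).
#' @param cad_prevalence baseline disease prevalence.
#' @param cad_effects like `effects` but `beta` in log-odds units, applied to
#'   the disease trait.
#' @param prs_weight_sd SD of the per-SNP score weights.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return config list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples = 5000,
                              genes = paste0("G", sprintf("%02d", 1:4)),
                              snps = paste0("rs", 1:4),
                              carrier_freq = 0.01,
                              maf = 0.2,
                              variants_per_gene = 4L,
                              traits = c("LDLc", "HDLc", "TG", "TC"),
                              trait_mean = c(LDLc = 138.3, HDLc = 55,
                                             TG = 150, TC = 220),
                              noise_sd = c(LDLc = 33, HDLc = 14,
                                           TG = 80, TC = 40),
                              effects = NULL,
                              cad_prevalence = 0.08,
                              cad_effects = NULL,
                              prs_weight_sd = 0.05,
                              seed = 1L) {
  stopifnot(n_samples >= 10, all(carrier_freq > 0 & carrier_freq < 0.5),
            all(maf > 0 & maf <= 0.5), all(noise_sd[traits] > 0))
  structure(list(
    n_samples = as.integer(n_samples), genes = genes, snps = snps,
    carrier_freq = rep_len(carrier_freq, length(genes)),
    maf = rep_len(maf, length(snps)),
    variants_per_gene = as.integer(variants_per_gene),
    traits = traits, trait_mean = trait_mean, noise_sd = noise_sd,
    effects = effects, cad_prevalence = cad_prevalence,
    cad_effects = cad_effects, prs_weight_sd = prs_weight_sd,
    seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

#' Simulate a cohort with planted pairwise genetic effects
#'
#' Draws covariates, rare carriers (Bernoulli per gene, with per-carrier
#' variant assignment), SNP dosages (Binomial(2, MAF)), polygenic-score
#' weights, quantitative traits (covariate signal + planted genetic effects +
#' Gaussian noise) and a binary disease trait (logistic link). All randomness
#' derives from `config$seed`; the global RNG state is restored on exit.
#'
#' A warning is raised for planted interactions whose expected double-carrier
#' count is below 1 (an underpowered design).
#'
#' @param config a [cohort_sim_config()].
#' @return list with `cohort` (phenotype/covariate table incl. `CAD`),
#'   `ptv_calls` (`sample`, `gene`, `variant`), `dosages` (matrix),
#'   `snp_info` (`snp`, `chrom`, `pos`), `prs_weights` (`snp`, `chrom`,
#'   `pos`, `weight`), `gene_regions` (`gene`, `chrom`, `start`, `end`),
#'   `truth` (planted `predictor1`, `predictor2`, `trait`, `beta`,
#'   `true_label`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  samples <- sprintf("S%06d", seq_len(n))

  cohort <- data.frame(
    sample = samples,
    age = stats::runif(n, 40, 69),
    sex = stats::rbinom(n, 1, 0.46),
    smoking = stats::rbinom(n, 1, 0.45),
    alcohol = stats::rbinom(n, 1, 0.9),
    bmi = stats::rnorm(n, 27, 4),
    lipid_medication = stats::rbinom(n, 1, 0.17),
    stringsAsFactors = FALSE)
  for (j in 1:10) cohort[[paste0("PC", j)]] <- stats::rnorm(n)

  # carriers and their variants; variant frequencies within a gene decay
  # geometrically so the first variant dominates the burden
  calls <- list()
  burden <- matrix(0, n, length(cfg$genes),
                   dimnames = list(samples, cfg$genes))
  for (gi in seq_along(cfg$genes)) {
    carrier <- stats::rbinom(n, 1, cfg$carrier_freq[gi]) == 1
    burden[carrier, gi] <- 1
    if (any(carrier)) {
      vfreq <- 0.5^(seq_len(cfg$variants_per_gene) - 1)
      v <- sample(cfg$variants_per_gene, sum(carrier), replace = TRUE,
                  prob = vfreq)
      calls[[cfg$genes[gi]]] <- data.frame(
        sample = samples[carrier], gene = cfg$genes[gi],
        variant = paste0(cfg$genes[gi], "_v", v), stringsAsFactors = FALSE)
    }
  }
  ptv_calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample = character(), gene = character(),
               variant = character())
  rownames(ptv_calls) <- NULL

  dosages <- sapply(cfg$maf, function(f) stats::rbinom(n, 2, f))
  dimnames(dosages) <- list(samples, cfg$snps)

  # one gene region per panel slot; SNP i sits inside gene i's region where
  # both exist, so score exclusion by region is exercised
  gene_regions <- data.frame(
    gene = cfg$genes, chrom = paste0("chr", seq_along(cfg$genes)),
    start = 1e6, end = 2e6, stringsAsFactors = FALSE)
  snp_info <- data.frame(
    snp = cfg$snps, chrom = paste0("chr", seq_along(cfg$snps)),
    pos = 1.5e6, stringsAsFactors = FALSE)
  prs_weights <- cbind(snp_info,
                       weight = stats::rnorm(length(cfg$snps), 0,
                                             cfg$prs_weight_sd))
  prs <- drop(dosages %*% prs_weights$weight)
  names(prs) <- samples

  predictor_value <- function(id) {
    if (identical(id, "PRS")) return(scale(prs)[, 1])
    if (id %in% cfg$genes) return(burden[, id])
    if (id %in% cfg$snps) return(dosages[, id])
    stop("unknown planted predictor: ", id)
  }

  covar_signal <- with(cohort, 0.3 * (age - 55) + 4 * sex - 3 * smoking +
                         0.8 * (bmi - 27) - 6 * lipid_medication +
                         1.5 * PC1)
  eff <- cfg$effects
  for (tr in cfg$traits) {
    sdt <- cfg$noise_sd[[tr]]
    mu <- cfg$trait_mean[[tr]] + covar_signal
    if (!is.null(eff)) {
      rows <- eff[eff$trait == tr, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        x1 <- predictor_value(rows$predictor1[r])
        if (is.na(rows$predictor2[r])) {
          mu <- mu + rows$beta[r] * sdt * x1
        } else {
          x2 <- predictor_value(rows$predictor2[r])
          mu <- mu + rows$beta[r] * sdt * x1 * x2
          nj <- n * mean(x1 > 0) * mean(x2 > 0)
          if (nj < 1)
            warning("planted interaction ", rows$predictor1[r], ":",
                    rows$predictor2[r], " expects < 1 double-exposed sample")
        }
      }
    }
    cohort[[tr]] <- pmax(mu + stats::rnorm(n, 0, sdt), 1)
  }

  logit <- stats::qlogis(cfg$cad_prevalence) +
    with(cohort, 0.05 * (age - 55) + 0.5 * sex + 0.4 * smoking +
           0.04 * (bmi - 27))
  ce <- cfg$cad_effects
  if (!is.null(ce)) {
    for (r in seq_len(nrow(ce))) {
      x1 <- predictor_value(ce$predictor1[r])
      if (is.na(ce$predictor2[r])) logit <- logit + ce$beta[r] * x1
      else logit <- logit +
          ce$beta[r] * x1 * predictor_value(ce$predictor2[r])
    }
  }
  cohort$CAD <- stats::rbinom(n, 1, stats::plogis(logit))

  truth <- sim_truth_table(eff, ce)
  list(cohort = cohort, ptv_calls = ptv_calls, dosages = dosages,
       snp_info = snp_info, prs_weights = prs_weights,
       gene_regions = gene_regions, truth = truth)
}

# planted-truth bookkeeping: a pair is GI-truth iff its interaction beta is
# nonzero; AE-truth iff the interaction is zero/absent but both members carry
# planted single effects on that trait
sim_truth_table <- function(effects, cad_effects = NULL) {
  eff <- rbind(
    if (!is.null(effects)) cbind(effects, trait_kind = "quantitative"),
    if (!is.null(cad_effects)) cbind(cad_effects, trait_kind = "binary",
                                     trait = "CAD"))
  if (is.null(eff) || nrow(eff) == 0L)
    return(data.frame(predictor1 = character(), predictor2 = character(),
                      trait = character(), beta = numeric(),
                      true_label = character()))
  singles <- eff[is.na(eff$predictor2), , drop = FALSE]
  eff$true_label <- ifelse(
    !is.na(eff$predictor2) & eff$beta != 0, "GI",
    ifelse(is.na(eff$predictor2), "single", "none"))
  pairs <- eff[!is.na(eff$predictor2), , drop = FALSE]
  if (nrow(pairs)) {
    has_single <- function(p, tr)
      any(singles$predictor1 == p & singles$trait == tr &
            singles$beta != 0)
    ae <- vapply(seq_len(nrow(pairs)), function(i) {
      pairs$beta[i] == 0 &&
        has_single(pairs$predictor1[i], pairs$trait[i]) &&
        has_single(pairs$predictor2[i], pairs$trait[i])
    }, logical(1))
    eff$true_label[!is.na(eff$predictor2)][ae] <- "AE"
  }
  eff[, c("predictor1", "predictor2", "trait", "beta", "true_label")]
}

# evaluate `expr` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
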