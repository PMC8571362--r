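#' Enumerate the (pair, predictor) design of a scan
#'
#' Pair enumeration rules per design:
#' * `PTV-PTV`: all unordered pairs of genes (burden x burden).
#' * `SNP-SNP`: all unordered pairs of lead SNPs (dosage x dosage).
#' * `PTV-SNP`: all (SNP, gene) combinations excluding a SNP paired with the
#'   burden of the gene(s) it is mapped to (`gene_snp_map`).
#' * `PTV-PRS`: one unit per gene (the gene's burden against the trait's
#'   gene-excluded polygenic score).
#'
#' @param design one of `"PTV-PTV"`, `"SNP-SNP"`, `"PTV-SNP"`, `"PTV-PRS"`.
#' @param genes character vector of gene ids.
#' @param snps character vector of SNP ids.
#' @param gene_snp_map data frame with columns `snp`, `gene`, required for
#'   `PTV-SNP`.
#' @return data frame with columns `id1`, `id2`, `pair` (canonical label,
#'   lexicographically sorted and `"__"`-joined for same-kind designs).
#' @export
enumerate_pairs <- function(design = c("PTV-PTV", "SNP-SNP", "PTV-SNP",
                                       "PTV-PRS"),
                            genes = NULL, snps = NULL, gene_snp_map = NULL) {
  design <- match.arg(design)
  pairs <- switch(design,
    "PTV-PTV" = {
      stopifnot(length(genes) >= 2L)
      m <- t(utils::combn(sort(genes), 2))
      data.frame(id1 = m[, 1], id2 = m[, 2], stringsAsFactors = FALSE)
    },
    "SNP-SNP" = {
      stopifnot(length(snps) >= 2L)
      m <- t(utils::combn(sort(snps), 2))
      data.frame(id1 = m[, 1], id2 = m[, 2], stringsAsFactors = FALSE)
    },
    "PTV-SNP" = {
      stopifnot(length(genes) >= 1L, length(snps) >= 1L,
                !is.null(gene_snp_map),
                all(c("snp", "gene") %in% names(gene_snp_map)))
      g <- expand.grid(id1 = sort(snps), id2 = sort(genes),
                       stringsAsFactors = FALSE)
      mapped <- paste(gene_snp_map$snp, gene_snp_map$gene, sep = "\r")
      g[!(paste(g$id1, g$id2, sep = "\r") %in% mapped), , drop = FALSE]
    },
    "PTV-PRS" = {
      stopifnot(length(genes) >= 1L)
      data.frame(id1 = sort(genes), id2 = "PRS", stringsAsFactors = FALSE)
    })
  pairs$pair <- paste(pairs$id1, pairs$id2, sep = "__")
  rownames(pairs) <- NULL
  pairs
}

#' Canonical gene-pair label
#'
#' Lexicographically sorted ids joined by `"__"`, so `(A, B)` and `(B, A)`
#' share one label.
#' @param a,b character vectors of ids.
#' @return character vector of labels.
#' @export
canonical_pair <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "__"), paste(b, a, sep = "__"))
}

#' Run a pairwise genetic-effect scan
#'
#' Fits the four-model battery ([fit_pair_battery()]) for every (pair, trait)
#' unit of a design, pools the three per-unit p-values (both single terms and
#' the interaction) into one Benjamini-Hochberg family across all traits of
#' the design - never across designs - and applies the two-step GI/AE
#' classification ([classify_pair()]). Inestimable p-values stay missing and
#' do not count toward the family size.
#'
#' @param phenotypes named list of residualized trait vectors (names = sample
#'   ids), e.g. the `$residuals` of [residualize_phenotypes()], or the object
#'   itself.
#' @param predictors list of predictor inputs, by design:
#'   `PTV-PTV`: `burden` (samples x genes matrix);
#'   `SNP-SNP`: `dosage` (samples x SNPs matrix);
#'   `PTV-SNP`: `burden`, `dosage`, `gene_snp_map`;
#'   `PTV-PRS`: `burden`, `prs` = per-trait list of either one score vector or
#'   a samples x genes matrix of gene-excluded scores.
#' @param design scan design, see [enumerate_pairs()].
#' @param traits trait names to scan (default: all in `phenotypes`).
#' @param cad optional (SNP-SNP only) list with `y` (named 0/1 vector) and
#'   `covariates` (samples x covariates matrix); scanned as the extra trait
#'   `"CAD"` with the logistic battery, pooled into the same FDR family.
#' @param min_joint testability threshold.
#' @param alpha_gi,alpha_excl,alpha_single classification thresholds.
#' @param ... passed to the model fitters.
#' @return data frame with one row per (pair, trait) unit and the fixed
#'   column order `pair, trait, bic_m1..bic_m4, best_model, delta_bic,
#'   beta_a, beta_b, beta_ab, p_a, p_b, p_ab, p_a_fdr, p_b_fdr, p_ab_fdr,
#'   testable, n, n_joint, classification`; attribute `summary` holds the
#'   per-trait AE/GI counts and attribute `family_size` the FDR family size m.
#' @export
run_pairwise_scan <- function(phenotypes, predictors,
                              design = c("PTV-PTV", "SNP-SNP", "PTV-SNP",
                                         "PTV-PRS"),
                              traits = NULL, cad = NULL, min_joint = 1L,
                              alpha_gi = 0.005, alpha_excl = 0.01,
                              alpha_single = 0.005, ...) {
  design <- match.arg(design)
  if (inherits(phenotypes, "residual_phenotypes"))
    phenotypes <- phenotypes$residuals
  if (is.null(traits)) traits <- names(phenotypes)
  if (!is.null(cad) && design != "SNP-SNP")
    stop("the logistic battery for disease status is part of the SNP-SNP design")

  pairs <- switch(design,
    "PTV-PTV" = enumerate_pairs(design, genes = colnames(predictors$burden)),
    "SNP-SNP" = enumerate_pairs(design, snps = colnames(predictors$dosage)),
    "PTV-SNP" = enumerate_pairs(design, genes = colnames(predictors$burden),
                                snps = colnames(predictors$dosage),
                                gene_snp_map = predictors$gene_snp_map),
    "PTV-PRS" = enumerate_pairs(design, genes = colnames(predictors$burden)))
  if (nrow(pairs) == 0L) stop("empty pair list for design ", design)

  get_xy <- function(trait, id1, id2) {
    y <- phenotypes[[trait]]
    x1 <- switch(design,
      "PTV-PTV" = predictors$burden[, id1],
      "SNP-SNP" = predictors$dosage[, id1],
      "PTV-SNP" = predictors$dosage[, id1],
      "PTV-PRS" = {
        p <- predictors$prs[[trait]]
        if (is.matrix(p)) p[, id1] else p
      })
    x2 <- switch(design,
      "PTV-PTV" = predictors$burden[, id2],
      "SNP-SNP" = predictors$dosage[, id2],
      "PTV-SNP" = predictors$burden[, id2],
      "PTV-PRS" = predictors$burden[, id1])
    ids <- Reduce(intersect, list(names(y), names(x1), names(x2)))
    list(y = y[ids], x1 = x1[ids], x2 = x2[ids])
  }

  rows <- list()
  for (trait in traits) {
    for (i in seq_len(nrow(pairs))) {
      d <- get_xy(trait, pairs$id1[i], pairs$id2[i])
      bat <- fit_pair_battery(d$y, d$x1, d$x2, family = "gaussian",
                              min_joint = min_joint, ...)
      rows[[length(rows) + 1L]] <- battery_row(pairs$pair[i], trait, bat)
    }
  }
  if (!is.null(cad)) {
    ids <- intersect(names(cad$y), rownames(predictors$dosage))
    covs <- cad$covariates[ids, , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      x1 <- predictors$dosage[ids, pairs$id1[i]]
      x2 <- predictors$dosage[ids, pairs$id2[i]]
      bat <- fit_pair_battery(cad$y[ids], x1, x2, family = "binomial",
                              covariates = covs, min_joint = min_joint, ...)
      rows[[length(rows) + 1L]] <- battery_row(pairs$pair[i], "CAD", bat)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  # one FDR family for the whole design: 3 slots per unit, NAs excluded
  fam <- c(out$p_a, out$p_b, out$p_ab)
  adj <- bh_fdr(fam)
  nu <- nrow(out)
  out$p_a_fdr <- adj[seq_len(nu)]
  out$p_b_fdr <- adj[nu + seq_len(nu)]
  out$p_ab_fdr <- adj[2 * nu + seq_len(nu)]
  out$classification <- classify_pair(out$p_a_fdr, out$p_b_fdr, out$p_ab_fdr,
                                      out$best_model, out$testable,
                                      alpha_gi, alpha_excl, alpha_single)
  out <- out[, c("pair", "trait", "bic_m1", "bic_m2", "bic_m3", "bic_m4",
                 "best_model", "delta_bic", "beta_a", "beta_b", "beta_ab",
                 "p_a", "p_b", "p_ab", "p_a_fdr", "p_b_fdr", "p_ab_fdr",
                 "testable", "n", "n_joint", "classification")]
  attr(out, "family_size") <- sum(!is.na(fam))
  attr(out, "summary") <- as.data.frame.matrix(
    table(out$trait, factor(out$classification, c("AE", "GI", "none"))))
  out
}

battery_row <- function(pair, trait, bat) {
  data.frame(
    pair = pair, trait = trait,
    bic_m1 = bat$bic[["M1"]], bic_m2 = bat$bic[["M2"]],
    bic_m3 = bat$bic[["M3"]], bic_m4 = bat$bic[["M4"]],
    best_model = if (is.na(bat$best_model)) NA_character_ else bat$best_model,
    delta_bic = bat$delta_bic,
    beta_a = bat$beta_a, beta_b = bat$beta_b, beta_ab = bat$beta_ab,
    p_a = bat$p_a, p_b = bat$p_b, p_ab = bat$p_ab,
    testable = bat$testable, n = bat$n, n_joint = bat$n_joint,
    stringsAsFactors = FALSE)
}

#' Re-run a burden scan with one variant removed (conditioning)
#'
#' Sensitivity analysis for a burden signal dominated by a single variant:
#' the scan is re-run with that variant excluded from the burden encoding and
#' the before/after classifications and p-values are reported side by side.
#' If no remaining signal survives, the original association was carried by
#' the conditioned variant.
#'
#' @param phenotypes as in [run_pairwise_scan()].
#' @param ptv_calls data frame `sample`, `gene`, `variant`.
#' @param samples character vector of sample ids for the burden encoding.
#' @param variant the variant id to remove; must be present in `ptv_calls`.
#' @param genes optional gene set for the burden matrix.
#' @param mode burden encoding mode.
#' @param ... passed to [run_pairwise_scan()].
#' @return list with `before` and `after` scan tables and `comparison`, a
#'   merged per-unit table of classifications and interaction p-values.
#' @export
condition_on_variant <- function(phenotypes, ptv_calls, samples, variant,
                                 genes = NULL, mode = "indicator", ...) {
  if (!variant %in% ptv_calls$variant)
    stop("variant ", variant, " not present in the PTV calls")
  b0 <- encode_ptv_burden(ptv_calls, samples, genes = genes, mode = mode)
  b1 <- encode_ptv_burden(ptv_calls, samples, genes = genes, mode = mode,
                          exclude_variants = variant)
  before <- run_pairwise_scan(phenotypes, list(burden = b0),
                              design = "PTV-PTV", ...)
  after <- run_pairwise_scan(phenotypes, list(burden = b1),
                             design = "PTV-PTV", ...)
  cols <- c("pair", "trait", "classification", "p_ab_fdr", "p_a_fdr",
            "p_b_fdr", "n_joint")
  cmp <- merge(before[, cols], after[, cols], by = c("pair", "trait"),
               suffixes = c("_before", "_after"), sort = TRUE)
  list(before = before, after = after, comparison = cmp, variant = variant)
}
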