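#' Fit the four-model battery for one predictor pair
#'
#' Fits, for a residualized quantitative trait (robust Gaussian family) or a
#' binary trait (logistic family with covariates inside the model):
#'
#' * M1: `y ~ x1`
#' * M2: `y ~ x2`
#' * M3: `y ~ x1 + x2` (the additive model)
#' * M4: `y ~ x1 + x2 + x1:x2` (the interaction model)
#'
#' each with intercept. The interaction model is skipped when the pair is
#' untestable (no double-exposed samples, or a collinear product column). The
#' best model is the BIC minimum over the fitted battery; single-term p-values
#' are read from the BIC-selected full model (M4 if selected, otherwise M3),
#' while the interaction p-value can only come from M4.
#'
#' @param y numeric response (residualized trait, or 0/1 disease status).
#' @param x1,x2 aligned predictor vectors (burden indicator, dosage, or score).
#' @param family `"gaussian"` (robust) or `"binomial"`.
#' @param covariates optional matrix/data frame of covariate columns included
#'   in every model (used for the binomial family, where the outcome is not
#'   residualized).
#' @param min_joint testability threshold, see [assess_testability()].
#' @param ... passed to [huber_irls_fit()] / [logistic_fit()].
#' @return list of class `pair_fit` with per-model BICs, `best_model`,
#'   `delta_bic`, effect estimates and p-values for both single terms and the
#'   interaction, `testable`, `n`, `n_joint`, `p_source_model`, `fits`.
#' @export
fit_pair_battery <- function(y, x1, x2, family = c("gaussian", "binomial"),
                             covariates = NULL, min_joint = 1L, ...) {
  family <- match.arg(family)
  stopifnot(length(y) == length(x1), length(y) == length(x2))
  test <- assess_testability(x1, x2, min_joint = min_joint)

  base <- if (is.null(covariates)) NULL else as.matrix(covariates)
  design <- function(cols) {
    m <- do.call(cbind, cols)
    if (!is.null(base)) cbind(m, base) else m
  }
  fitter <- if (family == "gaussian") {
    function(X) huber_irls_fit(y, X, ...)
  } else {
    function(X) logistic_fit(y, X, ...)
  }

  fits <- list(
    M1 = fitter(design(list(x1 = x1))),
    M2 = fitter(design(list(x2 = x2))),
    M3 = fitter(design(list(x1 = x1, x2 = x2)))
  )
  if (test$testable) {
    fits$M4 <- fitter(design(list(x1 = x1, x2 = x2, `x1:x2` = x1 * x2)))
  }
  cmp <- compare_models(fits)

  get_p <- function(fit, term, what = "p") {
    if (is.null(fit)) return(NA_real_)
    tab <- fit$coefficients
    i <- match(term, tab$term)
    if (is.na(i)) NA_real_ else tab[[what]][i]
  }
  p_source <- if (identical(cmp$best_model, "M4")) "M4" else "M3"
  src <- fits[[p_source]]

  structure(list(
    bic = vapply(c("M1", "M2", "M3", "M4"),
                 function(m) if (is.null(fits[[m]])) NA_real_ else fits[[m]]$bic,
                 numeric(1)),
    best_model = cmp$best_model,
    delta_bic = cmp$delta_bic,
    available = cmp$available,
    beta_a = get_p(src, "x1", "estimate"),
    beta_b = get_p(src, "x2", "estimate"),
    beta_ab = get_p(fits$M4, "x1:x2", "estimate"),
    se_ab = get_p(fits$M4, "x1:x2", "se"),
    p_a = get_p(src, "x1"),
    p_b = get_p(src, "x2"),
    p_ab = get_p(fits$M4, "x1:x2"),
    testable = test$testable,
    n = length(y),
    n_joint = test$joint_exposed,
    p_source_model = p_source,
    fits = fits
  ), class = "pair_fit")
}

#' Two-step classification of a (pair, trait) unit
#'
#' Applies the two-step decision rule on family-wide FDR-adjusted p-values:
#'
#' * **GI** (genetic interaction): interaction `p_fdr < alpha_gi` *and* the
#'   interaction model (M4) is the BIC-best model.
#' * **AE** (additive effect): interaction `p_fdr > alpha_excl` *or* the pair
#'   is untestable, *and* both single-term `p_fdr < alpha_single`, *and* the
#'   additive model (M3) is BIC-best.
#' * otherwise **none**. Interaction p-values falling in the band
#'   `[alpha_gi, alpha_excl]` can satisfy neither branch, by construction.
#'
#' All arguments are vectorized over units.
#'
#' @param p_a_fdr,p_b_fdr,p_ab_fdr FDR-adjusted p-values for the two single
#'   terms and the interaction term (`NA` where inestimable).
#' @param best_model character, `"M1"`..`"M4"`.
#' @param testable logical.
#' @param alpha_gi,alpha_excl,alpha_single decision thresholds.
#' @return character vector in `{"GI", "AE", "none"}`.
#' @export
classify_pair <- function(p_a_fdr, p_b_fdr, p_ab_fdr, best_model, testable,
                          alpha_gi = 0.005, alpha_excl = 0.01,
                          alpha_single = 0.005) {
  n <- length(p_ab_fdr)
  best_model <- rep_len(as.character(best_model), n)
  testable <- rep_len(testable, n)
  gi <- !is.na(p_ab_fdr) & p_ab_fdr < alpha_gi & best_model %in% "M4"
  excl <- !testable | is.na(p_ab_fdr) | p_ab_fdr > alpha_excl
  ae <- excl & best_model %in% "M3" &
    !is.na(p_a_fdr) & p_a_fdr < alpha_single &
    !is.na(p_b_fdr) & p_b_fdr < alpha_single
  out <- rep("none", n)
  out[ae] <- "AE"
  out[gi] <- "GI"  # GI and AE cannot co-fire (different best models)
  out
}
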