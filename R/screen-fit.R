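#' Fit the five-model interaction battery for one siRNA pair
#'
#' The response is the concatenated replicate-level robust Z-scores of the two
#' single knockdowns, the double knockdown, and the negative controls (the
#' controls anchor the baseline, so the intercept stays near 0). Indicator
#' predictors `x_A`, `x_B` are 1 wherever that siRNA is present. The battery
#'
#' * M0: `z ~ 1`
#' * M1: `z ~ x_A`
#' * M2: `z ~ x_B`
#' * M3: `z ~ x_A + x_B` (additive)
#' * M4: `z ~ x_A + x_B + x_A:x_B` (interaction)
#'
#' is fitted by [huber_irls_fit()] and compared by pseudo-BIC. The coefficient
#' of the product term is the **Interaction Value**: the difference between
#' the observed double-knockdown score and the additive expectation
#' (`beta_AB = y_AB - beta_0 - beta_A - beta_B`). Evidence is `"strong"` when
#' the BIC gap to the runner-up exceeds 2 (the conventional positive-evidence
#' threshold), else `"ambiguous"`.
#'
#' @param z_a,z_b replicate z-scores for the single knockdowns of genes A, B.
#' @param z_ab replicate z-scores for the double knockdown.
#' @param z_ctrl replicate z-scores for the negative controls.
#' @param min_replicates minimum replicates required per treatment group.
#' @param ... passed to [huber_irls_fit()].
#' @return list of class `screen_fit`: `beta0`, `beta_a`, `beta_b`,
#'   `beta_ab` (= `interaction_value`) with `se`/`t`/`p` per term, per-model
#'   `bic` (M0..M4), `best_model`, `delta_bic`, `evidence`, `estimable`,
#'   `n`, `tau` (standard error of the joint-cell mean, the default taxonomy
#'   tolerance), `fits`.
#' @export
fit_screen_models <- function(z_a, z_b, z_ab, z_ctrl, min_replicates = 3L,
                              ...) {
  groups <- list(A = z_a, B = z_b, AB = z_ab, CTRL = z_ctrl)
  sizes <- lengths(groups)
  if (any(sizes < min_replicates)) {
    return(structure(list(estimable = FALSE, n = sum(sizes),
                          missing = names(groups)[sizes < min_replicates]),
                     class = "screen_fit"))
  }
  y <- unlist(groups, use.names = FALSE)
  xA <- rep(c(1, 0, 1, 0), sizes)
  xB <- rep(c(0, 1, 1, 0), sizes)

  fits <- list(
    M0 = huber_irls_fit(y, NULL, ...),
    M1 = huber_irls_fit(y, cbind(x_A = xA), ...),
    M2 = huber_irls_fit(y, cbind(x_B = xB), ...),
    M3 = huber_irls_fit(y, cbind(x_A = xA, x_B = xB), ...),
    M4 = huber_irls_fit(y, cbind(x_A = xA, x_B = xB, `x_A:x_B` = xA * xB), ...)
  )
  cmp <- compare_models(fits)
  tab <- fits$M4$coefficients
  pick <- function(term, what) {
    i <- match(term, tab$term)
    tab[[what]][i]
  }
  structure(list(
    estimable = TRUE,
    beta0 = pick("(Intercept)", "estimate"),
    beta_a = pick("x_A", "estimate"),
    beta_b = pick("x_B", "estimate"),
    beta_ab = pick("x_A:x_B", "estimate"),
    interaction_value = pick("x_A:x_B", "estimate"),
    se_a = pick("x_A", "se"), se_b = pick("x_B", "se"),
    se_ab = pick("x_A:x_B", "se"),
    p_a = pick("x_A", "p"), p_b = pick("x_B", "p"),
    p_ab = pick("x_A:x_B", "p"),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    best_model = cmp$best_model,
    delta_bic = cmp$delta_bic,
    evidence = if (isTRUE(cmp$delta_bic > 2)) "strong" else "ambiguous",
    n = length(y),
    tau = stats::sd(z_ab) / sqrt(length(z_ab)),
    fits = fits
  ), class = "screen_fit")
}

#' Classify a significant genetic interaction into the GI taxonomy
#'
#' Labels the interaction by comparing the joint phenotype
#' `J = beta0 + beta_A + beta_B + beta_AB` with the additive expectation
#' `E = beta0 + beta_A + beta_B` and the most severe single effect `M` (the
#' single-knockdown coefficient of larger magnitude). Severity is deviation
#' from control in the direction of the dominant single effect,
#' `s(x) = x * sign(M)`:
#'
#' * **negative-aggravating** (synergistic): `s(J) > max(s(E), s(M)) + tau`,
#'   the joint effect exceeds the additive expectation.
#' * **positive-suppressive**: `s(J) < s(M) - tau`, the joint phenotype is
#'   less severe ("healthier") than the most severe single.
#' * **positive-alleviating** otherwise: the joint effect is approximately
#'   equal to (or partially masked toward) the most severe single phenotype.
#' * **emergent**: both singles within `tau` of 0 (no dominant direction);
#'   reported separately.
#'
#' The tolerance `tau` defaults to the standard error of the joint-cell mean
#' ([fit_screen_models()]'s `tau`).
#'
#' @param fit a `screen_fit`, or `NULL` if the betas are given directly.
#' @param tau numeric tolerance, in robust-Z units.
#' @param beta0,beta_a,beta_b,beta_ab direct coefficients (override `fit`).
#' @return one of `"negative-aggravating"`, `"positive-alleviating"`,
#'   `"positive-suppressive"`, `"emergent"`.
#' @export
classify_gi_type <- function(fit = NULL, tau = NULL, beta0 = NULL,
                             beta_a = NULL, beta_b = NULL, beta_ab = NULL) {
  if (!is.null(fit)) {
    if (is.null(beta0)) beta0 <- fit$beta0
    if (is.null(beta_a)) beta_a <- fit$beta_a
    if (is.null(beta_b)) beta_b <- fit$beta_b
    if (is.null(beta_ab)) beta_ab <- fit$beta_ab
    if (is.null(tau)) tau <- fit$tau
  }
  stopifnot(!is.null(tau), !is.null(beta_a), !is.null(beta_b),
            !is.null(beta_ab))
  if (is.null(beta0)) beta0 <- 0
  if (abs(beta_a) <= tau && abs(beta_b) <= tau) return("emergent")
  M <- if (abs(beta_a) >= abs(beta_b)) beta_a else beta_b
  s <- function(x) x * sign(M)
  J <- beta0 + beta_a + beta_b + beta_ab
  E <- beta0 + beta_a + beta_b
  if (s(J) > max(s(E), s(M)) + tau) return("negative-aggravating")
  if (s(J) < s(M) - tau) return("positive-suppressive")
  "positive-alleviating"
}
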