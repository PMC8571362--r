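#' Logistic regression fit for a binary trait
#'
#' Maximum-likelihood logistic regression via [stats::glm()], returned in the
#' same `pairscan_fit` shape as [huber_irls_fit()] so the model battery and
#' BIC comparison treat both families uniformly. Wald z-statistics take the
#' place of t-values and are converted to p-values with the same normal rule.
#'
#' Complete (or quasi-complete) separation is detected from the fitted
#' probabilities degenerating to 0/1; the fit is flagged `separated` and the
#' affected coefficients are reported as inestimable (`NA`).
#'
#' @inheritParams huber_irls_fit
#' @param y binary response in `{0, 1}`; both classes must be present.
#' @param max_iter,tol passed to the IRLS control of `glm`.
#' @return A `pairscan_fit` with `family = "binomial"` and an extra
#'   `separated` flag. `bic = -2*loglik + k*log(n)`.
#' @export
logistic_fit <- function(y, x = NULL, max_iter = 50L, tol = 1e-10) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be 0/1")
  if (length(unique(y)) < 2L) stop("single-class response: both classes required")
  n <- length(y)
  X <- build_design(x, n)

  sep_warn <- FALSE
  g <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })

  aliased <- is.na(g$coefficients)
  k <- sum(!aliased)
  est <- g$coefficients
  # Wald covariance from the final IRLS weights
  Xe <- X[, !aliased, drop = FALSE]
  W <- g$weights
  XtWXinv <- tryCatch(chol2inv(chol(crossprod(Xe * sqrt(W)))),
                      error = function(e) matrix(NA_real_, k, k))
  se <- rep(NA_real_, ncol(X))
  se[!aliased] <- sqrt(pmax(diag(XtWXinv), 0))

  separated <- sep_warn || any(se > 50, na.rm = TRUE)
  if (separated) {
    bad <- !is.na(se) & (se > 50 | abs(est) > 15)
    est[bad] <- NA_real_
    se[bad] <- NA_real_
  }
  z <- est / se
  z[!is.finite(z)] <- NA_real_

  mu <- g$fitted.values
  loglik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  fit <- structure(list(
    coefficients = data.frame(
      term = colnames(X), estimate = est, se = se, t = z,
      p = pval_from_t(z), stringsAsFactors = FALSE),
    scale = NA_real_,
    weights = g$weights,
    residuals = y - mu,
    fitted = mu,
    n = n, k = k,
    loglik = loglik,
    converged = g$converged && !separated,
    separated = separated,
    iterations = g$iter,
    family = "binomial",
    inestimable = c(colnames(X)[aliased],
                    colnames(X)[!aliased & is.na(est)])
  ), class = "pairscan_fit")
  fit$bic <- model_bic(fit)
  fit
}
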