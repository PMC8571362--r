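#' Robust linear regression by Huber IRLS
#'
#' Fits `y ~ 1 + x` by M-estimation with the Huber psi function, using
#' iteratively reweighted least squares. The residual scale is re-estimated at
#' every iteration as the scaled median absolute residual
#' (`1.4826 * median(|r|)`, floored at `scale_floor`), so the estimator is the
#' usual 95%-Gaussian-efficiency Huber regression when `tuning = 1.345`.
#'
#' Coefficient standard errors use the weighted least-squares covariance at the
#' optimum, `s^2 (X'WX)^{-1}` with `s^2 = sum(w r^2)/(n - k)`; this reduces
#' exactly to the ordinary least-squares covariance when no observation is
#' downweighted. t-statistics are referred to the standard normal via
#' [pval_from_t()].
#'
#' Rank-deficient designs do not error: aliased columns are reported with `NA`
#' estimates and flagged in `$inestimable`. Non-convergence returns the last
#' iterate with `converged = FALSE` and a warning.
#'
#' @param y numeric response vector (no missing values).
#' @param x predictor matrix or data frame (one column per term, no
#'   intercept column); `NULL` or zero columns fits the intercept-only model.
#' @param tuning Huber tuning constant, in units of the robust scale.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the maximum absolute coefficient change.
#' @param scale_floor lower bound for the robust scale, guarding `log(0)` in
#'   the information criterion for (near-)noiseless fits.
#' @return An object of class `pairscan_fit`: a list with `coefficients`
#'   (data frame of term/estimate/se/t/p), `scale`, `weights`, `residuals`,
#'   `n`, `k`, `sigma2_w` (Huber-weighted mean squared residual), `bic`,
#'   `converged`, `iterations`, `family = "gaussian-robust"`, `inestimable`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50)
#' fit <- huber_irls_fit(2 + 0.5 * x + rnorm(50), cbind(x = x))
#' coef_table(fit)
#' @export
huber_irls_fit <- function(y, x = NULL, tuning = 1.345, max_iter = 50L,
                           tol = 1e-8, scale_floor = 1e-10) {
  y <- as.numeric(y)
  n <- length(y)
  X <- build_design(x, n)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(y) || anyNA(X)) stop("missing values are not allowed in the fit")
  k_full <- ncol(X)
  qrX <- qr(X)
  aliased <- rep(FALSE, k_full)
  if (qrX$rank < k_full) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased[-keep] <- TRUE
  }
  Xe <- X[, !aliased, drop = FALSE]
  k <- ncol(Xe)
  if (n <= k) stop("underdetermined: n <= number of estimable coefficients")

  beta <- qr.coef(qr(Xe), y)
  converged <- FALSE
  iter <- 0L
  w <- rep(1, n)
  sigma <- scale_floor
  # two-phase scheme: the scale is re-estimated from the current residuals
  # for the first iterations, then frozen; at fixed scale the Huber problem
  # is convex and IRLS converges monotonically (no MAD limit cycles)
  freeze_after <- max(10L, max_iter %/% 2L)
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - drop(Xe %*% beta)
    if (iter <= freeze_after)
      sigma <- max(1.4826 * stats::median(abs(r)), scale_floor)
    w <- pmin(1, tuning * sigma / abs(r))
    w[!is.finite(w)] <- 1  # zero residuals get full weight
    wfit <- stats::lm.wfit(Xe, y, w)
    delta <- max(abs(wfit$coefficients - beta))
    beta <- wfit$coefficients
    if (is.finite(delta) && delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("huber_irls_fit did not converge in ", max_iter, " iterations")
  }
  r <- y - drop(Xe %*% beta)
  sigma <- max(1.4826 * stats::median(abs(r)), scale_floor)
  w <- pmin(1, tuning * sigma / abs(r))
  w[!is.finite(w)] <- 1

  # WLS covariance at the optimum
  sw <- sqrt(w)
  qrw <- qr(Xe * sw)
  Rinv <- backsolve(qr.R(qrw), diag(ncol(Xe)))
  unpiv <- order(qrw$pivot)
  XtWXinv <- tcrossprod(Rinv)[unpiv, unpiv, drop = FALSE]
  s2 <- sum(w * r^2) / (n - k)
  se <- sqrt(pmax(diag(XtWXinv) * s2, 0))

  est <- se_full <- rep(NA_real_, k_full)
  est[!aliased] <- beta
  se_full[!aliased] <- se
  tval <- est / se_full
  tval[!is.finite(tval)] <- NA_real_

  sigma2_w <- max(sum(w * r^2) / sum(w), scale_floor^2)
  sigma2 <- max(mean(r^2), scale_floor^2)
  fit <- structure(list(
    coefficients = data.frame(
      term = colnames(X), estimate = est, se = se_full, t = tval,
      p = pval_from_t(tval), stringsAsFactors = FALSE),
    scale = sigma,
    weights = w,
    residuals = r,
    fitted = y - r,
    n = n, k = k,
    sigma2 = sigma2,
    sigma2_w = sigma2_w,
    converged = converged,
    iterations = iter,
    family = "gaussian-robust",
    inestimable = colnames(X)[aliased]
  ), class = "pairscan_fit")
  fit$bic <- model_bic(fit)
  fit
}

# Assemble [intercept | predictors]; accepts NULL, vector, matrix, data.frame.
build_design <- function(x, n) {
  if (is.null(x)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  if (nrow(x) != n) stop("predictors and response have different lengths")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("term names must be unique")
  storage.mode(x) <- "double"
  cbind(`(Intercept)` = 1, x)
}

#' Coefficient table of a fit
#'
#' @param fit a `pairscan_fit` object.
#' @return data frame with columns term, estimate, se, t, p.
#' @export
coef_table <- function(fit) fit$coefficients

#' @export
print.pairscan_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, k = %d, BIC = %.3f, converged = %s (%d it.)\n",
              x$family, x$n, x$k, x$bic, x$converged, x$iterations))
  print(x$coefficients, row.names = FALSE)
  if (length(x$inestimable))
    cat("inestimable terms:", paste(x$inestimable, collapse = ", "), "\n")
  invisible(x)
}
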