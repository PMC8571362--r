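#' Schwarz information criterion for a fitted model
#'
#' For binomial fits, the textbook `BIC = -2*loglik + k*log(n)`.
#'
#' For Huber-robust fits there is no canonical likelihood; the pseudo-BIC
#' used here evaluates the Gaussian profile criterion at the robust
#' coefficient estimates, `n*log(sigma2) + (k + 1)*log(n)`, where the `+1`
#' charges the estimated scale. By default `sigma2` is the plain mean squared
#' residual at the robust coefficients: selection differences then follow
#' the familiar chi-square calibration against the `log(n)` penalty, which
#' keeps small-replicate model choice honest. `variance = "huber-weighted"`
#' instead uses `sum(w r^2)/sum(w)` (the Huber-weighted mean square); its
#' weights re-adapt to each model's residuals, which behaves like extra free
#' parameters at small n and over-selects the larger model, so it is not the
#' default. Both reduce exactly to the textbook Gaussian
#' `n*log(RSS/n) + (k + 1)*log(n)` when no observation is downweighted.
#' `sigma2` is floored (see [huber_irls_fit()]'s `scale_floor`) so saturated
#' noiseless fits stay finite.
#'
#' @param fit a `pairscan_fit`.
#' @param variance which residual variance enters the Gaussian criterion for
#'   robust fits: `"unweighted"` (default) or `"huber-weighted"`.
#' @return the (pseudo-)BIC, a finite scalar for converged fits.
#' @export
model_bic <- function(fit, variance = c("unweighted", "huber-weighted")) {
  if (fit$n <= fit$k) stop("underdetermined: n <= k")
  if (identical(fit$family, "binomial")) {
    -2 * fit$loglik + fit$k * log(fit$n)
  } else {
    variance <- match.arg(variance)
    s2 <- if (variance == "unweighted") fit$sigma2 else fit$sigma2_w
    fit$n * log(s2) + (fit$k + 1) * log(fit$n)
  }
}

#' Two-sided normal p-value from a t- (or z-) statistic
#'
#' The normal-approximation rule `p = 2 - 2*pnorm(|t|)`: symmetric in the sign
#' of `t`, equal to 1 at `t = 0`, and strictly decreasing in `|t|`.
#' Non-finite statistics propagate as `NA` (inestimable terms).
#'
#' @param t numeric vector of statistics.
#' @return p-values in `[0, 1]`, `NA` where `t` is not finite.
#' @export
pval_from_t <- function(t) {
  p <- 2 - 2 * stats::pnorm(abs(t))
  p[!is.finite(t)] <- NA_real_
  p
}

#' Benjamini-Hochberg adjustment over a family with missing entries
#'
#' Step-up FDR adjustment of the non-missing p-values; missing entries (the
#' inestimable interaction terms of untestable pairs) stay missing and do not
#' count toward the family size m. Delegates the step-up itself to
#' [stats::p.adjust()] on the non-missing subset.
#'
#' @param pvals numeric vector of raw p-values, `NA` allowed.
#' @return adjusted p-values, same length and `NA` pattern as the input.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Select the best-fitting model by BIC
#'
#' Ranks converged fits by (pseudo-)BIC; the lowest wins. Exact ties are broken
#' toward the model with fewer estimated coefficients (parsimony), then by
#' model id, so selection is deterministic. `delta_bic` is the gap from the
#' best to the second-best model (the Raftery evidence statistic; > 2 is
#' conventionally read as positive evidence).
#'
#' @param fits named list of `pairscan_fit` objects; names are the model ids.
#' @return list with `bics` (data frame model/bic/k/converged ordered as
#'   given), `best_model`, `delta_bic`, `available`. When no fit converged,
#'   `available = FALSE` and the selection fields are `NA`.
#' @examples
#' # ties go to the smaller model:
#' # compare_models(list(M3 = fit3, M4 = fit4))
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L, !is.null(names(fits)))
  tab <- data.frame(
    model = names(fits),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    stringsAsFactors = FALSE)
  usable <- tab[tab$converged & is.finite(tab$bic), , drop = FALSE]
  if (nrow(usable) == 0L) {
    return(list(bics = tab, best_model = NA_character_,
                delta_bic = NA_real_, available = FALSE))
  }
  ord <- order(usable$bic, usable$k, usable$model)
  usable <- usable[ord, , drop = FALSE]
  delta <- if (nrow(usable) >= 2L) usable$bic[2] - usable$bic[1] else Inf
  list(bics = tab, best_model = usable$model[1],
       delta_bic = delta, available = TRUE)
}
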