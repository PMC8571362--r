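#' Scan all siRNA pairs of a screen
#'
#' Runs [fit_screen_models()] for every gene pair present in the replicate
#' z-table (replicates of a treatment are pooled across arrays), adjusts the
#' pooled family of 3 x n_pairs p-values (both single terms and the
#' interaction) by Benjamini-Hochberg, and applies the same two-step rule as
#' the cohort arm: **GI** candidates have interaction `p_fdr < alpha_gi` with
#' the interaction model BIC-best; **AE** candidates have both single-term
#' `p_fdr < alpha_single`, the additive model BIC-best, and interaction
#' `p_fdr > alpha_excl` or inestimable. Significant GIs receive a taxonomy
#' label from [classify_gi_type()].
#'
#' @param zrep replicate-level z table from [robust_z_scores()].
#' @param pairs optional data frame `id1`, `id2` restricting the pair list;
#'   default: every `"A__B"` treatment found in `zrep`.
#' @param alpha_gi,alpha_excl,alpha_single decision thresholds.
#' @param tau taxonomy tolerance override; default: per-pair joint-cell SE.
#' @param min_replicates per-treatment replicate floor.
#' @param ... passed to the robust fitter.
#' @return data frame with columns `pair, beta0, beta_a, beta_b, beta_ab,
#'   interaction_value, bic_m0..bic_m4, best_model, delta_bic, evidence,
#'   p_a, p_b, p_ab, p_a_fdr, p_b_fdr, p_ab_fdr, n, classification, gi_type,
#'   tau`; attribute `family_size` gives the FDR family size.
#' @export
screen_scan <- function(zrep, pairs = NULL, alpha_gi = 0.005,
                        alpha_excl = 0.01, alpha_single = 0.005, tau = NULL,
                        min_replicates = 3L, ...) {
  stopifnot(all(c("treatment", "replicate", "z") %in% names(zrep)))
  labs <- unique(zrep$treatment)
  if (is.null(pairs)) {
    double <- labs[!grepl("CTRL", labs) & grepl("__", labs)]
    parts <- strsplit(double, "__", fixed = TRUE)
    pairs <- data.frame(id1 = vapply(parts, `[`, "", 1),
                        id2 = vapply(parts, `[`, "", 2),
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$id1, pairs$id2), , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no siRNA pairs to scan")
  z_of <- function(lab) zrep$z[zrep$treatment == lab]
  z_ctrl <- z_of("CTRL")

  rows <- vector("list", nrow(pairs))
  taus <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$id1[i]; b <- pairs$id2[i]
    fit <- fit_screen_models(z_of(paste0(a, "__CTRL")),
                             z_of(paste0(b, "__CTRL")),
                             z_of(canonical_pair(a, b)), z_ctrl,
                             min_replicates = min_replicates, ...)
    if (!isTRUE(fit$estimable)) {
      rows[[i]] <- data.frame(
        pair = canonical_pair(a, b), beta0 = NA_real_, beta_a = NA_real_,
        beta_b = NA_real_, beta_ab = NA_real_, interaction_value = NA_real_,
        bic_m0 = NA_real_, bic_m1 = NA_real_, bic_m2 = NA_real_,
        bic_m3 = NA_real_, bic_m4 = NA_real_, best_model = NA_character_,
        delta_bic = NA_real_, evidence = NA_character_,
        p_a = NA_real_, p_b = NA_real_, p_ab = NA_real_,
        n = fit$n, stringsAsFactors = FALSE)
      taus[i] <- NA_real_
      next
    }
    taus[i] <- if (is.null(tau)) fit$tau else tau
    rows[[i]] <- data.frame(
      pair = canonical_pair(a, b), beta0 = fit$beta0, beta_a = fit$beta_a,
      beta_b = fit$beta_b, beta_ab = fit$beta_ab,
      interaction_value = fit$interaction_value,
      bic_m0 = fit$bic[["M0"]], bic_m1 = fit$bic[["M1"]],
      bic_m2 = fit$bic[["M2"]], bic_m3 = fit$bic[["M3"]],
      bic_m4 = fit$bic[["M4"]], best_model = fit$best_model,
      delta_bic = fit$delta_bic, evidence = fit$evidence,
      p_a = fit$p_a, p_b = fit$p_b, p_ab = fit$p_ab,
      n = fit$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  fam <- c(out$p_a, out$p_b, out$p_ab)
  adj <- bh_fdr(fam)
  np <- nrow(out)
  out$p_a_fdr <- adj[seq_len(np)]
  out$p_b_fdr <- adj[np + seq_len(np)]
  out$p_ab_fdr <- adj[2 * np + seq_len(np)]
  out$classification <- classify_pair(out$p_a_fdr, out$p_b_fdr, out$p_ab_fdr,
                                      out$best_model, !is.na(out$p_ab),
                                      alpha_gi, alpha_excl, alpha_single)
  out$tau <- taus
  out$gi_type <- NA_character_
  sig <- which(out$classification == "GI")
  for (i in sig) {
    out$gi_type[i] <- classify_gi_type(
      tau = out$tau[i], beta0 = out$beta0[i], beta_a = out$beta_a[i],
      beta_b = out$beta_b[i], beta_ab = out$beta_ab[i])
  }
  attr(out, "family_size") <- sum(!is.na(fam))
  out
}

#' Confirm primary screen interactions against a validation screen
#'
#' A primary genetic-interaction call is validated when the pair's
#' FDR-adjusted interaction p-value in the independent validation screen is
#' below `alpha` **and** the Interaction Value has the same sign
#' (directionality) as in the primary screen. The validation FDR family is
#' the validation scan's own (3 x number of re-tested pairs).
#'
#' @param primary screen results table ([screen_scan()]) of the primary
#'   screen, or any data frame with `pair`, `interaction_value`, and
#'   optionally `gi_type`.
#' @param validation screen results table of the validation experiments.
#' @param alpha validation significance threshold on the adjusted p.
#' @return the validation rows of pairs present in both tables, with
#'   `primary_interaction_value`, `sign_match`, `validated`, and the primary
#'   `gi_type` carried over; pairs absent from the primary table are skipped
#'   with a warning.
#' @export
validate_gi_calls <- function(primary, validation, alpha = 0.01) {
  stopifnot(all(c("pair", "interaction_value") %in% names(primary)),
            all(c("pair", "interaction_value", "p_ab_fdr") %in%
                  names(validation)))
  unknown <- setdiff(validation$pair, primary$pair)
  if (length(unknown))
    warning("validation pair(s) absent from the primary screen, skipped: ",
            paste(unknown, collapse = ", "))
  v <- validation[validation$pair %in% primary$pair, , drop = FALSE]
  i <- match(v$pair, primary$pair)
  v$primary_interaction_value <- primary$interaction_value[i]
  if ("gi_type" %in% names(primary)) v$primary_gi_type <- primary$gi_type[i]
  v$sign_match <- sign(v$interaction_value) ==
    sign(v$primary_interaction_value)
  v$validated <- !is.na(v$p_ab_fdr) & v$p_ab_fdr < alpha &
    v$sign_match %in% TRUE
  rownames(v) <- NULL
  v
}
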