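#' Robust Z-scores of screen treatments against negative controls
#'
#' Per array, the treated value for each (treatment, biological replicate) is
#' the mean of its per-image mean cell intensities (images from the same
#' replicate are averaged first). It is then centred by the median and scaled
#' by the median absolute deviation of the array's negative-control per-image
#' intensities:
#'
#' `z = (I_treated - median(I_controls)) / mad(I_controls)`
#'
#' The MAD is scaled by 1.4826 by default (so z is in Gaussian-SD-equivalent
#' units); `mad_scale = FALSE` gives the raw MAD. Negative-control replicates
#' themselves receive z-scores too (the baseline rows the interaction model
#' needs). An array whose control MAD is zero is excluded with an error
#' record.
#'
#' @param measurements QC-passed per-image table (see [qc_filter_images()]).
#' @param layout array layout table with `array`, `spot`, `gene_a`, `gene_b`,
#'   `role`.
#' @param mad_scale logical; scale the MAD by 1.4826 (default) or not.
#' @return data frame of class `robust_z`: `array`, `treatment` (canonical
#'   label: `"A__B"`, `"A__CTRL"`, or `"CTRL"`), `replicate`, `z`, `n_images`;
#'   attributes `medians` (per-treatment median z across replicates, the
#'   heatmap statistic), `control_stats` (per-array median/MAD) and `errors`
#'   (arrays excluded for zero control MAD).
#' @export
robust_z_scores <- function(measurements, layout, mad_scale = TRUE) {
  m <- merge(measurements, layout[, c("array", "spot", "gene_a", "gene_b",
                                      "role")],
             by = c("array", "spot"))
  if (nrow(m) == 0L) stop("measurements and layout share no (array, spot)")
  m$treatment <- treatment_label(m$gene_a, m$gene_b)
  const <- if (mad_scale) 1.4826 else 1

  rows <- list()
  medstats <- list()
  errors <- character(0)
  for (arr in unique(m$array)) {
    a <- m[m$array == arr, , drop = FALSE]
    ctrl <- a$mean_cell_intensity[a$role == "negative-control"]
    if (length(ctrl) < 3L)
      stop("array ", arr, " has fewer than 3 negative-control values")
    med <- stats::median(ctrl)
    mad <- const * stats::median(abs(ctrl - med))
    medstats[[as.character(arr)]] <- c(median = med, mad = mad)
    if (mad == 0) {
      errors <- c(errors, as.character(arr))
      next
    }
    agg <- stats::aggregate(
      mean_cell_intensity ~ treatment + replicate, data = a, FUN = mean)
    cnt <- stats::aggregate(
      mean_cell_intensity ~ treatment + replicate, data = a, FUN = length)
    rows[[length(rows) + 1L]] <- data.frame(
      array = arr, treatment = agg$treatment, replicate = agg$replicate,
      z = (agg$mean_cell_intensity - med) / mad,
      n_images = cnt$mean_cell_intensity,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no array with positive control MAD")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  med_z <- stats::aggregate(z ~ treatment, data = out, FUN = stats::median)
  names(med_z)[2] <- "median_z"
  structure(out, class = c("robust_z", "data.frame"),
            medians = med_z,
            control_stats = do.call(rbind, medstats),
            errors = errors)
}

# canonical treatment label: genes sorted, controls pushed to the right,
# pure control collapses to "CTRL"
treatment_label <- function(gene_a, gene_b) {
  a <- as.character(gene_a)
  b <- as.character(gene_b)
  ctrl_a <- a == "CTRL"
  ctrl_b <- b == "CTRL"
  lab <- canonical_pair(a, b)
  lab[ctrl_a & !ctrl_b] <- paste0(b[ctrl_a & !ctrl_b], "__CTRL")
  lab[!ctrl_a & ctrl_b] <- paste0(a[!ctrl_a & ctrl_b], "__CTRL")
  lab[ctrl_a & ctrl_b] <- "CTRL"
  lab
}
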