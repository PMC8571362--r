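#' Collapse protein-truncating variant calls to per-gene burden
#'
#' Encodes, per sample and gene, either a carrier indicator (1 if the sample
#' carries at least one qualifying PTV in the gene; the default) or the PTV
#' count. Variants listed in `exclude_variants` are ignored before collapsing,
#' which supports conditioning a scan on a single variant (for instance the
#' gain-of-function stop variant dominating a gene's burden).
#'
#' @param ptv_calls data frame with columns `sample`, `gene`, `variant`.
#' @param samples character vector of all sample ids (non-carriers included).
#' @param genes optional character vector fixing the gene set/order; defaults
#'   to the genes present in `ptv_calls`.
#' @param mode `"indicator"` or `"count"`.
#' @param exclude_variants character vector of variant ids to drop.
#' @return numeric matrix samples x genes with a `carriers` attribute (per-gene
#'   carrier counts) and a `provenance` attribute (the contributing calls).
#' @export
encode_ptv_burden <- function(ptv_calls, samples, genes = NULL,
                              mode = c("indicator", "count"),
                              exclude_variants = character()) {
  mode <- match.arg(mode)
  stopifnot(all(c("sample", "gene", "variant") %in% names(ptv_calls)))
  if (anyDuplicated(ptv_calls[, c("sample", "gene", "variant")]))
    stop("variant ids must be unique per (sample, gene)")
  if (is.null(genes)) genes <- sort(unique(ptv_calls$gene))
  if (length(exclude_variants)) {
    known <- exclude_variants %in% ptv_calls$variant
    if (!all(known))
      warning("exclude_variants not present in calls: ",
              paste(exclude_variants[!known], collapse = ", "))
    ptv_calls <- ptv_calls[!ptv_calls$variant %in% exclude_variants, ,
                           drop = FALSE]
  }
  burden <- matrix(0, length(samples), length(genes),
                   dimnames = list(samples, genes))
  calls <- ptv_calls[ptv_calls$sample %in% samples &
                       ptv_calls$gene %in% genes, , drop = FALSE]
  if (nrow(calls)) {
    counts <- table(factor(calls$sample, levels = samples),
                    factor(calls$gene, levels = genes))
    burden[] <- as.numeric(counts)
  }
  if (mode == "indicator") burden <- (burden > 0) + 0
  attr(burden, "carriers") <- colSums(burden > 0)
  attr(burden, "provenance") <- calls
  burden
}

#' Polygenic score from dosages and per-SNP weights
#'
#' Weighted allele-dosage sum per sample. When testing a gene's burden against
#' the trait's polygenic score, all SNPs falling in that gene's region are
#' removed from the score first (`exclude_region`), so the score carries no
#' signal from the gene under test.
#'
#' @param dosages numeric matrix samples x SNPs (column names = SNP ids),
#'   hard calls in `{0,1,2}` or imputed dosages in `[0,2]`.
#' @param weights data frame with columns `snp`, `chrom`, `pos`, `weight`.
#' @param exclude_region optional list/row with `chrom`, `start`, `end`; SNPs
#'   inside it are excluded before summation.
#' @return numeric vector of scores, named by sample, with attribute
#'   `n_excluded`.
#' @export
compute_prs <- function(dosages, weights, exclude_region = NULL) {
  stopifnot(all(c("snp", "weight") %in% names(weights)))
  w <- weights
  n_excl <- 0L
  if (!is.null(exclude_region)) {
    stopifnot(all(c("chrom", "pos") %in% names(w)))
    inside <- w$chrom == exclude_region$chrom &
      w$pos >= exclude_region$start & w$pos <= exclude_region$end
    n_excl <- sum(inside)
    w <- w[!inside, , drop = FALSE]
  }
  if (nrow(w) == 0L) stop("no SNPs left in the score after exclusion")
  present <- w$snp %in% colnames(dosages)
  if (!all(present)) {
    message(sum(!present), " weighted SNP(s) missing from the dosage matrix")
    w <- w[present, , drop = FALSE]
  }
  if (nrow(w) == 0L) stop("no weighted SNPs present in the dosage matrix")
  score <- drop(dosages[, w$snp, drop = FALSE] %*% w$weight)
  names(score) <- rownames(dosages)
  attr(score, "n_excluded") <- n_excl
  score
}

#' Is the interaction between two predictors testable?
#'
#' The interaction term of a pair is estimable only when some samples are
#' exposed to both predictors and the product column is not collinear with the
#' main effects. `joint_exposed` counts samples with both predictors positive;
#' as few as one informative double-exposed sample makes a pair testable by
#' default (double carriers of rare truncating variants are that scarce).
#'
#' @param x1,x2 aligned numeric predictor vectors.
#' @param min_joint minimum number of double-exposed samples.
#' @return list with `testable` (flag) and `joint_exposed` (count).
#' @export
assess_testability <- function(x1, x2, min_joint = 1L) {
  stopifnot(length(x1) == length(x2))
  joint <- sum(x1 > 0 & x2 > 0, na.rm = TRUE)
  full_rank <- qr(cbind(1, x1, x2, x1 * x2))$rank == 4L
  list(testable = joint >= min_joint && full_rank, joint_exposed = joint)
}
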