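#' Configuration for the synthetic coRNAi screen generator
#'
#' Emulates a combinatorial-knockdown cell-microarray screen: every unordered
#' gene pair of the panel occupies one spot per array design, every
#' single-gene knockdown (gene + control siRNA) two spots, plus a set of
#' negative-control spots per design; pair spots spill over as many array
#' designs as `spots_per_array` requires. Each biological replicate assays
#' every design, with several images per spot.
#'
#' Intensities are log-normal (fluorescence is positive and right-skewed):
#' control images draw `L * exp(s * eps)`; treated spots add their planted
#' effect on the intensity scale in units of the control scaled MAD (~ `L*s`),
#' so planted and recovered robust-Z effects share units exactly. One image's
#' robust Z has SD ~ 1, hence a replicate mean over `images_per_replicate = 4`
#' images has the reference per-replicate noise SD of ~0.5.
#'
#' @param genes gene panel.
#' @param spots_per_array physical spots per array design.
#' @param n_replicates biological replicates (each assays all designs);
#'   the reference design uses 8 (at least 7 in the emulated screen).
#' @param images_per_replicate images per spot and replicate.
#' @param n_control_spots negative-control spots per design.
#' @param control_location,control_log_sd location `L` and log-scale `s` of
#'   control intensities (arbitrary fluorescence units).
#' @param gene_effects named numeric vector, per-gene single-knockdown effect
#'   in robust-Z units (missing genes default to 0).
#' @param interaction_effects named numeric vector of pair effects in
#'   robust-Z units, names are canonical `"A__B"` labels.
#' @param cells_mean mean informative cells per image (Poisson).
#' @param qc_fail_rate fraction of images planted as QC failures (zero cells,
#'   blurred, or high background).
#' @param seed integer seed.
#' @return config list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(genes = paste0("G", sprintf("%02d", 1:8)),
                              spots_per_array = 384,
                              n_replicates = 8L,
                              images_per_replicate = 4L,
                              n_control_spots = 8L,
                              control_location = 1000,
                              control_log_sd = 0.1,
                              gene_effects = NULL,
                              interaction_effects = NULL,
                              cells_mean = 75,
                              qc_fail_rate = 0.14,
                              seed = 1L) {
  stopifnot(length(genes) >= 2L, n_replicates >= 3L, n_control_spots >= 3L,
            images_per_replicate >= 1L, control_log_sd > 0,
            qc_fail_rate >= 0, qc_fail_rate < 1)
  structure(list(
    genes = genes, spots_per_array = as.integer(spots_per_array),
    n_replicates = as.integer(n_replicates),
    images_per_replicate = as.integer(images_per_replicate),
    n_control_spots = as.integer(n_control_spots),
    control_location = control_location, control_log_sd = control_log_sd,
    gene_effects = gene_effects, interaction_effects = interaction_effects,
    cells_mean = cells_mean, qc_fail_rate = qc_fail_rate,
    seed = as.integer(seed)
  ), class = "screen_sim_config")
}

#' Simulate a combinatorial RNAi screen
#'
#' Builds the array layout (pair spots never duplicated as `(B, A)`), then
#' draws per-image measurements with planted single and interaction effects
#' and injected QC failures. Pure function of `config`; the caller's RNG
#' state is restored.
#'
#' @param config a [screen_sim_config()].
#' @return list with `layout` (`array`, `spot`, `gene_a`, `gene_b`, `role`),
#'   `measurements` (`array`, `spot`, `image`, `replicate`,
#'   `mean_cell_intensity`, `cell_count`, `sharpness`, `background`),
#'   `truth` (per pair: `pair`, `beta_a`, `beta_b`, `beta_ab`, `true_label`,
#'   `true_gi_type`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, simulate_screen_impl(config))
}

simulate_screen_impl <- function(cfg) {
  genes <- sort(cfg$genes)
  pairs <- t(utils::combn(genes, 2))
  fixed_per_array <- cfg$n_control_spots + 2L * length(genes)
  pair_capacity <- cfg$spots_per_array - fixed_per_array
  if (pair_capacity < 1L)
    stop("spots_per_array too small to hold the panel singles and controls")
  n_designs <- ceiling(nrow(pairs) / pair_capacity)

  layout <- list()
  for (d in seq_len(n_designs)) {
    idx <- seq((d - 1) * pair_capacity + 1,
               min(d * pair_capacity, nrow(pairs)))
    rows <- rbind(
      data.frame(gene_a = "CTRL", gene_b = "CTRL", role = "negative-control",
                 stringsAsFactors = FALSE)[rep(1, cfg$n_control_spots), ],
      data.frame(gene_a = rep(genes, each = 2), gene_b = "CTRL",
                 role = "treatment", stringsAsFactors = FALSE),
      data.frame(gene_a = pairs[idx, 1], gene_b = pairs[idx, 2],
                 role = "treatment", stringsAsFactors = FALSE))
    rows$array <- paste0("A", d)
    rows$spot <- seq_len(nrow(rows))
    layout[[d]] <- rows
  }
  layout <- do.call(rbind, layout)[, c("array", "spot", "gene_a", "gene_b",
                                       "role")]
  rownames(layout) <- NULL

  ge <- function(g) {
    if (g == "CTRL") 0
    else if (!is.null(cfg$gene_effects) && g %in% names(cfg$gene_effects))
      cfg$gene_effects[[g]]
    else 0
  }
  ie <- function(a, b) {
    if (a == "CTRL" || b == "CTRL") return(0)
    lab <- canonical_pair(a, b)
    if (!is.null(cfg$interaction_effects) &&
        lab %in% names(cfg$interaction_effects))
      cfg$interaction_effects[[lab]]
    else 0
  }
  shift <- mapply(function(a, b) ge(a) + ge(b) + ie(a, b),
                  layout$gene_a, layout$gene_b)

  L <- cfg$control_location
  s <- cfg$control_log_sd
  unit <- L * s  # ~ the scaled MAD of control intensities
  n_img_total <- nrow(layout) * cfg$n_replicates * cfg$images_per_replicate
  meas <- data.frame(
    array = rep(layout$array, each = cfg$n_replicates *
                  cfg$images_per_replicate),
    spot = rep(layout$spot, each = cfg$n_replicates *
                 cfg$images_per_replicate),
    replicate = rep(rep(seq_len(cfg$n_replicates),
                        each = cfg$images_per_replicate), nrow(layout)),
    image = rep(seq_len(cfg$images_per_replicate),
                nrow(layout) * cfg$n_replicates),
    stringsAsFactors = FALSE)
  meas$mean_cell_intensity <- pmax(
    L * exp(s * stats::rnorm(n_img_total)) +
      rep(shift, each = cfg$n_replicates * cfg$images_per_replicate) * unit,
    0)
  meas$cell_count <- stats::rpois(n_img_total, cfg$cells_mean)
  meas$sharpness <- stats::rnorm(n_img_total, 1, 0.05)
  meas$background <- stats::rnorm(n_img_total, 100, 5)

  fail <- which(stats::runif(n_img_total) < cfg$qc_fail_rate)
  if (length(fail)) {
    kind <- sample(3, length(fail), replace = TRUE)
    meas$cell_count[fail[kind == 1]] <- 0L
    meas$sharpness[fail[kind == 2]] <- 0.2
    meas$background[fail[kind == 3]] <- 500
  }
  attr(meas, "planted_fail") <- seq_len(n_img_total) %in% fail

  truth <- data.frame(
    pair = canonical_pair(pairs[, 1], pairs[, 2]),
    beta_a = vapply(pairs[, 1], ge, numeric(1)),
    beta_b = vapply(pairs[, 2], ge, numeric(1)),
    beta_ab = mapply(ie, pairs[, 1], pairs[, 2]),
    stringsAsFactors = FALSE)
  truth$true_label <- ifelse(
    truth$beta_ab != 0, "GI",
    ifelse(truth$beta_a != 0 & truth$beta_b != 0, "AE", "none"))
  truth$true_gi_type <- NA_character_
  gi <- which(truth$true_label == "GI")
  for (i in gi) {
    truth$true_gi_type[i] <- classify_gi_type(
      tau = 0, beta0 = 0, beta_a = truth$beta_a[i],
      beta_b = truth$beta_b[i], beta_ab = truth$beta_ab[i])
  }
  rownames(truth) <- NULL
  list(layout = layout, measurements = meas, truth = truth)
}
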