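#' Quality-filter per-image screen measurements
#'
#' Removes images failing any of the pre-defined criteria: minimum cell
#' count, minimum image sharpness, maximum background intensity. When the
#' sharpness/background thresholds are not given they are derived from the
#' negative-control images of each array (5th percentile of control sharpness,
#' 95th percentile of control background), which requires `layout`.
#' Arrays losing all their images are dropped with a warning.
#'
#' @param measurements data frame with columns `array`, `spot`, `image`,
#'   `replicate`, `mean_cell_intensity`, `cell_count`, `sharpness`,
#'   `background`.
#' @param min_cells minimum cells per image.
#' @param min_sharpness,max_background fixed thresholds; `NULL` = derive from
#'   the array's negative controls.
#' @param layout array layout (columns `array`, `spot`, `gene_a`, `gene_b`,
#'   `role`), needed only for control-derived thresholds.
#' @return list with `measurements` (the passing rows), `report` (per-array
#'   `n_images`, `n_pass`, `pass_rate`) and `thresholds`.
#' @export
qc_filter_images <- function(measurements, min_cells = 20,
                             min_sharpness = NULL, max_background = NULL,
                             layout = NULL) {
  m <- measurements
  need <- c("array", "spot", "image", "mean_cell_intensity", "cell_count",
            "sharpness", "background")
  stopifnot(all(need %in% names(m)))

  derive <- is.null(min_sharpness) || is.null(max_background)
  ctrl_of <- NULL
  if (derive) {
    if (is.null(layout))
      stop("layout required to derive thresholds from negative controls")
    ctrl <- layout[layout$role == "negative-control", c("array", "spot")]
    key <- paste(m$array, m$spot)
    ctrl_of <- key %in% paste(ctrl$array, ctrl$spot)
  }

  pass <- rep(TRUE, nrow(m))
  thresholds <- list(min_cells = min_cells)
  for (arr in unique(m$array)) {
    sel <- m$array == arr
    ms <- if (derive) {
      cc <- sel & ctrl_of
      if (!any(cc)) stop("array ", arr, " has no negative-control images")
      stats::quantile(m$sharpness[cc], 0.05, names = FALSE)
    } else min_sharpness
    mb <- if (derive) {
      cc <- sel & ctrl_of
      stats::quantile(m$background[cc], 0.95, names = FALSE)
    } else max_background
    pass[sel] <- m$cell_count[sel] >= min_cells &
      m$sharpness[sel] >= ms & m$background[sel] <= mb
    thresholds[[paste0("array_", arr)]] <- c(min_sharpness = ms,
                                             max_background = mb)
  }

  report <- do.call(rbind, lapply(split(pass, m$array), function(p) {
    data.frame(n_images = length(p), n_pass = sum(p),
               pass_rate = mean(p))
  }))
  report <- cbind(array = rownames(report), report)
  rownames(report) <- NULL
  gone <- report$array[report$n_pass == 0L]
  if (length(gone))
    warning("array(s) dropped, no images passed QC: ",
            paste(gone, collapse = ", "))
  list(measurements = m[pass, , drop = FALSE], report = report,
       thresholds = thresholds)
}
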