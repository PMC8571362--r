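#' Residualize lipid phenotypes against covariates
#'
#' Each quantitative trait is regressed by ordinary least squares on the full
#' covariate set (age, sex, smoking, alcohol, BMI, lipid medication and ten
#' genotype principal components by default) and the residuals become the
#' outcome for all downstream genetic models. Binary disease status is not
#' residualized: the covariates enter the logistic models directly.
#'
#' Samples missing the trait or any covariate are dropped for that trait, with
#' the count recorded. Zero-variance covariates are dropped with a warning.
#'
#' @param cohort data frame with a `sample` id column, the trait columns and
#'   the covariate columns.
#' @param traits character vector of trait column names.
#' @param covariates character vector of covariate column names.
#' @return object of class `residual_phenotypes`: list with `residuals` (named
#'   list of named numeric vectors, names = sample ids), `n_dropped`,
#'   `covariates_used`.
#' @export
residualize_phenotypes <- function(cohort,
                                   traits = c("LDLc", "HDLc", "TG", "TC"),
                                   covariates = default_covariates()) {
  stopifnot("sample" %in% names(cohort))
  missing_cols <- setdiff(c(traits, covariates), names(cohort))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))

  cov_mat <- as.matrix(cohort[, covariates, drop = FALSE])
  variances <- apply(cov_mat, 2, function(v) stats::var(v, na.rm = TRUE))
  constant <- !is.na(variances) & variances == 0
  if (any(constant)) {
    warning("dropping zero-variance covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }

  res <- list()
  n_dropped <- integer(0)
  for (tr in traits) {
    keep <- stats::complete.cases(cohort[, c(tr, covariates), drop = FALSE])
    n_dropped[[tr]] <- sum(!keep)
    d <- cohort[keep, , drop = FALSE]
    if (nrow(d) < length(covariates) + 2L)
      stop("too few complete samples to residualize ", tr)
    if (length(covariates)) {
      f <- stats::as.formula(paste(tr, "~", paste(covariates, collapse = " + ")))
      r <- stats::residuals(stats::lm(f, data = d))
    } else {
      r <- d[[tr]] - mean(d[[tr]])
    }
    names(r) <- d$sample
    res[[tr]] <- r
  }
  structure(list(residuals = res, n_dropped = n_dropped,
                 covariates_used = covariates),
            class = "residual_phenotypes")
}

#' Default covariate column names
#' @return character vector: age, sex, smoking, alcohol, bmi,
#'   lipid_medication, PC1..PC10.
#' @export
default_covariates <- function() {
  c("age", "sex", "smoking", "alcohol", "bmi", "lipid_medication",
    paste0("PC", 1:10))
}
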