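#' Table schemas understood by the package
#'
#' Each schema names its required columns, their types and (where meaningful)
#' ranges. `read_table()` validates against them. Tables are tab-separated
#' UTF-8 with a mandatory header row and `"NA"` as the missing token; comma
#' delimiters are auto-detected on read.
#'
#' @return named list of schema definitions.
#' @export
table_schemas <- function() {
  num <- function(min = -Inf, max = Inf) list(type = "numeric", min = min,
                                              max = max)
  chr <- list(type = "character")
  list(
    phenotype = list(
      sample = chr, age = num(0, 150), sex = num(0, 1), smoking = num(0, 1),
      alcohol = num(0, 1), bmi = num(5, 100), lipid_medication = num(0, 1)),
    ptv_calls = list(sample = chr, gene = chr, variant = chr),
    prs_weights = list(snp = chr, chrom = chr, pos = num(0),
                       weight = num()),
    gene_snp_map = list(snp = chr, gene = chr),
    dosage = list(sample = chr),  # remaining columns checked as [0, 2]
    screen_layout = list(array = chr, spot = num(1), gene_a = chr,
                         gene_b = chr, role = chr),
    screen_measurements = list(array = chr, spot = num(1), image = num(1),
                               replicate = num(1),
                               mean_cell_intensity = num(0),
                               cell_count = num(0), sharpness = num(),
                               background = num())
  )
}

#' Read and validate a delimited table
#'
#' Tab or comma delimiter is auto-detected (tab canonical); the header row is
#' mandatory and `"NA"` is the missing-value token. The named schema's
#' required columns must be present with in-range values; violations error
#' with the offending column and row. An empty file is an explicit error, not
#' an empty success.
#'
#' @param path file path.
#' @param schema schema id, one of `names(table_schemas())`, or `NULL` to
#'   skip validation.
#' @return the validated data frame; the row count is reported via `message`.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("no records in ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           na.strings = "NA", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) == 0L) stop("no records in ", path)
  if (!is.null(schema)) {
    defs <- table_schemas()
    if (!schema %in% names(defs)) stop("unknown schema: ", schema)
    def <- defs[[schema]]
    missing_cols <- setdiff(names(def), names(tab))
    if (length(missing_cols))
      stop("missing required column(s) in ", path, ": ",
           paste(missing_cols, collapse = ", "))
    check_range <- function(col, vals, lo, hi) {
      bad <- which(!is.na(vals) & (vals < lo | vals > hi))
      if (length(bad))
        stop("value out of range [", lo, ", ", hi, "] in column '", col,
             "', row ", bad[1])
    }
    for (col in names(def)) {
      d <- def[[col]]
      if (d$type == "numeric") {
        vals <- suppressWarnings(as.numeric(tab[[col]]))
        if (anyNA(vals) && !anyNA(tab[[col]]))
          stop("non-numeric value in column '", col, "'")
        check_range(col, vals, d$min, d$max)
        tab[[col]] <- vals
      } else {
        tab[[col]] <- as.character(tab[[col]])
      }
    }
    if (schema == "dosage") {
      for (col in setdiff(names(tab), "sample"))
        check_range(col, as.numeric(tab[[col]]), 0, 2)
    }
  }
  message(nrow(tab), " record(s) read from ", path)
  tab
}

#' Write a table in the package's canonical format
#'
#' Tab-separated, UTF-8, header row, no quoting, `"NA"` missing token;
#' byte-identical output for identical input.
#'
#' @param tab data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: the command label, a hash of the
#' configuration, checksums of the input files, the seed(s), package version,
#' timestamp and output paths. Re-running with the same inputs, config and
#' seed reproduces the outputs byte-identically; the manifest is the audit
#' trail for that claim.
#'
#' @param path manifest destination (JSON).
#' @param command short label of the pipeline step.
#' @param config the configuration object (hashed after serialization).
#' @param inputs character vector of input file paths (checksummed).
#' @param seed the seed(s) used.
#' @param outputs character vector of output paths.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config = NULL,
                           inputs = character(), seed = NA_integer_,
                           outputs = character()) {
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    saveRDS(config, tmp, version = 2)
    cfg_hash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(
    command = command,
    config_hash = cfg_hash,
    inputs = as.list(if (length(inputs))
      vapply(inputs, function(f) unname(tools::md5sum(f)), character(1))
      else stats::setNames(character(), character())),
    seed = seed,
    package_version = as.character(utils::packageVersion("pairscan")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
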