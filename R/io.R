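# Plain-text interchange formats. All writers emit dot-decimal numbers at
# full double precision (>= 15 significant digits, so 12-digit round-trips
# are lossless) and an optional "# seed=<n>" header comment; readers validate
# the header and report malformed rows with their line numbers.

write_delim_with_seed <- function(df, path, sep, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

read_delim_checked <- function(path, sep, required, numeric_cols) {
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_mrm("%s: missing required column(s): %s", basename(path),
             paste(miss, collapse = ", "), class = "io_error")
  }
  for (cc in intersect(numeric_cols, names(df))) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad)) {
        stop_mrm("%s: non-numeric '%s' at data row(s) %s", basename(path), cc,
                 paste(utils::head(bad, 5), collapse = ", "),
                 class = "io_error")
      }
      df[[cc]] <- parsed
    }
  }
  df
}

#' Read and write transition-level MRM reports
#'
#' A simplified dialect of a Skyline-style transition export: CSV with
#' columns `protein_id`, `peptide`, `sample_id`, `nat_area`, `sis_area`
#' (plus the derived `ratio`).
#'
#' @param records transition data.frame.
#' @param path file path.
#' @param seed optional seed recorded as a header comment.
#' @export
write_transition_report <- function(records, path, seed = NULL) {
  write_delim_with_seed(records, path, sep = ",", seed = seed)
  invisible(path)
}

#' @rdname write_transition_report
#' @export
read_transition_report <- function(path) {
  df <- read_delim_checked(path, ",",
                           required = c("protein_id", "peptide", "sample_id",
                                        "nat_area", "sis_area"),
                           numeric_cols = c("nat_area", "sis_area", "ratio"))
  if (!"ratio" %in% names(df)) df$ratio <- df$nat_area / df$sis_area
  df
}

#' Read and write calibration series tables
#'
#' CSV with columns `protein_id`, `concentration`, `ratio`.
#' @inheritParams write_transition_report
#' @param series calibration data.frame.
#' @export
write_calibration_series <- function(series, path, seed = NULL) {
  write_delim_with_seed(series, path, sep = ",", seed = seed)
  invisible(path)
}

#' @rdname write_calibration_series
#' @export
read_calibration_series <- function(path) {
  read_delim_checked(path, ",",
                     required = c("protein_id", "concentration", "ratio"),
                     numeric_cols = c("concentration", "ratio"))
}

#' Read and write the protein quant matrix
#'
#' TSV with samples as rows (first column `sample_id`) and proteins as
#' columns, plus a parallel boolean censoring TSV of identical shape.
#'
#' @param quant a `protein_quant_matrix`.
#' @param path concentrations TSV path.
#' @param censor_path censoring-flags TSV path (optional on read).
#' @param seed optional seed recorded as a header comment.
#' @export
write_quant_matrix <- function(quant, path, censor_path = NULL, seed = NULL) {
  df <- data.frame(sample_id = quant$sample_ids,
                   quant$concentrations, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_delim_with_seed(df, path, sep = "\t", seed = seed)
  if (!is.null(censor_path)) {
    cf <- data.frame(sample_id = quant$sample_ids,
                     quant$censored * 1L, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_delim_with_seed(cf, censor_path, sep = "\t", seed = seed)
  }
  invisible(path)
}

#' @rdname write_quant_matrix
#' @param group_labels optional named group vector to attach.
#' @export
read_quant_matrix <- function(path, censor_path = NULL, group_labels = NULL) {
  df <- read_delim_checked(path, "\t", required = "sample_id",
                           numeric_cols = character(0))
  conc <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(conc) <- "double"
  rownames(conc) <- df$sample_id
  censored <- if (!is.null(censor_path)) {
    cf <- read_delim_checked(censor_path, "\t", required = "sample_id",
                             numeric_cols = character(0))
    cm <- as.matrix(cf[, setdiff(names(cf), "sample_id"), drop = FALSE]) == 1
    rownames(cm) <- cf$sample_id
    cm[rownames(conc), colnames(conc), drop = FALSE]
  } else {
    matrix(FALSE, nrow(conc), ncol(conc), dimnames = dimnames(conc))
  }
  structure(
    list(concentrations = conc, censored = censored,
         sample_ids = rownames(conc), protein_ids = colnames(conc),
         group_labels = if (!is.null(group_labels))
           group_labels[rownames(conc)] else NULL,
         lloq = NULL),
    class = "protein_quant_matrix"
  )
}

#' Read and write sample metadata
#'
#' CSV with `sample_id`, `group`, and any covariate/outcome columns.
#' @inheritParams write_transition_report
#' @param metadata metadata data.frame.
#' @export
write_metadata <- function(metadata, path, seed = NULL) {
  write_delim_with_seed(metadata, path, sep = ",", seed = seed)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  read_delim_checked(path, ",", required = c("sample_id", "group"),
                     numeric_cols = character(0))
}

#' Serialize and restore a model report as JSON
#'
#' Numbers are written at full precision so reports round-trip losslessly.
#'
#' @param report a `model_report`.
#' @param path JSON file path.
#' @export
write_model_report <- function(report, path) {
  validate_model_report(report)
  obj <- unclass(report)
  attr(obj, "stages") <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_model_report
#' @export
read_model_report <- function(path) {
  obj <- jsonlite::fromJSON(path)
  rep <- structure(
    list(contrast = obj$contrast,
         variables = as.data.frame(obj$variables,
                                   stringsAsFactors = FALSE),
         threshold = obj$threshold,
         sensitivity = obj$sensitivity,
         specificity = obj$specificity,
         auc = obj$auc,
         cross_validation = obj$cross_validation,
         n_fallback_folds = as.integer(obj$n_fallback_folds),
         n_separation_warnings = as.integer(obj$n_separation_warnings)),
    class = "model_report"
  )
  validate_model_report(rep)
  rep
}

#' ROC operating points of a probability vector
#'
#' Sensitivity/specificity at every observed probability cut (rule
#' `p >= threshold` positive), exportable as CSV.
#'
#' @param probabilities predicted probabilities.
#' @param y binary 0/1 outcome.
#' @export
roc_points <- function(probabilities, y) {
  y <- as.numeric(y)
  cand <- sort(unique(probabilities))
  do.call(rbind, lapply(cand, function(thr) {
    pos <- probabilities >= thr
    data.frame(threshold = thr,
               sensitivity = sum(pos & y == 1) / sum(y == 1),
               specificity = sum(!pos & y == 0) / sum(y == 0))
  }))
}
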