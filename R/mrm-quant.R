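#' Fit a weighted linear calibration curve for one peptide
#'
#' Regresses the measured NAT/SIS area ratio on the known spiked
#' concentration with 1/x^2 weights (the bioanalytical default when
#' measurement error is proportional to concentration), via
#' `stats::lm(ratio ~ concentration, weights = 1/concentration^2)`.
#'
#' @param points data.frame with columns `concentration` (> 0) and `ratio`.
#' @param weighting `"1/x^2"` (default), `"1/x"`, or `"none"`.
#' @param lloq lower limit of quantification carried on the curve (fmol/uL);
#'   an input per peptide, not re-derived from the fit.
#' @param protein_id identifier stored on the curve.
#' @return object of class `calibration_curve` with `slope`, `intercept`,
#'   `weighting`, `lloq`, `n_points` and `r_squared_weighted` (coefficient of
#'   determination in the weighted metric).
#' @export
fit_calibration <- function(points, weighting = c("1/x^2", "1/x", "none"),
                            lloq = NA_real_, protein_id = NA_character_) {
  weighting <- match.arg(weighting)
  need <- c("concentration", "ratio")
  if (!all(need %in% names(points))) {
    stop_mrm("calibration points need columns: %s",
             paste(need, collapse = ", "), class = "validation_error")
  }
  x <- points$concentration
  y <- points$ratio
  if (length(unique(x)) < 2) {
    stop_mrm("need >= 2 distinct concentrations to fit a line",
             class = "degenerate_design_error")
  }
  if (weighting != "none" && any(x <= 0)) {
    stop_mrm("weighting %s is undefined at concentration <= 0", weighting,
             class = "weight_error")
  }
  w <- switch(weighting, `1/x^2` = 1 / x^2, `1/x` = 1 / x,
              none = rep(1, length(x)))
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  ybar_w <- sum(w * y) / sum(w)
  sse <- sum(w * stats::residuals(fit)^2)
  sst <- sum(w * (y - ybar_w)^2)
  structure(
    list(protein_id = protein_id,
         slope = unname(cf[2]),
         intercept = unname(cf[1]),
         weighting = weighting,
         lloq = lloq,
         n_points = length(x),
         r_squared_weighted = if (sst > 0) 1 - sse / sst else NA_real_),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve [%s]: ratio = %.6g + %.6g * conc (%s weighting, n = %d, wR^2 = %.4f, LLOQ = %.4g)\n",
    x$protein_id, x$intercept, x$slope, x$weighting, x$n_points,
    x$r_squared_weighted, x$lloq))
  invisible(x)
}

#' Fit calibration curves for every protein in a series table
#'
#' @param series data.frame (`protein_id`, `concentration`, `ratio`).
#' @param lloq named vector of per-protein LLOQs (fmol/uL).
#' @param weighting passed to [fit_calibration()].
#' @return named list of `calibration_curve` objects.
#' @export
fit_calibration_curves <- function(series, lloq, weighting = "1/x^2") {
  ids <- unique(series$protein_id)
  curves <- lapply(ids, function(id) {
    fit_calibration(series[series$protein_id == id, , drop = FALSE],
                    weighting = weighting,
                    lloq = unname(lloq[id]), protein_id = id)
  })
  stats::setNames(curves, ids)
}

#' Back-calculate concentrations from transition records
#'
#' Inverts each protein's fitted calibration line:
#' `concentration = (ratio - intercept) / slope`, in fmol/uL plasma. Negative
#' back-calculations (legitimate consequences of intercept noise near the
#' assay floor) are retained as raw values; [substitute_below_lloq()]
#' resolves them.
#'
#' @param records transition data.frame (`protein_id`, `sample_id`, `ratio`;
#'   or `nat_area`/`sis_area` from which the ratio is derived).
#' @param curves named list of `calibration_curve` objects.
#' @return samples x proteins numeric matrix of raw concentrations.
#' @export
quantify <- function(records, curves) {
  if (!"ratio" %in% names(records)) {
    if (!all(c("nat_area", "sis_area") %in% names(records))) {
      stop_mrm("records need a ratio or nat_area/sis_area columns",
               class = "validation_error")
    }
    if (any(records$sis_area <= 0)) {
      stop_mrm("sis_area must be > 0", class = "validation_error")
    }
    records$ratio <- records$nat_area / records$sis_area
  }
  prot <- unique(records$protein_id)
  missing_curves <- setdiff(prot, names(curves))
  if (length(missing_curves)) {
    stop_mrm("no calibration curve for: %s",
             paste(missing_curves, collapse = ", "), class = "lookup_error")
  }
  slopes <- vapply(curves[prot], `[[`, numeric(1), "slope")
  if (any(slopes == 0)) {
    stop_mrm("calibration slope is zero for: %s",
             paste(prot[slopes == 0], collapse = ", "),
             class = "degenerate_curve_error")
  }
  intercepts <- vapply(curves[prot], `[[`, numeric(1), "intercept")
  samp <- unique(records$sample_id)
  conc <- matrix(NA_real_, nrow = length(samp), ncol = length(prot),
                 dimnames = list(samp, prot))
  i <- match(records$sample_id, samp)
  j <- match(records$protein_id, prot)
  conc[cbind(i, j)] <- (records$ratio - intercepts[j]) / slopes[j]
  conc
}

#' Substitute below-LLOQ concentrations with random in-range values
#'
#' Values at or above the protein's LLOQ pass through unchanged; values below
#' it (including non-positive back-calculations) are replaced with a uniform
#' draw strictly inside (0, LLOQ) and flagged as censored. The draw is seeded
#' so the substitution is reproducible.
#'
#' @param raw samples x proteins matrix from [quantify()].
#' @param curves named list of `calibration_curve` objects carrying `lloq`.
#' @param group_labels optional named group vector (names = sample ids).
#' @param seed RNG seed for the substitution draws.
#' @return object of class `protein_quant_matrix`: `concentrations`,
#'   `censored` (logical matrix), `sample_ids`, `protein_ids`,
#'   `group_labels`, `lloq`.
#' @export
substitute_below_lloq <- function(raw, curves, group_labels = NULL,
                                  seed = 1L) {
  lloq <- vapply(curves[colnames(raw)], `[[`, numeric(1), "lloq")
  if (any(!is.finite(lloq) | lloq <= 0)) {
    stop_mrm("every curve must carry a finite LLOQ > 0",
             class = "validation_error")
  }
  lloq_mat <- matrix(lloq, nrow = nrow(raw), ncol = ncol(raw), byrow = TRUE)
  censored <- raw < lloq_mat
  conc <- raw
  n_c <- sum(censored)
  if (n_c > 0) {
    draws <- with_local_seed(seed, stats::runif(n_c))
    # strictly inside (0, LLOQ): runif returns values in (0, 1)
    conc[censored] <- draws * lloq_mat[censored]
  }
  if (!is.null(group_labels)) {
    group_labels <- group_labels[rownames(raw)]
  }
  structure(
    list(concentrations = conc,
         censored = censored,
         sample_ids = rownames(raw),
         protein_ids = colnames(raw),
         group_labels = group_labels,
         lloq = lloq),
    class = "protein_quant_matrix"
  )
}

#' @export
print.protein_quant_matrix <- function(x, ...) {
  cat("Protein quant matrix:", length(x$sample_ids), "samples x",
      length(x$protein_ids), "proteins (fmol/uL);",
      sum(x$censored), "cells censored below LLOQ\n")
  invisible(x)
}
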