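#' Pipeline configuration
#'
#' Ties the stages together: the synthetic cohort design, the diagnostic
#' contrasts (each a case/control group pair with its feature grammar), the
#' prognostic outcomes (modeled in ratio mode over all samples), thresholds,
#' and the single seed every stage's randomness flows from (through fixed
#' per-stage substreams).
#'
#' @param cohort a [cohort_config()].
#' @param out_dir output directory (created if absent).
#' @param contrasts list of `list(name, case, control, mode)`; defaults to
#'   the three gestational-age-matched diagnostic contrasts in quadratic
#'   mode.
#' @param outcome_modes feature grammar per generated outcome (default ratio
#'   mode, the prognostic grammar).
#' @param vip_threshold,alpha,n_orthogonal cascade tuning knobs.
#' @param calibration_levels calibration design, in multiples of each
#'   protein's LLOQ.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            out_dir = tempfile("mrmrun"),
                            contrasts = list(
                              list(name = "early_IUGR_vs_early_control",
                                   case = "early_IUGR",
                                   control = "early_control",
                                   mode = "quadratic"),
                              list(name = "late_IUGR_vs_late_control",
                                   case = "late_IUGR",
                                   control = "late_control",
                                   mode = "quadratic"),
                              list(name = "late_IUGR_vs_SGA",
                                   case = "late_IUGR", control = "SGA",
                                   mode = "quadratic")
                            ),
                            outcome_modes = "ratio",
                            vip_threshold = 1, alpha = 0.05,
                            n_orthogonal = 1,
                            calibration_levels = c(1, 2, 5, 10, 20, 50, 100,
                                                   200)) {
  stopifnot(inherits(cohort, "cohort_config"))
  for (ct in contrasts) {
    need <- c("name", "case", "control", "mode")
    if (!all(need %in% names(ct))) {
      stop_mrm("each contrast needs fields: %s", paste(need, collapse = ", "),
               class = "config_error")
    }
    missing_groups <- setdiff(c(ct$case, ct$control),
                              names(cohort$group_sizes))
    if (length(missing_groups)) {
      stop_mrm("contrast '%s' references unknown group(s): %s", ct$name,
               paste(missing_groups, collapse = ", "),
               class = "config_error")
    }
  }
  structure(
    list(cohort = cohort, out_dir = out_dir, contrasts = contrasts,
         outcome_modes = outcome_modes, vip_threshold = vip_threshold,
         alpha = alpha, n_orthogonal = n_orthogonal,
         calibration_levels = calibration_levels, seed = cohort$seed),
    class = "pipeline_config"
  )
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> quantify -> compare -> build-model -> report: a
#' synthetic cohort and its transition/calibration tables are generated,
#' concentrations are back-calculated through 1/x^2-weighted calibration
#' curves with below-LLOQ substitution, every diagnostic contrast gets a
#' gated univariate comparison table and a cascade-built logistic model, each
#' generated outcome gets a ratio-mode prognostic model, and every artifact
#' is written under `config$out_dir` and checksummed in the returned
#' manifest. Reruns with the same seed produce identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_manifest`: `artifacts` (file/md5 table),
#'   `seed`, `settings`, `warnings`, `reports` (the in-memory model reports),
#'   `stats` (univariate tables), `timestamp`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  pth <- function(...) file.path(config$out_dir, ...)
  emitted <- character(0)
  emit <- function(p) {
    emitted <<- c(emitted, p)
    p
  }
  warnings_log <- list()

  # --- simulate ---
  cohort <- generate_cohort(config$cohort)
  records <- generate_transition_records(cohort)
  series <- generate_calibration_series(config$cohort,
                                        levels = config$calibration_levels,
                                        relative = TRUE)
  metadata <- cohort_metadata(cohort)
  emit(write_transition_report(records, pth("transitions.csv"), seed = seed))
  emit(write_calibration_series(series, pth("calibration_series.csv"),
                                seed = seed))
  emit(write_metadata(metadata, pth("metadata.csv"), seed = seed))
  jsonlite::write_json(
    list(seed = seed,
         group_sizes = as.list(config$cohort$group_sizes),
         noise_cv = config$cohort$noise_cv,
         panel = config$cohort$panel),
    emit(pth("ground_truth.json")), auto_unbox = TRUE, digits = NA)

  # --- quantify ---
  lloq <- stats::setNames(config$cohort$panel$lloq,
                          config$cohort$panel$protein_id)
  curves <- fit_calibration_curves(series, lloq, weighting = "1/x^2")
  raw <- quantify(records, curves)
  quant <- substitute_below_lloq(raw, curves,
                                 group_labels = cohort$group_labels,
                                 seed = stage_seed(seed, 4))
  emit(write_quant_matrix(quant, pth("quant_matrix.tsv"),
                          censor_path = pth("quant_censored.tsv"),
                          seed = seed))
  emit(pth("quant_censored.tsv"))

  # --- compare (univariate layer) ---
  stats_tables <- list()
  for (ct in config$contrasts) {
    tab <- compare_proteins(quant, ct$case, ct$control)
    stats_tables[[ct$name]] <- tab
    f <- pth(sprintf("stats_%s.csv", ct$name))
    write_delim_with_seed(tab, f, sep = ",", seed = seed)
    emit(f)
  }
  cov_cols <- setdiff(names(cohort$covariates), "sample_id")
  if (length(cov_cols)) {
    correlations <- correlate_clinical(quant, cohort$covariates)
    write_delim_with_seed(correlations, pth("clinical_correlations.csv"),
                          sep = ",", seed = seed)
    emit(pth("clinical_correlations.csv"))
    stats_tables[["clinical_correlations"]] <- correlations
  }
  jsonlite::write_json(
    lapply(stats_tables, function(tab) {
      if ("p_value" %in% names(tab)) {
        list(n_tested = nrow(tab),
             n_p_lt_05 = sum(tab$p_value < 0.05),
             n_adjusted_lt_05 = if ("p_adjusted" %in% names(tab))
               sum(tab$p_adjusted < 0.05) else NULL)
      } else {
        list(n_tested = nrow(tab))
      }
    }),
    emit(pth("stats_summary.json")), auto_unbox = TRUE, digits = NA)

  # --- build-model (diagnostic contrasts) ---
  reports <- list()
  for (ct in config$contrasts) {
    keep <- quant$group_labels %in% c(ct$case, ct$control)
    sub <- structure(
      list(concentrations = quant$concentrations[keep, , drop = FALSE],
           censored = quant$censored[keep, , drop = FALSE],
           sample_ids = quant$sample_ids[keep],
           protein_ids = quant$protein_ids,
           group_labels = quant$group_labels[keep],
           lloq = quant$lloq),
      class = "protein_quant_matrix")
    yv <- as.numeric(sub$group_labels == ct$case)
    report <- build_model(sub, yv, mode = ct$mode, contrast = ct$name,
                          vip_threshold = config$vip_threshold,
                          n_orthogonal = config$n_orthogonal,
                          alpha = config$alpha)
    reports[[ct$name]] <- report
    emit(write_model_report(report, pth(sprintf("model_%s.json", ct$name))))
    write_delim_with_seed(as.data.frame(report),
                          pth(sprintf("model_%s.csv", ct$name)),
                          sep = ",", seed = seed)
    emit(pth(sprintf("model_%s.csv", ct$name)))
    rp <- roc_points(attr(report, "stages")$probabilities, yv)
    write_delim_with_seed(rp, pth(sprintf("roc_%s.csv", ct$name)), sep = ",",
                          seed = seed)
    emit(pth(sprintf("roc_%s.csv", ct$name)))
    if (report$n_separation_warnings > 0) {
      warnings_log[[ct$name]] <- sprintf("%d separation event(s)",
                                         report$n_separation_warnings)
    }
  }

  # --- build-model (prognostic outcomes, ratio grammar) ---
  for (os in config$cohort$outcome_specs) {
    yv <- cohort$outcomes[[os$name]][match(quant$sample_ids,
                                           cohort$outcomes$sample_id)]
    if (length(unique(yv)) < 2) {
      warnings_log[[os$name]] <- "outcome degenerate (single class); skipped"
      next
    }
    nm <- sprintf("outcome_%s", os$name)
    report <- build_model(quant, yv, mode = config$outcome_modes,
                          contrast = nm,
                          vip_threshold = config$vip_threshold,
                          n_orthogonal = config$n_orthogonal,
                          alpha = config$alpha)
    reports[[nm]] <- report
    emit(write_model_report(report, pth(sprintf("model_%s.json", nm))))
    write_delim_with_seed(as.data.frame(report),
                          pth(sprintf("model_%s.csv", nm)), sep = ",",
                          seed = seed)
    emit(pth(sprintf("model_%s.csv", nm)))
    if (report$n_separation_warnings > 0) {
      warnings_log[[nm]] <- sprintf("%d separation event(s)",
                                    report$n_separation_warnings)
    }
  }

  artifacts <- data.frame(
    file = basename(emitted),
    md5 = unname(tools::md5sum(emitted)),
    stringsAsFactors = FALSE
  )
  structure(
    list(artifacts = artifacts,
         seed = seed,
         settings = list(weighting = "1/x^2",
                         vip_threshold = config$vip_threshold,
                         alpha = config$alpha,
                         n_orthogonal = config$n_orthogonal,
                         noise_cv = config$cohort$noise_cv,
                         modes = vapply(config$contrasts, `[[`, "", "mode")),
         warnings = warnings_log,
         reports = reports,
         stats = stats_tables,
         out_dir = config$out_dir,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest (seed", x$seed, ")\n")
  cat("  artifacts:", nrow(x$artifacts), "files in", x$out_dir, "\n")
  cat("  models:   ", paste(names(x$reports), collapse = ", "), "\n")
  if (length(x$warnings)) {
    cat("  warnings: ", paste(sprintf("%s: %s", names(x$warnings),
                                      unlist(x$warnings)), collapse = "; "),
        "\n")
  }
  invisible(x)
}
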