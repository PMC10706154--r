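#' Default 125-protein panel description
#'
#' Synthetic panel fixture for the cohort generator: per-protein baseline
#' log10 concentration (fmol/uL), biological log10 SD, lower limit of
#' quantification, and the true calibration line used when simulating NAT/SIS
#' area ratios. About twenty proteins carry their field names (serum albumin,
#' alpha-2-macroglobulin, the apolipoproteins, ...) at physiologically
#' plausible plasma levels; the remainder are generic panel members spaced so
#' the whole panel spans 5.43 orders of magnitude of abundance. These values
#' are declared fixtures of this package, not measurements of any commercial
#' kit.
#'
#' @param n_proteins panel size (default 125).
#' @param log10_sd baseline between-subject biological SD on the log10 scale.
#' @return data.frame with columns `protein_id`, `log10_mean`, `log10_sd`,
#'   `lloq`, `slope`, `intercept`.
#' @export
default_panel <- function(n_proteins = 125, log10_sd = 0.15) {
  named <- c(
    ALB = 5.81, APOC1 = 3.96, RBP4 = 3.70, APOD = 3.60, APOA4 = 3.54,
    A2M = 3.44, SERPINC1 = 3.36, A1BG = 3.30, PLG = 3.30, APOB100 = 3.20,
    GSN = 3.00, FN1 = 3.00, C5 = 2.90, PZP = 2.80, GPX3 = 2.70,
    PON3 = 2.40, ADIPOQ = 2.22, LBP = 2.00, APOA = 1.70, S100A9 = 1.50,
    CAMP = 0.90, PLAT = 0.60
  )
  if (n_proteins < length(named)) {
    named <- named[seq_len(n_proteins)]
  }
  n_generic <- n_proteins - length(named)
  generic <- if (n_generic > 0) {
    # 0.38 anchors the low end so max - min = 5.81 - 0.38 = 5.43 decades
    stats::setNames(
      seq(0.38, 5.50, length.out = n_generic),
      sprintf("P%03d", seq_len(n_generic))
    )
  } else {
    numeric(0)
  }
  log10_mean <- c(named, generic)
  data.frame(
    protein_id = names(log10_mean),
    log10_mean = unname(log10_mean),
    log10_sd = log10_sd,
    lloq = 10^(unname(log10_mean) - 2 * log10_sd),
    slope = 10^(-unname(log10_mean)),
    intercept = 0,
    stringsAsFactors = FALSE
  )
}

#' Default group effect table
#'
#' Per-(protein, group) log10 fold-changes versus the matched baseline;
#' directions follow the published early/late IUGR plasma patterns
#' (adiponectin, alpha-2-macroglobulin, gelsolin up in early IUGR;
#' apolipoprotein A-IV up in late IUGR; apolipoprotein B-100 down early ...).
#'
#' @return data.frame with columns `protein_id`, `group`, `log10_fc`.
#' @export
default_effect_table <- function() {
  # log10 fold-changes vs the gestational-age-matched baseline; directions
  # follow the published early/late IUGR plasma patterns
  data.frame(
    protein_id = c(
      "ADIPOQ", "A2M", "GSN", "PZP", "S100A9", "ALB", "APOB100", "CAMP",
      "PLAT",
      "APOA4", "GSN", "GPX3", "PLG", "RBP4", "BTD",
      "GSN"
    ),
    group = c(
      rep("early_IUGR", 9),
      rep("late_IUGR", 5), "late_IUGR",
      "SGA"
    )[seq_len(16)],
    log10_fc = c(
      0.15, 0.18, 0.12, 0.15, 0.15, 0.05, -0.12, -0.12, -0.10,
      0.15, 0.10, 0.10, 0.08, 0.10, 0.08,
      0.05
    ),
    stringsAsFactors = FALSE
  )
}

#' Default clinical covariate specification
#'
#' Three covariates tied to panel proteins by Spearman correlation: newborn
#' weight (negatively to alpha-2-macroglobulin), cord blood glucose
#' (negatively to adiponectin), and uterine artery pulsatility index
#' (positively to adiponectin).
#'
#' @return data.frame with columns `covariate`, `protein_id`, `spearman`,
#'   `mean`, `sd`.
#' @export
default_covariate_spec <- function() {
  data.frame(
    covariate = c("newborn_weight", "cord_glucose", "uta_pi"),
    protein_id = c("A2M", "ADIPOQ", "ADIPOQ"),
    spearman = c(-0.40, -0.30, 0.42),
    mean = c(2500, 4.5, 1.2),
    sd = c(600, 1.0, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Engineered-feature descriptors
#'
#' The model grammar admits raw concentrations, squares, unordered pairwise
#' products, and ordered pairwise ratios of panel proteins. These constructors
#' build the descriptor used by both the outcome generator and the feature
#' expansion.
#'
#' @param i,j protein identifiers (panel `protein_id` strings).
#' @return list with elements `kind` and `proteins`.
#' @export
feat_raw <- function(i) list(kind = "raw", proteins = i)

#' @rdname feat_raw
#' @export
feat_square <- function(i) list(kind = "square", proteins = i)

#' @rdname feat_raw
#' @export
feat_product <- function(i, j) list(kind = "product", proteins = c(i, j))

#' @rdname feat_raw
#' @export
feat_ratio <- function(i, j) list(kind = "ratio", proteins = c(i, j))

feature_label <- function(f) {
  switch(f$kind,
    raw = f$proteins[1],
    square = paste0(f$proteins[1], "^2"),
    product = paste0(f$proteins[1], "*", f$proteins[2]),
    ratio = paste0(f$proteins[1], "/", f$proteins[2]),
    stop_mrm("unknown feature kind '%s'", f$kind, class = "config_error")
  )
}

#' Evaluate engineered features on a concentration matrix
#'
#' @param conc samples x proteins matrix with column names matching the
#'   protein identifiers referenced by `features`.
#' @param features list of descriptors from [feat_raw()] and friends.
#' @return samples x features numeric matrix, columns labelled by feature.
#' @export
evaluate_features <- function(conc, features) {
  vals <- vapply(features, function(f) {
    miss <- setdiff(f$proteins, colnames(conc))
    if (length(miss)) {
      stop_mrm("feature references unknown protein(s): %s",
               paste(miss, collapse = ", "), class = "config_error")
    }
    switch(f$kind,
      raw = conc[, f$proteins[1]],
      square = conc[, f$proteins[1]]^2,
      product = conc[, f$proteins[1]] * conc[, f$proteins[2]],
      ratio = conc[, f$proteins[1]] / conc[, f$proteins[2]]
    )
  }, numeric(nrow(conc)))
  vals <- matrix(vals, nrow = nrow(conc))
  dimnames(vals) <- list(rownames(conc),
                         vapply(features, feature_label, character(1)))
  vals
}

# natural-log-scale (mu, sigma) of an engineered feature of independent
# log-normal baseline concentrations; exact under the generator's law
feature_lnorm_params <- function(f, panel) {
  row <- function(id) {
    k <- match(id, panel$protein_id)
    if (is.na(k)) {
      stop_mrm("feature references unknown protein '%s'", id,
               class = "config_error")
    }
    panel[k, ]
  }
  ln10 <- log(10)
  a <- row(f$proteins[1])
  switch(f$kind,
    raw = c(mu = a$log10_mean * ln10, sigma = a$log10_sd * ln10),
    square = c(mu = 2 * a$log10_mean * ln10, sigma = 2 * a$log10_sd * ln10),
    product = {
      b <- row(f$proteins[2])
      c(mu = (a$log10_mean + b$log10_mean) * ln10,
        sigma = sqrt(a$log10_sd^2 + b$log10_sd^2) * ln10)
    },
    ratio = {
      b <- row(f$proteins[2])
      c(mu = (a$log10_mean - b$log10_mean) * ln10,
        sigma = sqrt(a$log10_sd^2 + b$log10_sd^2) * ln10)
    }
  )
}

#' Closed-form baseline moments of an engineered feature
#'
#' Mean and SD of the feature under the generator's baseline log-normal law
#' (group fold-changes excluded), used to place outcome coefficients on the
#' raw concentration scale.
#'
#' @param f feature descriptor.
#' @param panel panel data.frame as from [default_panel()].
#' @return named vector `c(mean, sd)`.
#' @export
feature_moments <- function(f, panel) {
  p <- feature_lnorm_params(f, panel)
  m <- exp(p[["mu"]] + p[["sigma"]]^2 / 2)
  s <- m * sqrt(exp(p[["sigma"]]^2) - 1)
  c(mean = m, sd = s)
}

#' Outcome specification for the cohort generator
#'
#' Defines a binary outcome drawn Bernoulli(plogis(b0 + sum b_k f_k)) from
#' engineered features of the true concentrations. Coefficients can be given
#' directly on the raw concentration scale (`true_beta`, intercept first), or
#' per-feature on the standardized scale (`slope_sd`, log-odds per baseline SD
#' of the feature), from which raw coefficients are derived so the linear
#' predictor is centered at the baseline feature mean.
#'
#' @param features list of feature descriptors.
#' @param true_beta numeric, length `length(features) + 1`, intercept first.
#' @param slope_sd numeric, length `length(features)`; ignored when
#'   `true_beta` is given.
#' @param name outcome label.
#' @export
outcome_spec <- function(features, true_beta = NULL, slope_sd = NULL,
                         name = "outcome") {
  if (!length(features)) {
    stop_mrm("outcome needs at least one feature", class = "config_error")
  }
  if (is.null(true_beta) && is.null(slope_sd)) {
    stop_mrm("give true_beta or slope_sd", class = "config_error")
  }
  if (!is.null(true_beta) && length(true_beta) != length(features) + 1L) {
    stop_mrm("true_beta must have length %d (intercept first)",
             length(features) + 1L, class = "config_error")
  }
  structure(
    list(features = features, true_beta = true_beta, slope_sd = slope_sd,
         name = name),
    class = "outcome_spec"
  )
}

# raw-scale coefficient vector (intercept first) for an outcome spec
resolve_outcome_beta <- function(spec, panel) {
  if (!is.null(spec$true_beta)) {
    return(spec$true_beta)
  }
  mom <- lapply(spec$features, feature_moments, panel = panel)
  b <- vapply(seq_along(spec$features), function(k) {
    spec$slope_sd[k] / mom[[k]][["sd"]]
  }, numeric(1))
  b0 <- -sum(vapply(seq_along(b), function(k) b[k] * mom[[k]][["mean"]],
                    numeric(1)))
  c(b0, b)
}

#' Cohort generator configuration
#'
#' Bundles the study design the generator emulates: five groups of ten
#' subjects, a 125-protein panel spanning 5.43 decades of abundance,
#' group-specific log10 fold-changes, proportional-CV measurement noise on the
#' NAT/SIS ratio, per-protein LLOQs, clinical covariates tied to chosen
#' proteins by Spearman correlation, and binary outcomes driven by a known
#' logistic model on engineered features.
#'
#' @param group_sizes named integer vector, group label -> subject count.
#' @param panel panel data.frame ([default_panel()]).
#' @param effect_table data.frame (protein_id, group, log10_fc) of group
#'   shifts on the log10 scale.
#' @param noise_cv proportional coefficient of variation of the measured area
#'   ratio (0.05 = 5\%).
#' @param outcome_specs list of [outcome_spec()] objects.
#' @param covariate_spec data.frame (covariate, protein_id, spearman, mean,
#'   sd) of clinical covariates and their target Spearman correlation with a
#'   linked protein.
#' @param seed integer RNG seed; all generator randomness flows from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(early_IUGR = 10, late_IUGR = 10,
                                          early_control = 10,
                                          late_control = 10, SGA = 10),
                          panel = default_panel(),
                          effect_table = default_effect_table(),
                          noise_cv = 0.05,
                          outcome_specs = list(
                            outcome_spec(list(feat_ratio("S100A9", "PON3")),
                                         slope_sd = 1.8, name = "bleeding")
                          ),
                          covariate_spec = default_covariate_spec(),
                          seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop_mrm("group_sizes must be a named vector", class = "config_error")
  }
  if (any(group_sizes < 2)) {
    stop_mrm("all group sizes must be >= 2", class = "config_error")
  }
  if (noise_cv < 0) {
    stop_mrm("noise_cv must be >= 0", class = "config_error")
  }
  need <- c("protein_id", "log10_mean", "log10_sd", "lloq", "slope",
            "intercept")
  if (!all(need %in% names(panel))) {
    stop_mrm("panel lacks column(s): %s",
             paste(setdiff(need, names(panel)), collapse = ", "),
             class = "config_error")
  }
  if (any(panel$lloq <= 0)) {
    stop_mrm("lloq must be > 0 for every protein", class = "config_error")
  }
  if (anyDuplicated(panel$protein_id)) {
    stop_mrm("duplicated protein_id in panel", class = "config_error")
  }
  if (nrow(effect_table)) {
    effect_table <- effect_table[effect_table$protein_id %in% panel$protein_id &
                                   effect_table$group %in% names(group_sizes), ,
                                 drop = FALSE]
  }
  for (os in outcome_specs) {
    for (f in os$features) {
      if (!all(f$proteins %in% panel$protein_id)) {
        stop_mrm("outcome '%s' references protein(s) outside the panel",
                 os$name, class = "config_error")
      }
    }
  }
  if (nrow(covariate_spec)) {
    bad <- setdiff(covariate_spec$protein_id, panel$protein_id)
    if (length(bad)) {
      stop_mrm("covariate_spec references unknown protein(s): %s",
               paste(bad, collapse = ", "), class = "config_error")
    }
  }
  structure(
    list(group_sizes = group_sizes, panel = panel,
         effect_table = effect_table, noise_cv = noise_cv,
         outcome_specs = outcome_specs, covariate_spec = covariate_spec,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("MRM synthetic cohort configuration\n")
  cat("  groups:  ", paste(sprintf("%s (n=%d)", names(x$group_sizes),
                                   x$group_sizes), collapse = ", "), "\n")
  cat("  panel:   ", nrow(x$panel), "proteins spanning",
      sprintf("%.2f", diff(range(x$panel$log10_mean))),
      "orders of magnitude\n")
  cat("  noise:   ", sprintf("%.1f%% CV on the NAT/SIS ratio",
                             100 * x$noise_cv), "\n")
  cat("  outcomes:", paste(vapply(x$outcome_specs, `[[`, "", "name"),
                           collapse = ", "), "\n")
  cat("  seed:    ", x$seed, "\n")
  invisible(x)
}
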