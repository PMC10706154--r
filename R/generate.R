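#' Generate a synthetic MRM cohort with known ground truth
#'
#' Draws per-subject true protein concentrations from independent per-protein
#' log-normal laws (baseline log10 mean/SD plus group-specific log10
#' fold-changes), clinical covariates tied to chosen proteins through a
#' Gaussian copula on the shared latent normal (targeting a Spearman
#' correlation without constraining the covariate marginal), and binary
#' outcomes drawn Bernoulli from a known logistic model on engineered
#' features of the true concentrations. Fixing `config$seed` makes the result
#' reproducible to the last digit.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: `true_concentrations`
#'   (samples x proteins, fmol/uL), `group_labels`, `covariates`, `outcomes`,
#'   `linear_predictors`, and `config` (the retained ground truth).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- config$panel
  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n <- length(groups)
  p <- nrow(panel)
  sample_ids <- sprintf("%s_%02d", groups,
                        unlist(lapply(config$group_sizes, seq_len)))

  # per-(protein, group) log10 shift
  shift <- matrix(0, nrow = p, ncol = length(config$group_sizes),
                  dimnames = list(panel$protein_id,
                                  names(config$group_sizes)))
  if (nrow(config$effect_table)) {
    for (k in seq_len(nrow(config$effect_table))) {
      e <- config$effect_table[k, ]
      shift[e$protein_id, e$group] <- shift[e$protein_id, e$group] + e$log10_fc
    }
  }

  out <- with_local_seed(stage_seed(config$seed, 1), {
    z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
    log10_conc <- sweep(z, 2, panel$log10_sd, `*`)
    log10_conc <- sweep(log10_conc, 2, panel$log10_mean, `+`)
    log10_conc <- log10_conc + t(shift[, groups, drop = FALSE])
    conc <- 10^log10_conc
    dimnames(conc) <- list(sample_ids, panel$protein_id)

    covariates <- data.frame(sample_id = sample_ids,
                             stringsAsFactors = FALSE)
    if (nrow(config$covariate_spec)) {
      for (k in seq_len(nrow(config$covariate_spec))) {
        cs <- config$covariate_spec[k, ]
        # bivariate-normal rho achieving the target Spearman correlation
        rho <- 2 * sin(pi * cs$spearman / 6)
        zj <- z[, match(cs$protein_id, panel$protein_id)]
        w <- rho * zj + sqrt(1 - rho^2) * stats::rnorm(n)
        covariates[[cs$covariate]] <- cs$mean + cs$sd * w
      }
    }

    outcomes <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
    linpred <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
    for (os in config$outcome_specs) {
      beta <- resolve_outcome_beta(os, panel)
      f <- evaluate_features(conc, os$features)
      eta <- drop(cbind(1, f) %*% beta)
      outcomes[[os$name]] <- stats::rbinom(n, 1, stats::plogis(eta))
      linpred[[os$name]] <- eta
    }
    list(conc = conc, covariates = covariates, outcomes = outcomes,
         linpred = linpred)
  })

  structure(
    list(true_concentrations = out$conc,
         group_labels = stats::setNames(groups, sample_ids),
         covariates = out$covariates,
         outcomes = out$outcomes,
         linear_predictors = out$linpred,
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic MRM cohort:", nrow(x$true_concentrations), "samples x",
      ncol(x$true_concentrations), "proteins\n")
  print(table(x$group_labels))
  invisible(x)
}

#' Sample metadata table of a synthetic cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @return data.frame with `sample_id`, `group`, covariates and outcomes.
#' @export
cohort_metadata <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  md <- data.frame(sample_id = names(cohort$group_labels),
                   group = unname(cohort$group_labels),
                   stringsAsFactors = FALSE)
  md <- merge(md, cohort$covariates, by = "sample_id", sort = FALSE)
  merge(md, cohort$outcomes, by = "sample_id", sort = FALSE)
}

#' Simulate transition-level NAT/SIS measurements for a cohort
#'
#' Inverts the quantitation model: for every sample x protein the error-free
#' NAT/SIS area ratio is `slope * concentration + intercept` (the protein's
#' true calibration line), multiplied by `(1 + e)`, `e ~ N(0, noise_cv)`
#' (proportional-CV noise, the regime 1/x^2-weighted regression is optimal
#' for). Ratios are floored at 1e-9 to keep them positive. The SIS spike is
#' reported at a fixed nominal area so `nat_area / sis_area` reproduces the
#' simulated ratio.
#'
#' @param cohort a `synthetic_cohort`.
#' @param config defaults to the cohort's own configuration.
#' @return data.frame with columns `protein_id`, `peptide`, `sample_id`,
#'   `nat_area`, `sis_area`, `ratio` (one proteotypic peptide per protein).
#' @export
generate_transition_records <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  panel <- config$panel
  conc <- cohort$true_concentrations
  if (!all(colnames(conc) %in% panel$protein_id)) {
    stop_mrm("calibration truth missing for some proteins",
             class = "config_error")
  }
  idx <- match(colnames(conc), panel$protein_id)
  true_ratio <- sweep(conc, 2, panel$slope[idx], `*`)
  true_ratio <- sweep(true_ratio, 2, panel$intercept[idx], `+`)
  measured <- with_local_seed(stage_seed(config$seed, 2), {
    eps <- matrix(stats::rnorm(length(true_ratio), sd = config$noise_cv),
                  nrow = nrow(true_ratio))
    pmax(true_ratio * (1 + eps), 1e-9)
  })
  sis_area <- 1e5
  data.frame(
    protein_id = rep(colnames(conc), each = nrow(conc)),
    peptide = rep(paste0("PEP_", colnames(conc)), each = nrow(conc)),
    sample_id = rep(rownames(conc), times = ncol(conc)),
    nat_area = as.vector(measured) * sis_area,
    sis_area = sis_area,
    ratio = as.vector(measured),
    stringsAsFactors = FALSE
  )
}

#' Simulate a calibration dilution series for every panel protein
#'
#' Each calibration point carries a known spiked concentration and a
#' simulated NAT/SIS ratio under the same proportional-CV noise model as the
#' cohort measurements.
#'
#' @param config a [cohort_config()].
#' @param levels strictly positive concentrations (fmol/uL); `relative = TRUE`
#'   interprets them as multiples of each protein's LLOQ so one series design
#'   spans every protein's own working range.
#' @param relative see `levels`.
#' @return data.frame with columns `protein_id`, `concentration`, `ratio`.
#' @export
generate_calibration_series <- function(config,
                                        levels = c(1, 2, 5, 10, 20, 50, 100,
                                                   200),
                                        relative = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(levels) < 2 || any(levels <= 0)) {
    stop_mrm("need >= 2 strictly positive calibration levels (1/x^2 weights are undefined at 0)",
             class = "config_error")
  }
  panel <- config$panel
  protein <- rep(panel$protein_id, each = length(levels))
  slope <- rep(panel$slope, each = length(levels))
  intercept <- rep(panel$intercept, each = length(levels))
  conc <- rep(levels, times = nrow(panel))
  if (relative) {
    conc <- conc * rep(panel$lloq, each = length(levels))
  }
  true_ratio <- slope * conc + intercept
  ratio <- with_local_seed(stage_seed(config$seed, 3), {
    pmax(true_ratio * (1 + stats::rnorm(length(true_ratio),
                                        sd = config$noise_cv)), 1e-9)
  })
  data.frame(protein_id = protein, concentration = conc, ratio = ratio,
             stringsAsFactors = FALSE)
}

# weighted AUC of a logistic outcome model: P(f_case > f_control) where the
# case/control mixture is induced by p = plogis(eta); O(n log n) via sorting
weighted_auc_from_eta <- function(f, eta) {
  o <- order(f)
  p <- stats::plogis(eta[o])
  q <- 1 - p
  # sum over i of p_i * (number-weight of controls with smaller f)
  num <- sum(p * (cumsum(q) - q))
  num / (sum(p) * sum(q))
}

#' Size a standardized outcome effect for a target true AUC
#'
#' For a single-feature logistic outcome `logit p = s * (f - mean)/sd`, finds
#' by bisection the standardized slope `s` whose population AUC (probability
#' that a random case outranks a random control on the feature) equals
#' `target_auc`, using a large deterministic Monte-Carlo draw from the
#' feature's closed-form baseline law.
#'
#' @param panel panel data.frame.
#' @param feature feature descriptor.
#' @param target_auc desired generating-model AUC.
#' @param n_mc Monte-Carlo draw size.
#' @param seed RNG seed for the draw.
#' @return standardized slope suitable for [outcome_spec()]'s `slope_sd`.
#' @export
calibrate_outcome_slope <- function(panel, feature, target_auc = 0.9,
                                    n_mc = 200000, seed = 20260101) {
  prm <- feature_lnorm_params(feature, panel)
  f <- with_local_seed(seed, stats::rlnorm(n_mc, prm[["mu"]], prm[["sigma"]]))
  m <- exp(prm[["mu"]] + prm[["sigma"]]^2 / 2)
  s <- m * sqrt(exp(prm[["sigma"]]^2) - 1)
  z <- (f - m) / s
  auc_of <- function(b) weighted_auc_from_eta(f, b * z)
  lo <- 1e-3
  hi <- 50
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (auc_of(mid) < target_auc) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Monte-Carlo true AUC of an outcome specification
#'
#' The population AUC of the generating logistic model (the discriminability
#' ceiling any fitted classifier is compared against), estimated on a large
#' draw from the baseline concentration law.
#'
#' @param config a [cohort_config()].
#' @param spec an [outcome_spec()] from `config` (default: first).
#' @param n_mc Monte-Carlo draw size.
#' @param seed RNG seed.
#' @export
outcome_true_auc <- function(config, spec = config$outcome_specs[[1]],
                             n_mc = 200000, seed = 20260102) {
  panel <- config$panel
  beta <- resolve_outcome_beta(spec, panel)
  prot <- unique(unlist(lapply(spec$features, `[[`, "proteins")))
  conc <- with_local_seed(seed, {
    idx <- match(prot, panel$protein_id)
    m <- matrix(stats::rnorm(n_mc * length(prot)), nrow = n_mc)
    m <- sweep(m, 2, panel$log10_sd[idx], `*`)
    m <- sweep(m, 2, panel$log10_mean[idx], `+`)
    m <- 10^m
    colnames(m) <- prot
    m
  })
  fmat <- evaluate_features(conc, spec$features)
  eta <- drop(cbind(1, fmat) %*% beta)
  weighted_auc_from_eta(eta, eta)
}
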