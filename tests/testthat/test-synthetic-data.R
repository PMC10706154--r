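small_config <- function(seed = 1, noise_cv = 0.05, n_proteins = 6,
                         group_sizes = c(case = 5, control = 5),
                         effect_table = data.frame(protein_id = character(0),
                                                   group = character(0),
                                                   log10_fc = numeric(0)),
                         ...) {
  cohort_config(group_sizes = group_sizes,
                panel = default_panel(n_proteins),
                effect_table = effect_table,
                noise_cv = noise_cv,
                outcome_specs = list(
                  outcome_spec(list(feat_raw("A2M")), slope_sd = 1,
                               name = "event")),
                covariate_spec = default_covariate_spec()[0, ],
                seed = seed, ...)
}

test_that("same config and seed give byte-identical cohorts and records", {
  cfg <- small_config(seed = 33)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_identical(generate_transition_records(c1),
                   generate_transition_records(c2))
  expect_identical(generate_calibration_series(cfg),
                   generate_calibration_series(cfg))
})

test_that("null effect table leaves only sampling noise between groups", {
  cfg <- small_config(seed = 5, group_sizes = c(case = 10000,
                                                control = 10000))
  co <- generate_cohort(cfg)
  a <- co$true_concentrations[co$group_labels == "case", "A2M"]
  b <- co$true_concentrations[co$group_labels == "control", "A2M"]
  expect_lt(abs(cohen_d(a, b)), 0.1)
})

test_that("a configured log10 fold-change moves the geometric mean ratio accordingly", {
  cfg <- small_config(
    seed = 8, group_sizes = c(case = 10000, control = 10000),
    effect_table = data.frame(protein_id = "A2M", group = "case",
                              log10_fc = 0.3))
  co <- generate_cohort(cfg)
  a <- co$true_concentrations[co$group_labels == "case", "A2M"]
  b <- co$true_concentrations[co$group_labels == "control", "A2M"]
  gm_ratio <- exp(mean(log(a)) - mean(log(b)))
  expect_lt(abs(gm_ratio / 10^0.3 - 1), 0.01)
})

test_that("zero-noise transition records carry the exact calibration line", {
  panel <- default_panel(3)
  panel$slope <- 1
  panel$intercept <- 0
  cfg <- cohort_config(group_sizes = c(g1 = 3, g2 = 3), panel = panel,
                       effect_table = default_effect_table()[0, ],
                       noise_cv = 0,
                       outcome_specs = list(
                         outcome_spec(list(feat_raw(panel$protein_id[1])),
                                      slope_sd = 1)),
                       covariate_spec = default_covariate_spec()[0, ],
                       seed = 2)
  co <- generate_cohort(cfg)
  rec <- generate_transition_records(co)
  conc_by_record <- co$true_concentrations[cbind(rec$sample_id,
                                                 rec$protein_id)]
  expect_equal(rec$ratio, unname(conc_by_record), tolerance = 1e-14)
})

test_that("empirical CV of back-calculated concentrations matches the noise model", {
  # 1,000 replicate measurements of one analyte at 5% ratio CV
  panel <- default_panel(1)
  panel$log10_sd <- 0  # constant true concentration: no biological variance
  cfg <- cohort_config(group_sizes = c(g = 1000), panel = panel,
                       effect_table = default_effect_table()[0, ],
                       noise_cv = 0.05,
                       outcome_specs = list(
                         outcome_spec(list(feat_raw(panel$protein_id[1])),
                                      true_beta = c(0, 0))),
                       covariate_spec = default_covariate_spec()[0, ],
                       seed = 77)
  co <- generate_cohort(cfg)
  rec <- generate_transition_records(co)
  curves <- list(truth_curve(panel$protein_id[1], slope = panel$slope[1]))
  names(curves) <- panel$protein_id[1]
  conc <- quantify(rec, curves)
  cv <- stats::sd(conc) / mean(conc)
  expect_gt(cv, 0.045)
  expect_lt(cv, 0.055)
})

test_that("calibration series reproduces known ratios without noise", {
  panel <- default_panel(1)
  panel$slope <- 2
  panel$intercept <- 0
  cfg <- cohort_config(group_sizes = c(g = 2), panel = panel,
                       effect_table = default_effect_table()[0, ],
                       noise_cv = 0,
                       outcome_specs = list(
                         outcome_spec(list(feat_raw(panel$protein_id[1])),
                                      slope_sd = 1)),
                       covariate_spec = default_covariate_spec()[0, ],
                       seed = 3)
  ser <- generate_calibration_series(cfg, levels = c(1, 2, 4),
                                     relative = FALSE)
  expect_equal(ser$ratio, c(2, 4, 8))
  # round-trip: fitting recovers the truth exactly
  curve <- fit_calibration(ser, lloq = 1, protein_id = panel$protein_id[1])
  expect_equal(curve$slope, 2, tolerance = 1e-12)
  expect_equal(curve$intercept, 0, tolerance = 1e-12)
  expect_error(generate_calibration_series(cfg, levels = c(0, 1),
                                           relative = FALSE),
               class = "config_error")
})

test_that("outcome event rate converges to the generating logistic mean", {
  cfg <- small_config(seed = 10, group_sizes = c(g = 20000))
  co <- generate_cohort(cfg)
  p_true <- stats::plogis(co$linear_predictors$event)
  expected <- mean(p_true)
  observed <- mean(co$outcomes$event)
  mc_se <- sqrt(sum(p_true * (1 - p_true))) / length(p_true)
  expect_lt(abs(observed - expected), 3 * mc_se)
})

test_that("copula covariates achieve their target Spearman correlation", {
  cfg <- cohort_config(group_sizes = c(g = 20000),
                       panel = default_panel(25),
                       effect_table = default_effect_table()[0, ],
                       noise_cv = 0.05,
                       outcome_specs = list(
                         outcome_spec(list(feat_raw("A2M")), slope_sd = 1)),
                       covariate_spec = default_covariate_spec(),
                       seed = 12)
  co <- generate_cohort(cfg)
  for (k in seq_len(nrow(cfg$covariate_spec))) {
    cs <- cfg$covariate_spec[k, ]
    rho <- stats::cor(co$true_concentrations[, cs$protein_id],
                      co$covariates[[cs$covariate]], method = "spearman")
    expect_lt(abs(rho - cs$spearman), 0.03)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(small_config(group_sizes = c(a = 1, b = 5)),
               class = "config_error")
  expect_error(small_config(noise_cv = -0.1), class = "config_error")
  expect_error(
    cohort_config(outcome_specs = list(
      outcome_spec(list(feat_raw("NOT_A_PROTEIN")), slope_sd = 1))),
    class = "config_error")
  expect_error(outcome_spec(list(), true_beta = 1), class = "config_error")
  expect_error(outcome_spec(list(feat_raw("A2M")), true_beta = c(1, 2, 3)),
               class = "config_error")
})

test_that("effect sizing helper hits its target AUC", {
  panel <- default_panel(10)
  s <- calibrate_outcome_slope(panel, feat_square("A2M"), target_auc = 0.9)
  cfg <- cohort_config(group_sizes = c(case = 5, control = 5),
                       panel = panel,
                       effect_table = default_effect_table()[0, ],
                       outcome_specs = list(
                         outcome_spec(list(feat_square("A2M")),
                                      slope_sd = s, name = "event")),
                       covariate_spec = default_covariate_spec()[0, ],
                       seed = 4)
  expect_lt(abs(outcome_true_auc(cfg) - 0.9), 0.01)
})
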