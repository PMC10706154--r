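test_that("feature expansion counts and values follow the grammar", {
  conc <- matrix(c(2, 3), nrow = 1, dimnames = list("s1", c("A", "B")))
  quad <- expand_features(conc, "quadratic")
  expect_equal(unname(quad$X[1, ]), c(2, 3, 4, 9, 6))
  expect_equal(colnames(quad$X), c("A", "B", "A^2", "B^2", "A*B"))

  conc3 <- matrix(runif(12, 1, 2), nrow = 4,
                  dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  expect_equal(ncol(expand_features(conc3, "quadratic")$X), 9)  # 3+3+3
  rat <- expand_features(conc3, "ratio")
  expect_equal(ncol(rat$X), 9)                                  # 3+6
  expect_false(anyDuplicated(colnames(rat$X)) > 0)
  expect_equal(rat$X[, "A/B"], conc3[, "A"] / conc3[, "B"])
  conc0 <- conc3
  conc0[1, 1] <- 0
  expect_error(expand_features(conc0, "ratio"), class = "validation_error")
})

test_that("VIP filter keeps informative features and errors on empty selection", {
  set.seed(5)
  n <- 30
  y <- rep(0:1, each = n / 2)
  conc <- matrix(exp(rnorm(n * 4, 1)), n,
                 dimnames = list(paste0("s", seq_len(n)),
                                 c("SIG", "N1", "N2", "N3")))
  conc[, "SIG"] <- conc[, "SIG"] * exp(0.8 * as.numeric(y))
  ex <- expand_features(conc, "quadratic")
  sel <- vip_filter(ex, y, threshold = 1)
  kinds <- sel$provenance
  expect_true(any(kinds$protein_1 == "SIG" |
                    (!is.na(kinds$protein_2) & kinds$protein_2 == "SIG")))
  # threshold 0 retains every non-constant feature
  all_in <- vip_filter(ex, y, threshold = 0)
  expect_equal(ncol(all_in$X), ncol(ex$X))
  expect_error(vip_filter(ex, y, threshold = 1e6),
               class = "empty_selection_error")
})

test_that("identical feature copies share one VIP so the filter treats them alike", {
  set.seed(41)
  n <- 20
  y <- rep(0:1, each = 10)
  base <- rnorm(n) + as.numeric(y)
  X <- cbind(c1 = base, c2 = base, c3 = base)
  m <- fit_opls_da(autoscale(X), y, n_orthogonal = 0)
  v <- compute_vip(m)
  expect_equal(max(v) - min(v), 0, tolerance = 1e-10)
})

test_that("logistic fit matches closed forms on saturated designs", {
  # intercept-only with balanced outcomes
  m0 <- fit_logistic(matrix(numeric(0), nrow = 20, ncol = 0),
                     rep(0:1, each = 10))
  expect_equal(unname(m0$beta), 0, tolerance = 1e-10)

  # 2x2 design: x=0 -> 2/10 events, x=1 -> 8/10 events
  x <- rep(c(0, 1), each = 10)
  y <- c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2))
  m <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y)
  expect_equal(unname(m$beta["x"]), log(16), tolerance = 1e-8)
  expect_equal(unname(m$beta["(Intercept)"]), log(2 / 8), tolerance = 1e-8)
  expect_equal(sqrt(m$vcov["x", "x"]), sqrt(1 / 2 + 1 / 8 + 1 / 8 + 1 / 2),
               tolerance = 1e-8)
  expect_equal(m$aic, -2 * m$loglik + 2 * 2)
  # Wald inference for the slope: z ~ 2.48, retained at alpha = 0.05
  wt <- wald_table(m)
  z_x <- wt$z[wt$variable == "x"]
  expect_equal(z_x, log(16) / sqrt(1.25), tolerance = 1e-6)
  expect_lt(wt$p[wt$variable == "x"], 0.05)
  expect_identical(prune_by_pvalue(m)$variables, "x")
  # predicted probability at the linear-predictor zero is one half
  expect_equal(stats::plogis(0), 0.5)
})

test_that("logistic fit raises typed errors and flags separation", {
  X <- matrix(rnorm(10), dimnames = list(NULL, "a"))
  expect_error(fit_logistic(X, rep(1, 10)), class = "validation_error")
  expect_error(fit_logistic(cbind(X, b = X[, 1] * 2), rep(0:1, 5)),
               class = "singular_design_error")
  expect_error(fit_logistic(matrix(rnorm(12), 3), rep(0:1, length.out = 3)),
               class = "validation_error")
  y <- rep(0:1, each = 10)
  sep <- fit_logistic(matrix(as.numeric(y), dimnames = list(NULL, "x")), y)
  expect_true(sep$separation)
  expect_false(sep$converged)
})

test_that("backward AIC elimination drops noise, keeps signal, and matches the subset oracle", {
  set.seed(92)
  n <- 200
  X <- cbind(sig = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * X[, "sig"]))
  full <- fit_logistic(X, y)
  red <- stepwise_aic(full)
  expect_true("sig" %in% red$variables)
  path <- attr(red, "aic_path")
  expect_true(all(diff(path) < 0))
  expect_lte(red$aic, full$aic)
  # greedy backward reaches the exhaustive 2^3-subset optimum here
  oracle <- exhaustive_aic_best(X, y)
  expect_equal(sort(red$variables), sort(oracle$vars))
  expect_equal(red$aic, oracle$aic, tolerance = 1e-6)
})

test_that("all-noise designs usually collapse toward the intercept-only model", {
  keep_counts <- vapply(1:40, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(200 * 3), 200, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(200, 1, 0.5)
    length(stepwise_aic(fit_logistic(X, y))$variables)
  }, numeric(1))
  expect_gt(mean(keep_counts == 0), 0.5)
})

test_that("p-value pruning is a fixed point on significant models and removes weak terms", {
  set.seed(17)
  n <- 300
  X <- cbind(strong = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X[, "strong"]))
  m <- fit_logistic(X, y)
  expect_identical(prune_by_pvalue(m)$variables, m$variables)
  X2 <- cbind(X, weak = rnorm(n))
  m2 <- fit_logistic(X2, y)
  pruned <- prune_by_pvalue(m2)
  expect_false("weak" %in% pruned$variables)
  # a lone non-significant variable leaves intercept-only
  yr <- rbinom(n, 1, 0.5)
  lone <- prune_by_pvalue(fit_logistic(cbind(v = rnorm(n)), yr))
  expect_length(lone$variables, 0)
})

test_that("LOOCV covers each sample once, is order-invariant, and separates strong clusters", {
  set.seed(61)
  n <- 30
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n, mean = 6 * y), dimnames = list(NULL, "x"))
  cv <- loocv_predict(X, y)
  expect_length(cv$probabilities, n)
  expect_true(all(cv$probabilities[y == 1] >= 0.9))
  expect_true(all(cv$probabilities[y == 0] <= 0.1))
  perm <- sample(n)
  cvp <- loocv_predict(X[perm, , drop = FALSE], y[perm])
  expect_equal(sort(cvp$probabilities), sort(cv$probabilities),
               tolerance = 1e-10)
  expect_error(loocv_predict(X[1:2, , drop = FALSE], y[1:2]),
               class = "validation_error")
})

test_that("threshold selection maximizes sensitivity + specificity with the stated tie-break", {
  sep <- select_threshold(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(sep$threshold, 0.8)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  flat <- select_threshold(rep(0.4, 6), rep(0:1, 3))
  expect_equal(flat$sensitivity + flat$specificity, 1)

  mixed <- select_threshold(c(0.9, 0.4, 0.1, 0.6), c(1, 1, 0, 0))
  # exhaustive scan over all 4 candidate cuts: best sum is 1.5 at 0.4
  cand <- sort(unique(c(0.9, 0.4, 0.1, 0.6)))
  sums <- vapply(cand, function(thr) {
    pos <- c(0.9, 0.4, 0.1, 0.6) >= thr
    sum(pos & c(1, 1, 0, 0) == 1) / 2 + sum(!pos & c(1, 1, 0, 0) == 0) / 2
  }, numeric(1))
  expect_equal(mixed$sensitivity + mixed$specificity, max(sums))
  expect_equal(mixed$threshold, 0.4)
})

test_that("rank AUC equals the Mann-Whitney U identity and pair enumeration", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(compute_auc(c(0.9, 0.4, 0.1, 0.6), c(1, 1, 0, 0)), 0.75)
  set.seed(29)
  for (i in 1:20) {
    n1 <- sample(3:12, 1)
    n0 <- sample(3:12, 1)
    prob <- round(runif(n1 + n0), 2)  # induce some ties
    y <- c(rep(1, n1), rep(0, n0))
    u <- unname(suppressWarnings(
      wilcox.test(prob[y == 1], prob[y == 0])$statistic))
    expect_equal(compute_auc(prob, y), u / (n1 * n0), tolerance = 1e-12)
  }
  expect_error(compute_auc(runif(5), rep(1, 5)), class = "validation_error")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  prob <- runif(40)
  y <- rbinom(40, 1, prob)
  skip_if(length(unique(y)) < 2)
  ext <- as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                        direction = "<")))
  expect_equal(compute_auc(prob, y), ext, tolerance = 1e-10)
})

test_that("report assembly validates its schema and round-trips predictions", {
  set.seed(73)
  n <- 40
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n, 2 * y), dimnames = list(NULL, "m"))
  model <- fit_logistic(X, y)
  cv <- loocv_predict(X, y)
  thr <- select_threshold(cv$probabilities, y)
  auc <- compute_auc(cv$probabilities, y)
  rep <- build_report("demo", model, cv, thr, auc)
  expect_s3_class(rep, "model_report")
  expect_true(all(rep$variables$ci_low <= rep$variables$beta &
                    rep$variables$beta <= rep$variables$ci_high))
  flat <- as.data.frame(rep)
  expect_equal(unique(flat$auc), auc)
  p <- predict_report(rep, c(m = 0.5))
  expect_gt(p, 0)
  expect_lt(p, 1)
})

test_that("cascade recovers a quadratic single-protein outcome end to end", {
  panel <- default_panel(8)
  slope <- calibrate_outcome_slope(panel, feat_square("A2M"),
                                   target_auc = 0.9)
  cfg <- cohort_config(
    group_sizes = c(case = 50, control = 50), panel = panel,
    effect_table = default_effect_table()[0, ],
    outcome_specs = list(outcome_spec(list(feat_square("A2M")),
                                      slope_sd = slope, name = "event")),
    covariate_spec = default_covariate_spec()[0, ], seed = 303)
  co <- generate_cohort(cfg)
  rep <- build_model(co$true_concentrations, co$outcomes$event,
                     mode = "quadratic", contrast = "recovery")
  prov <- attr(rep, "stages")$final$variables
  expect_true(any(grepl("A2M", prov)))
  expect_lt(abs(rep$auc - outcome_true_auc(cfg)), 0.1)
})
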