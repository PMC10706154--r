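#' Leave-one-out cross-validated predicted probabilities
#'
#' For every sample the coefficients are refitted on the remaining n-1
#' observations (the variable set stays fixed; selection is not re-run per
#' fold) and the held-out probability is predicted. Folds whose training set
#' lacks a class, or whose refit fails, fall back to the full-data model and
#' are counted.
#'
#' @param X samples x variables design matrix (the final model's variables).
#' @param y binary 0/1 outcome.
#' @param variables columns of `X` to use (default all).
#' @return list: `probabilities` (out-of-fold, in sample order),
#'   `n_fallback` folds that used the full-data model, `n_separation` folds
#'   whose refit hit perfect separation.
#' @export
loocv_predict <- function(X, y, variables = colnames(X)) {
  X <- as.matrix(X)
  if (!is.null(variables)) X <- X[, variables, drop = FALSE]
  n <- nrow(X)
  if (n < 3) {
    stop_mrm("LOOCV needs n >= 3", class = "validation_error")
  }
  full <- fit_logistic(X, y)
  prob <- numeric(n)
  n_fallback <- 0L
  n_sep <- 0L
  for (i in seq_len(n)) {
    fit_i <- tryCatch({
      if (length(unique(y[-i])) < 2) NULL else {
        fit_logistic(X[-i, , drop = FALSE], y[-i])
      }
    }, error = function(e) NULL)
    if (is.null(fit_i)) {
      n_fallback <- n_fallback + 1L
      fit_i <- full
    } else if (fit_i$separation) {
      n_sep <- n_sep + 1L
    }
    eta <- sum(c(1, X[i, ]) * fit_i$beta)
    prob[i] <- stats::plogis(eta)
  }
  list(probabilities = prob, n_fallback = n_fallback, n_separation = n_sep)
}

#' Youden-optimal probability threshold
#'
#' Scans every observed predicted probability as a candidate cut (rule:
#' `p >= threshold` is called positive, ties count as positive) and returns
#' the one maximizing sensitivity + specificity; ties are broken toward the
#' smallest threshold.
#'
#' @param probabilities predicted probabilities.
#' @param y binary 0/1 outcome (both classes present).
#' @return list: `threshold`, `sensitivity`, `specificity`.
#' @export
select_threshold <- function(probabilities, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_mrm("both classes must be present", class = "validation_error")
  }
  cand <- sort(unique(probabilities))
  best <- NULL
  for (thr in cand) {
    pos <- probabilities >= thr
    sens <- sum(pos & y == 1) / n1
    spec <- sum(!pos & y == 0) / n0
    if (is.null(best) || sens + spec > best$sensitivity + best$specificity) {
      best <- list(threshold = thr, sensitivity = sens, specificity = spec)
    }
  }
  best
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic with midrank tie handling: the probability that a random event
#' outranks a random non-event (ties count one half).
#'
#' @param probabilities predicted probabilities (any monotone score works).
#' @param y binary 0/1 outcome (both classes present).
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(probabilities, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_mrm("AUC needs both classes", class = "validation_error")
  }
  r <- rank(probabilities)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble a diagnostic model report
#'
#' Collects the final model's variables with Wald inference (coefficient,
#' confidence interval, Z, P), the cross-validated operating point
#' (threshold, sensitivity, specificity) and AUC into the flat report schema
#' used for the diagnostic and prognostic classifiers.
#'
#' @param contrast contrast label (e.g. "early_IUGR vs early_control").
#' @param model the final `logistic_model`.
#' @param cv result of [loocv_predict()] (or NULL when not cross-validated).
#' @param threshold result of [select_threshold()].
#' @param auc AUC of the reported probabilities.
#' @param level confidence level for the Wald intervals.
#' @return object of class `model_report`.
#' @export
build_report <- function(contrast, model, cv, threshold, auc, level = 0.95) {
  wt <- wald_table(model, level = level)
  rep <- structure(
    list(contrast = contrast,
         variables = wt[, c("variable", "beta", "ci_low", "ci_high", "z",
                            "p")],
         threshold = threshold$threshold,
         sensitivity = threshold$sensitivity,
         specificity = threshold$specificity,
         auc = auc,
         cross_validation = if (is.null(cv)) "none" else "loocv",
         n_fallback_folds = if (is.null(cv)) 0L else cv$n_fallback,
         n_separation_warnings = if (is.null(cv)) as.integer(model$separation)
           else cv$n_separation + as.integer(model$separation)),
    class = "model_report"
  )
  validate_model_report(rep)
  rep
}

#' Validate a model report against the schema
#'
#' @param report a `model_report`.
#' @return the report, invisibly; errors on violation.
#' @export
validate_model_report <- function(report) {
  stopifnot(inherits(report, "model_report"))
  v <- report$variables
  need <- c("variable", "beta", "ci_low", "ci_high", "z", "p")
  if (!all(need %in% names(v))) {
    stop_mrm("report variables table lacks column(s): %s",
             paste(setdiff(need, names(v)), collapse = ", "),
             class = "validation_error")
  }
  for (m in c("sensitivity", "specificity", "auc")) {
    val <- report[[m]]
    if (!is.na(val) && (val < 0 || val > 1)) {
      stop_mrm("%s must lie in [0, 1]", m, class = "validation_error")
    }
  }
  ok_ci <- is.na(v$beta) | (v$ci_low <= v$beta & v$beta <= v$ci_high)
  if (!all(ok_ci)) {
    stop_mrm("confidence interval does not contain beta for: %s",
             paste(v$variable[!ok_ci], collapse = ", "),
             class = "validation_error")
  }
  invisible(report)
}

#' Evaluate a reported logistic model on new feature values
#'
#' Applies the report's model form `p = 1 / (1 + exp(-(b0 + sum b_k x_k)))`
#' to a named vector or matrix of engineered-feature values.
#'
#' @param report a `model_report`.
#' @param x named vector (or samples x variables matrix) of feature values
#'   matching the report's non-intercept variables.
#' @return predicted probability(ies).
#' @export
predict_report <- function(report, x) {
  v <- report$variables
  b0 <- v$beta[v$variable == "(Intercept)"]
  vars <- v$variable[v$variable != "(Intercept)"]
  beta <- v$beta[v$variable != "(Intercept)"]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  miss <- setdiff(vars, colnames(x))
  if (length(miss)) {
    stop_mrm("missing feature value(s): %s", paste(miss, collapse = ", "),
             class = "validation_error")
  }
  stats::plogis(drop(b0 + x[, vars, drop = FALSE] %*% beta))
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("Model report [%s]\n", x$contrast))
  cat(sprintf("  sensitivity %.3f | specificity %.3f | AUC %.3f | threshold %.4f (%s)\n",
              x$sensitivity, x$specificity, x$auc, x$threshold,
              x$cross_validation))
  if (x$n_separation_warnings > 0) {
    cat(sprintf("  separation warnings: %d\n", x$n_separation_warnings))
  }
  print(x$variables, row.names = FALSE)
  invisible(x)
}

#' Flatten a model report to one data.frame
#'
#' One row per variable, performance columns repeated, mirroring the flat
#' table layout used to publish such classifiers.
#'
#' @param x a `model_report`.
#' @param ... unused.
#' @export
as.data.frame.model_report <- function(x, ...) {
  data.frame(contrast = x$contrast,
             sensitivity = x$sensitivity,
             specificity = x$specificity,
             auc = x$auc,
             threshold = x$threshold,
             x$variables,
             stringsAsFactors = FALSE)
}

#' Run the full biomarker model-building cascade
#'
#' The model-building sequence for one contrast: engineered-feature expansion
#' of the quant matrix, OPLS-DA VIP > `vip_threshold` filter, a cap at the
#' top `max_candidates` features by VIP (so the full logistic fit satisfies
#' n > number of coefficients), maximum-likelihood logistic fit, backward AIC
#' elimination, Wald p-value pruning at `alpha`, leave-one-out
#' cross-validation of the final variable set, and Youden threshold selection
#' on the out-of-fold probabilities.
#'
#' @param quant a `protein_quant_matrix` (or positive concentration matrix).
#' @param y binary 0/1 outcome aligned with the samples.
#' @param mode feature grammar: `"quadratic"` (diagnosis) or `"ratio"`
#'   (prognosis).
#' @param contrast label stored on the report.
#' @param vip_threshold VIP cut (default 1).
#' @param n_orthogonal orthogonal OPLS components (default 1).
#' @param alpha Wald pruning level (default 0.05).
#' @param max_candidates cap on the post-VIP candidate set (default `n - 2`).
#' @return a `model_report`; the intermediate objects are attached as
#'   attribute `"stages"` (expanded, vip, full/step/final models, cv).
#' @export
build_model <- function(quant, y, mode = c("quadratic", "ratio"),
                        contrast = "model", vip_threshold = 1,
                        n_orthogonal = 1, alpha = 0.05,
                        max_candidates = NULL) {
  mode <- match.arg(mode)
  expanded <- expand_features(quant, mode)
  n <- nrow(expanded$X)
  if (is.null(max_candidates)) max_candidates <- max(1L, n - 2L)
  selected <- vip_filter(expanded, y, threshold = vip_threshold,
                         n_orthogonal = n_orthogonal)
  vip <- attr(selected, "vip")
  keep <- colnames(selected$X)
  if (length(keep) > max_candidates) {
    ranked <- names(vip)[names(vip) %in% keep]
    keep <- ranked[seq_len(max_candidates)]
    selected <- subset_expanded(selected, keep)
  }
  full <- fit_logistic(selected$X, y)
  stepped <- stepwise_aic(full)
  final <- prune_by_pvalue(stepped, alpha = alpha)
  if (length(final$variables)) {
    cv <- loocv_predict(selected$X[, final$variables, drop = FALSE], y)
    prob <- cv$probabilities
  } else {
    cv <- NULL
    prob <- rep(stats::plogis(final$beta[["(Intercept)"]]), length(y))
  }
  thr <- select_threshold(prob, y)
  auc <- compute_auc(prob, y)
  report <- build_report(contrast, final, cv, thr, auc)
  attr(report, "stages") <- list(expanded_n_features = ncol(expanded$X),
                                 vip = vip, full = full, stepped = stepped,
                                 final = final, cv = cv,
                                 probabilities = prob)
  report
}
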