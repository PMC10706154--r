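#' Expand a protein panel into the engineered-feature grammar
#'
#' Quadratic mode (diagnostic task): raw concentrations, squares, and
#' unordered pairwise products (i < j), giving `k + k + k(k-1)/2` features.
#' Ratio mode (prognostic task): raw concentrations plus all ordered pairwise
#' ratios, giving `k + k(k-1)` features. Feature order is deterministic (raw
#' in panel order, then squares, then pairs) and each feature carries its
#' provenance.
#'
#' @param quant a `protein_quant_matrix`, or a samples x proteins matrix of
#'   strictly positive concentrations.
#' @param mode `"quadratic"` or `"ratio"`.
#' @return object of class `expanded_features`: `X` (samples x features),
#'   `provenance` (data.frame name/kind/protein_1/protein_2), `mode`.
#' @export
expand_features <- function(quant, mode = c("quadratic", "ratio")) {
  mode <- match.arg(mode)
  conc <- if (inherits(quant, "protein_quant_matrix")) {
    quant$concentrations
  } else {
    as.matrix(quant)
  }
  k <- ncol(conc)
  ids <- colnames(conc)
  if (is.null(ids)) {
    stop_mrm("concentration matrix needs protein column names",
             class = "validation_error")
  }
  if (mode == "ratio" && any(conc == 0)) {
    stop_mrm("ratio mode requires strictly positive concentrations",
             class = "validation_error")
  }
  feats <- lapply(ids, feat_raw)
  if (mode == "quadratic") {
    feats <- c(feats, lapply(ids, feat_square))
    if (k >= 2) {
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          feats <- c(feats, list(feat_product(ids[i], ids[j])))
        }
      }
    }
  } else {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j) feats <- c(feats, list(feat_ratio(ids[i], ids[j])))
      }
    }
  }
  X <- evaluate_features(conc, feats)
  prov <- data.frame(
    name = vapply(feats, feature_label, character(1)),
    kind = vapply(feats, `[[`, character(1), "kind"),
    protein_1 = vapply(feats, function(f) f$proteins[1], character(1)),
    protein_2 = vapply(feats, function(f)
      if (length(f$proteins) > 1) f$proteins[2] else NA_character_,
      character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(X = X, provenance = prov, mode = mode),
            class = "expanded_features")
}

#' @export
print.expanded_features <- function(x, ...) {
  cat(sprintf("Expanded feature matrix (%s mode): %d samples x %d features\n",
              x$mode, nrow(x$X), ncol(x$X)))
  invisible(x)
}

subset_expanded <- function(expanded, keep) {
  structure(list(X = expanded$X[, keep, drop = FALSE],
                 provenance = expanded$provenance[
                   match(keep, expanded$provenance$name), , drop = FALSE],
                 mode = expanded$mode),
            class = "expanded_features")
}

#' First-stage variable filter by OPLS-DA VIP
#'
#' Autoscales the expanded matrix, fits a two-class OPLS-DA, and retains the
#' features whose VIP exceeds `threshold` (constant features are dropped
#' before the fit and can never pass).
#'
#' @param expanded an `expanded_features` object.
#' @param y binary labels.
#' @param threshold VIP cut (default 1, the conventional importance line).
#' @param n_orthogonal orthogonal components removed before the predictive
#'   component.
#' @return the reduced `expanded_features`, with the full VIP table attached
#'   as attribute `"vip"`.
#' @export
vip_filter <- function(expanded, y, threshold = 1, n_orthogonal = 1) {
  stopifnot(inherits(expanded, "expanded_features"))
  sc <- autoscale(expanded$X)
  model <- fit_opls_da(sc, y, n_orthogonal = n_orthogonal)
  vip <- compute_vip(model)
  keep <- names(vip)[vip > threshold]
  if (!length(keep)) {
    stop_mrm("no feature exceeds VIP threshold %g (max VIP = %.4f)",
             threshold, max(vip), class = "empty_selection_error")
  }
  out <- subset_expanded(expanded, keep)
  attr(out, "vip") <- sort(vip, decreasing = TRUE)
  out
}

#' Maximum-likelihood logistic regression fit
#'
#' Binomial IRLS fit (via `stats::glm.fit`, deviance tolerance 1e-10, at most
#' 100 iterations) with the observed-information covariance. Perfect
#' separation is detected (monotone likelihood: fitted probabilities pinned
#' at 0/1) and reported as a flag rather than silently returning divergent
#' coefficients. No standardization is applied: coefficients stay on raw
#' concentration scales.
#'
#' @param X samples x variables design matrix (no intercept column; an
#'   intercept is always added).
#' @param y binary 0/1 outcome.
#' @return object of class `logistic_model`: `variables`, `beta` (intercept
#'   first), `vcov`, `loglik`, `aic`, `converged`, `separation`, plus the
#'   training data for downstream refits.
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(unique(y)) < 2) {
    stop_mrm("both outcome classes must be present", class = "validation_error")
  }
  if (n <= ncol(X) + 1) {
    stop_mrm("need n > number of coefficients (%d <= %d)", n, ncol(X) + 1,
             class = "validation_error")
  }
  Xd <- cbind(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    bad <- colnames(Xd)[-qrd$pivot[seq_len(qrd$rank)]]
    stop_mrm("singular design; collinear column(s): %s",
             paste(bad, collapse = ", "), class = "singular_design_error")
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("algorithm did not converge", msg)) {
        # already reflected in the converged flag
        invokeRestart("muffleWarning")
      }
    }
  )
  mu <- fit$fitted.values
  # monotone likelihood: probabilities pinned onto the observed classes
  # (finite coefficients can never fit exactly, so this means divergence)
  separation <- sep_warn || all(abs(y - mu) < 1e-6)
  eps <- .Machine$double.eps
  loglik <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  k <- ncol(Xd)
  W <- mu * (1 - mu)
  info <- crossprod(Xd, Xd * W)
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, k, k, dimnames = list(colnames(Xd), colnames(Xd)))
  })
  dimnames(vcov) <- list(colnames(Xd), colnames(Xd))
  structure(
    list(variables = if (is.null(colnames(X))) character(0) else colnames(X),
         beta = stats::setNames(fit$coefficients, colnames(Xd)),
         vcov = vcov,
         loglik = loglik,
         aic = -2 * loglik + 2 * k,
         converged = fit$converged && !separation,
         separation = separation,
         n = n, X = X, y = y),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic model: %d variable(s) + intercept, n = %d, AIC = %.3f%s\n",
              length(x$variables), x$n, x$aic,
              if (x$separation) " [perfect separation]" else ""))
  print(wald_table(x))
  invisible(x)
}

#' Wald inference table of a logistic model
#'
#' @param model a `logistic_model`.
#' @param level confidence level for the Wald intervals.
#' @return data.frame: `variable`, `beta`, `se`, `ci_low`, `ci_high`, `z`,
#'   `p`.
#' @export
wald_table <- function(model, level = 0.95) {
  se <- sqrt(diag(model$vcov))
  z <- model$beta / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    variable = names(model$beta),
    beta = unname(model$beta),
    se = unname(se),
    ci_low = unname(model$beta - q * se),
    ci_high = unname(model$beta + q * se),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
}

refit_on <- function(model, vars) {
  fit_logistic(model$X[, vars, drop = FALSE], model$y)
}

#' Backward stepwise elimination minimizing AIC
#'
#' At every step the variable whose removal yields the lowest AIC is dropped,
#' until no removal lowers the AIC. The intercept is never dropped; ties are
#' broken by dropping the feature that comes later in the canonical feature
#' order. The accepted AIC path is strictly decreasing by construction.
#'
#' @param model a fitted `logistic_model` (the full selected set).
#' @return the reduced `logistic_model`, with the AIC path as attribute
#'   `"aic_path"`.
#' @export
stepwise_aic <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  current <- model
  path <- current$aic
  repeat {
    vars <- current$variables
    if (!length(vars)) break
    cand <- lapply(seq_along(vars), function(k) {
      remaining <- vars[-k]
      if (length(remaining)) {
        refit_on(model, remaining)
      } else {
        fit_logistic(matrix(numeric(0), nrow = model$n, ncol = 0), model$y)
      }
    })
    aics <- vapply(cand, `[[`, numeric(1), "aic")
    best_aic <- min(aics)
    if (best_aic >= current$aic) break
    # tie-break: drop the later feature in canonical order
    drop_k <- max(which(aics == best_aic))
    current <- cand[[drop_k]]
    path <- c(path, current$aic)
  }
  attr(current, "aic_path") <- path
  current
}

#' Wald p-value pruning of a logistic model
#'
#' Iteratively removes the non-intercept variable with the largest Wald p
#' >= `alpha` and refits, until every remaining coefficient has p < `alpha`
#' or only the intercept remains.
#'
#' @param model a fitted `logistic_model`.
#' @param alpha retention level (default 0.05).
#' @return the pruned `logistic_model`.
#' @export
prune_by_pvalue <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "logistic_model"))
  current <- model
  repeat {
    vars <- current$variables
    if (!length(vars)) break
    wt <- wald_table(current)
    pv <- wt$p[match(vars, wt$variable)]
    pv[!is.finite(pv)] <- 1
    if (all(pv < alpha)) break
    worst <- max(which(pv == max(pv)))  # later feature on ties
    remaining <- vars[-worst]
    current <- if (length(remaining)) {
      refit_on(model, remaining)
    } else {
      fit_logistic(matrix(numeric(0), nrow = model$n, ncol = 0), model$y)
    }
  }
  current
}
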