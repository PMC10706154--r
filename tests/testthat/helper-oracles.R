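# Independent oracles used to check package computations. Each is a direct,
# definition-level implementation kept deliberately separate from the code
# paths it verifies.

# weighted least squares (slope, intercept) by direct solve of the 2x2
# normal equations
wls_normal_equations <- function(x, y, w) {
  sw <- sum(w)
  sx <- sum(w * x)
  sxx <- sum(w * x^2)
  sy <- sum(w * y)
  sxy <- sum(w * x * y)
  A <- matrix(c(sw, sx, sx, sxx), 2, 2)
  b <- c(sy, sxy)
  sol <- solve(A, b)
  c(intercept = sol[1], slope = sol[2])
}

# exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments (tie-free data)
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  N <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(N, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg by the step-up definition: min over i >= rank of
# p_(i) * m / i, capped at 1
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- vapply(seq_len(m), function(j) {
    min(1, min(sort(p)[j:m] * m / (j:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# single-pass PLS1 weight vector by textbook NIPALS on (X, y)
nipals_pls1_weights <- function(X, y) {
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc))
  w / sqrt(sum(w^2))
}

# exhaustive best-subset logistic AIC over all 2^k variable subsets
exhaustive_aic_best <- function(X, y) {
  k <- ncol(X)
  best <- Inf
  best_vars <- character(0)
  for (code in 0:(2^k - 1)) {
    vars <- colnames(X)[bitwAnd(code, 2^(seq_len(k) - 1)) > 0]
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X[, vars, drop = FALSE]), y,
                     family = stats::binomial())
    )
    mu <- pmin(pmax(fit$fitted.values, .Machine$double.eps),
               1 - .Machine$double.eps)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    aic <- -2 * ll + 2 * (length(vars) + 1)
    if (aic < best) {
      best <- aic
      best_vars <- vars
    }
  }
  list(aic = best, vars = best_vars)
}

# small helper: protein_quant_matrix wrapper around a plain matrix
quant_from_matrix <- function(conc, group_labels = NULL) {
  structure(
    list(concentrations = conc,
         censored = matrix(FALSE, nrow(conc), ncol(conc),
                           dimnames = dimnames(conc)),
         sample_ids = rownames(conc), protein_ids = colnames(conc),
         group_labels = group_labels, lloq = NULL),
    class = "protein_quant_matrix"
  )
}

# curve object with known truth, bypassing fitting
truth_curve <- function(protein_id, slope, intercept = 0, lloq = 1) {
  structure(list(protein_id = protein_id, slope = slope,
                 intercept = intercept, weighting = "1/x^2", lloq = lloq,
                 n_points = NA_integer_, r_squared_weighted = NA_real_),
            class = "calibration_curve")
}
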