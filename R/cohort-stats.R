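#' Shapiro-Wilk normality gate for group comparisons
#'
#' Routes a comparison to the parametric branch only if every group passes
#' the Shapiro-Wilk test at `alpha`; any failing or constant group sends the
#' whole comparison to the nonparametric branch.
#'
#' @param groups list of numeric vectors (one per group, each n >= 3).
#' @param alpha gate level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop_mrm("Shapiro-Wilk needs n >= 3 in every group",
             class = "insufficient_data_error")
  }
  for (g in groups) {
    if (stats::sd(g) == 0) return("nonparametric")
    if (stats::shapiro.test(g)$p.value < alpha) return("nonparametric")
  }
  "parametric"
}

#' Two-group comparison on the gated branch
#'
#' Nonparametric branch: two-sided Mann-Whitney U (exact when both groups
#' have <= 8 observations and no ties, normal approximation with tie
#' correction otherwise). Parametric branch: Welch two-sample t test.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param branch `"parametric"` or `"nonparametric"` (from
#'   [normality_gate()]).
#' @return two-sided p-value.
#' @export
compare_two_groups <- function(a, b,
                               branch = c("nonparametric", "parametric")) {
  branch <- match.arg(branch)
  if (length(a) < 2 || length(b) < 2) {
    stop_mrm("each group needs n >= 2", class = "insufficient_data_error")
  }
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    warning("all values tied across both groups; p = 1 by convention")
    return(1)
  }
  if (branch == "nonparametric") {
    exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(pooled)
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)$p.value
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # equal constants were caught above; unequal constants separate fully
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }
}

# Games-Howell pairwise comparisons (Welch-type t with studentized-range
# reference); no installed package provides this post-hoc
games_howell <- function(groups) {
  k <- length(groups)
  nm <- names(groups)
  n <- vapply(groups, length, integer(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  res <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se2 <- v[i] / n[i] + v[j] / n[j]
      df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                       (v[j] / n[j])^2 / (n[j] - 1))
      tstat <- (m[i] - m[j]) / sqrt(se2)
      p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                         lower.tail = FALSE)
      res <- rbind(res, data.frame(
        group_a = nm[i], group_b = nm[j], estimate = m[i] - m[j],
        statistic = tstat, p_adjusted = p, stringsAsFactors = FALSE))
    }
  }
  res
}

# Dunn's pairwise z-tests after Kruskal-Wallis, with tie-corrected variance
# and Holm step-down adjustment
dunn_test <- function(groups) {
  k <- length(groups)
  nm <- names(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g, k)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  res <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
      z <- (rbar[i] - rbar[j]) / se
      p <- 2 * stats::pnorm(-abs(z))
      res <- rbind(res, data.frame(
        group_a = nm[i], group_b = nm[j], statistic = unname(z),
        p_value = unname(p), stringsAsFactors = FALSE))
    }
  }
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "holm")
  res
}

#' Omnibus k-group comparison with post-hoc table
#'
#' Parametric branch: one-way ANOVA; a Levene test (median-centered, via
#' `car::leveneTest`) routes the post-hocs to Tukey HSD (equal variances) or
#' Games-Howell (unequal variances). Nonparametric branch: Kruskal-Wallis
#' omnibus followed by Dunn's pairwise z-tests with Holm adjustment.
#'
#' @param groups named list of numeric vectors, >= 3 groups, each n >= 2.
#' @param branch `"parametric"` or `"nonparametric"`.
#' @param levene_alpha routing level for the equal-variance check.
#' @return list with `omnibus_p`, `omnibus_statistic`, `posthoc_method`, and
#'   a `posthoc` data.frame of pairwise adjusted p-values.
#' @export
compare_k_groups <- function(groups,
                             branch = c("nonparametric", "parametric"),
                             levene_alpha = 0.05) {
  branch <- match.arg(branch)
  if (length(groups) < 3) {
    stop_mrm("need >= 3 groups (use compare_two_groups otherwise)",
             class = "validation_error")
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop_mrm("each group needs n >= 2", class = "insufficient_data_error")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (length(unique(x)) == 1) {
    pairs <- t(utils::combn(names(groups), 2))
    return(list(omnibus_p = 1, omnibus_statistic = 0,
                posthoc_method = if (branch == "parametric") "tukey" else
                  "dunn_holm",
                posthoc = data.frame(group_a = pairs[, 1],
                                     group_b = pairs[, 2],
                                     p_adjusted = 1,
                                     stringsAsFactors = FALSE)))
  }
  if (branch == "parametric") {
    fit <- stats::aov(x ~ g)
    omni <- summary(fit)[[1]]
    lev_p <- car::leveneTest(x ~ g, center = stats::median)[1, "Pr(>F)"]
    if (is.finite(lev_p) && lev_p < levene_alpha) {
      posthoc <- games_howell(groups)
      method <- "games_howell"
    } else {
      tk <- stats::TukeyHSD(fit)$g
      pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
      posthoc <- data.frame(
        group_a = vapply(pairs, `[`, "", 1),
        group_b = vapply(pairs, `[`, "", 2),
        estimate = tk[, "diff"], p_adjusted = tk[, "p adj"],
        stringsAsFactors = FALSE)
      method <- "tukey"
    }
    list(omnibus_p = omni[["Pr(>F)"]][1],
         omnibus_statistic = omni[["F value"]][1],
         posthoc_method = method, posthoc = posthoc)
  } else {
    kw <- stats::kruskal.test(x, g)
    list(omnibus_p = kw$p.value,
         omnibus_statistic = unname(kw$statistic),
         posthoc_method = "dunn_holm", posthoc = dunn_test(groups))
  }
}

#' Pearson chi-square test on a contingency table
#'
#' @param tab 2-D count matrix; no continuity correction, df = (r-1)(c-1).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (length(dim(tab)) != 2 || any(dim(tab) < 2)) {
    stop_mrm("need a 2-D contingency table with >= 2 rows and columns",
             class = "validation_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_mrm("zero marginal in contingency table", class = "validation_error")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values in the input order (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  check_prob(p)
  stats::p.adjust(p, method = "BH")
}

#' Signed Cohen's d with pooled SD
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the usual (n-1)-weighted pooled
#' SD; positive when `a` exceeds `b`.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @export
cohen_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) {
    stop_mrm("each group needs n >= 2", class = "insufficient_data_error")
  }
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(0)
    stop_mrm("pooled SD is zero with unequal means: effect size undefined",
             class = "undefined_effect_error")
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Gated univariate comparison of every protein between two groups
#'
#' For each protein: Shapiro-Wilk gate, then Welch t (parametric) or
#' Mann-Whitney (nonparametric), Benjamini-Hochberg adjustment across the
#' panel, and signed Cohen's d (group a minus group b).
#'
#' @param quant a `protein_quant_matrix`.
#' @param group_a,group_b group labels present in `quant$group_labels`.
#' @return data.frame, one row per protein: `protein_id`, `test_used`,
#'   `p_value`, `p_adjusted`, `cohen_d`, `direction`.
#' @export
compare_proteins <- function(quant, group_a, group_b) {
  stopifnot(inherits(quant, "protein_quant_matrix"))
  gl <- quant$group_labels
  if (is.null(gl)) {
    stop_mrm("quant matrix carries no group labels", class = "validation_error")
  }
  ia <- which(gl == group_a)
  ib <- which(gl == group_b)
  if (!length(ia) || !length(ib)) {
    stop_mrm("group '%s' not found in quant matrix",
             if (!length(ia)) group_a else group_b, class = "validation_error")
  }
  res <- lapply(quant$protein_ids, function(pid) {
    a <- quant$concentrations[ia, pid]
    b <- quant$concentrations[ib, pid]
    branch <- normality_gate(list(a, b))
    p <- suppressWarnings(compare_two_groups(a, b, branch))
    d <- cohen_d(a, b)
    data.frame(protein_id = pid,
               test_used = if (branch == "parametric") "welch_t" else
                 "mann_whitney",
               p_value = p, cohen_d = d, direction = sign(d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- bh_adjust(res$p_value)
  res[, c("protein_id", "test_used", "p_value", "p_adjusted", "cohen_d",
          "direction")]
}

#' Protein-clinical covariate correlations
#'
#' Spearman by default (clinical covariates are often ordinal scores);
#' Pearson by flag. One row per protein x covariate with a two-sided p-value,
#' filterable at p < 0.05 downstream.
#'
#' @param quant a `protein_quant_matrix`.
#' @param covariates data.frame with `sample_id` plus numeric covariate
#'   columns.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame: `protein_id`, `covariate`, `r`, `p_value`, `method`.
#' @export
correlate_clinical <- function(quant, covariates,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(quant, "protein_quant_matrix"))
  idx <- match(quant$sample_ids, covariates$sample_id)
  if (anyNA(idx)) {
    stop_mrm("covariates missing for sample(s): %s",
             paste(quant$sample_ids[is.na(idx)], collapse = ", "),
             class = "validation_error")
  }
  cov_cols <- setdiff(names(covariates), "sample_id")
  out <- NULL
  for (cv in cov_cols) {
    y <- covariates[[cv]][idx]
    keep <- is.finite(y)
    if (sum(keep) < 4) {
      stop_mrm("covariate '%s' has < 4 paired observations", cv,
               class = "insufficient_data_error")
    }
    if (stats::sd(y[keep]) == 0) {
      stop_mrm("covariate '%s' is constant: correlation undefined", cv,
               class = "undefined_correlation_error")
    }
    for (pid in quant$protein_ids) {
      x <- quant$concentrations[keep, pid]
      ct <- suppressWarnings(
        stats::cor.test(x, y[keep], method = method, exact = FALSE))
      out <- rbind(out, data.frame(
        protein_id = pid, covariate = cv, r = unname(ct$estimate),
        p_value = ct$p.value, method = method, stringsAsFactors = FALSE))
    }
  }
  out
}
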