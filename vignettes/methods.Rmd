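---
title: "Methods: MRM panel quantitation and the biomarker model cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRM panel quantitation and the biomarker model cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmcascade)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The setting is discovery-scale clinical
proteomics: a multiplexed MRM assay quantifies on the order of 125 plasma
proteins (one proteotypic peptide each, with a stable-isotope-labeled
standard, SIS, spiked per peptide) in a small multi-group cohort, and the
analysis must go from raw NAT/SIS peak-area ratios to absolute
concentrations, univariate group statistics, and sparse logistic
classifiers.

## 1. Quantitation model

For each peptide the calibration model is a straight line on the
concentration axis,

$$ r = a + b\,x, $$

with $r$ the measured NAT/SIS area ratio and $x$ the spiked concentration in
fmol/µL. The fit minimizes $\sum_i w_i (r_i - a - b x_i)^2$ with
$w_i = 1/x_i^2$. The $1/x^2$ weighting is the bioanalytical convention for
assays whose error is proportional to signal: if
$r_i = (a + b x_i)(1 + \varepsilon_i)$ with
$\varepsilon_i \sim N(0, \mathrm{CV}^2)$, the response variance scales as
$x_i^2$ (for small $a$) and $1/x_i^2$ weights are close to
inverse-variance optimal. Because the synthetic generator injects noise in
exactly this multiplicative form, the optimality of the weighting is a
*testable* property here: the suite verifies on 500 simulated series that
weighted back-calculation at the lowest calibration level has lower median
absolute relative error than the unweighted fit.

Sample concentrations invert the fitted line, $\hat x = (r - \hat a)/\hat b$.
Negative back-calculations are legitimate consequences of intercept noise
near the assay floor, so they are *retained* rather than rejected and
resolved by the censoring step. Values below the peptide's LLOQ (an input
per peptide — the package never re-derives LLOQs from curves) are replaced
by a seeded uniform draw strictly inside $(0, \mathrm{LLOQ})$ and flagged.
Uniform is the minimal-assumption reading of "a random number within the
range"; the seed makes the substitution reproducible, which matters because
downstream statistics consume the substituted values. The ratio orientation
is NAT/SIS (analyte over heavy standard), chosen so the calibration line
increases with concentration; dilution and volume factors are fixed to 1
because the calibration is already expressed per µL of plasma.

**Tunable parameters.** `weighting` ("1/x^2" default, "1/x", "none");
per-peptide `lloq` (fmol/µL); the substitution `seed`.

## 2. Univariate layer

Each protein is compared between groups behind a normality gate: the
comparison is parametric only if *every* group passes Shapiro–Wilk at
$\alpha = 0.05$; a constant group routes nonparametric (the test is
undefined there, and the rank tests handle it without exceptions).

* Two groups — Welch's $t$ (parametric) or two-sided Mann–Whitney U
  (nonparametric; exact when both groups have $\le 8$ observations and no
  ties, midranks with tie-corrected variance otherwise). The parametric
  two-group test had to be chosen (the gate implies one must exist): Welch's
  $t$ avoids the equal-variance assumption, consistent with offering
  Games–Howell in the $k$-group branch.
* $k \ge 3$ groups — one-way ANOVA with post-hocs routed by a
  median-centered Levene test at $\alpha = 0.05$: Tukey HSD under equal
  variances, Games–Howell otherwise (hand-implemented: Welch-type statistic
  against the studentized-range distribution, as no installed package
  provides it). Nonparametric: Kruskal–Wallis, then Dunn's pairwise
  $z$-tests with the tie-corrected variance and Holm step-down adjustment.
* Categorical outcomes — Pearson chi-square without continuity correction.
* Multiplicity — Benjamini–Hochberg step-up across the panel per contrast.
* Effect sizes — signed Cohen's $d$ with the $(n-1)$-weighted pooled SD;
  the conventional $|d| > 0.5$ line is what "higher-than-medium" means in
  ranking displays.
* Protein–clinical correlations — Spearman by default, because clinical
  covariates are often ordinal (Apgar scores, severity grades); Pearson by
  flag. Two-sided p-values; downstream filtering at $p < 0.05$.

## 3. OPLS-DA and VIP

The first stage of variable selection is orthogonal projections to latent
structures discriminant analysis. The class vector is encoded as a centered
0/1 dummy (equivalent to ±1 up to scale for two classes). After
autoscaling (centering and unit variance — the common default for
concentration data spanning several decades; constant columns are dropped
and recorded), the algorithm removes `n_orthogonal` components of
X-variation orthogonal to the predictive direction: at each pass the
predictive weight is $w \propto X^\top y$, the orthogonal weight is the
X-loading residual after projecting out $w$, and the corresponding
component is deflated from $X$. One predictive PLS component is then fitted
on the filtered matrix, oriented so $\mathrm{cor}(t, y) \ge 0$ for
reproducible signs. With `n_orthogonal = 0` this is exactly
single-component PLS1, which is what the test oracle checks against.

Variable importance in projection over the predictive component reduces to
$\mathrm{VIP}_j = \sqrt{p}\,|w_j|$ for unit-norm $w$, so
$\sum_j \mathrm{VIP}_j^2 = p$ exactly — an identity the suite asserts at
$10^{-8}$ on every fitted model. Features with VIP > 1 carry more than an
average share of the discriminant direction; that conventional cut is the
cascade's first filter. Defaults: `n_orthogonal = 1` (one structured
nuisance direction is typical of plasma panels; configurable), VIP
threshold 1.

## 4. The model-building cascade

For proteins $C_1, \dots, C_k$ the candidate features are either the
quadratic grammar $\{C_i,\ C_i^2,\ C_i C_j\ (i<j)\}$ — used for the
diagnostic contrasts — or the ratio grammar $\{C_i,\ C_i/C_j\}$ with
*ordered* pairs ($C_i/C_j$ and $C_j/C_i$ are distinct predictors) — used for
prognostic outcomes. Products are unordered because multiplication commutes;
ratios are not. With $k = 125$ the quadratic grammar has 8,000 features.

The cascade is then:

1. **VIP filter** (> 1) on the expanded, autoscaled matrix.
2. **Identifiability cap**: the post-VIP candidates are ranked by VIP and
   truncated to `max_candidates` (default $n - 2$), since a maximum
   likelihood logistic fit needs more observations than coefficients. At
   $n = 20$ and ~2,600 VIP-passing features this cap is what makes the full
   fit defined at all; it is the one stage the small-sample regime forces.
3. **Logistic fit** by IRLS (deviance tolerance $10^{-10}$, max 100
   iterations), covariance from the observed information. Features are
   *not* standardized before fitting — coefficients stay on raw
   concentration scales (per fmol/µL or its square), which is how such
   models are published and applied.
4. **Backward AIC**: repeatedly drop the variable whose removal lowers AIC
   most; stop when no removal lowers it. Ties drop the later feature in
   canonical order, making the path deterministic. The accepted AIC path is
   strictly decreasing by construction.
5. **Wald pruning**: iteratively remove the variable with the largest Wald
   $P \ge 0.05$ and refit. The published wording ("coefficients reaching a
   probability of being equal to zero, less than 0.05") is read as
   *retain-if-P < 0.05*; the literal opposite reading would discard exactly
   the informative variables and is rejected.
6. **LOOCV**: coefficients are refitted per fold; the *variable set is not
   reselected* per fold. Re-running VIP + AIC inside each fold is not
   described in the procedure this package implements, so the out-of-fold
   probabilities carry selection optimism; reports label the
   cross-validation as `loocv` of coefficients only, and the recovery
   experiment quantifies how close the LOOCV AUC comes to the generating
   model's AUC. Folds that lose a class or fail to fit fall back to the
   full-data model and are counted in the report.
7. **Threshold**: the Youden-optimal cut over observed probabilities
   (`p >= threshold` is positive; ties toward the smallest threshold), plus
   the rank-based AUC (normalized Mann–Whitney U with midranks).

**Perfect separation** is endemic at $n = 10 + 10$ with thousands of
candidate features. It is detected from the monotone-likelihood signature —
fitted probabilities pinned onto the observed classes, which finite
coefficients can never achieve — and surfaced as a named flag and a count
in every report, never silently returned as huge coefficients. AIC and the
cascade remain well-defined through such fits.

Wald confidence intervals are the default. Published intervals for such
models are often asymmetric (profile-likelihood-like); the package keeps
Wald for speed and determinism and notes that reported CIs may therefore be
narrower near boundaries.

## 5. The synthetic cohort generator

The generator *is the study design* the analysis assumes, with known ground
truth:

* **Design**: five groups of 10 subjects (early IUGR, late IUGR, early and
  late gestational-age-matched controls, SGA), configurable.
* **Concentrations**: per-protein log-normal, i.e. $\log_{10} C \sim
  N(m_j + \delta_{jg}, s_j)$, with positive support and multiplicative
  group effects $\delta_{jg}$ (log10 fold-changes). The default panel spans
  exactly 5.43 orders of magnitude of abundance — the documented dynamic
  range of such 125-protein panels — with ~22 named proteins (serum
  albumin, alpha-2-macroglobulin, the apolipoproteins, adiponectin,
  gelsolin, ...) at physiologically plausible plasma levels and the rest
  evenly spaced. These values are declared fixtures of this package:
  per-protein ranges of any commercial kit are not public, so the defaults
  emulate the *scale*, not the kit. Default $s_j = 0.15$ (≈ 35% biological
  CV, a typical between-subject spread for plasma proteins). Default
  effects mirror the published early/late IUGR directions (ADIPOQ, A2M,
  GSN, PZP, S100A9 up and APOB100, CAMP, PLAT down in early IUGR; APOA4,
  GPX3, PLG, RBP4 up in late IUGR), at log10 fold-changes of 0.05–0.18.
* **Measurement**: the error-free ratio is the protein's true calibration
  line evaluated at the true concentration; measured ratios multiply it by
  $(1+\varepsilon)$, $\varepsilon \sim N(0, \mathrm{CV})$ with CV = 5%
  (typical MRM repeatability), floored at $10^{-9}$ so logs stay defined.
  True slopes default to $10^{-m_j}$ — the SIS spiked near the endogenous
  level, putting ratios near 1 — and intercepts to 0.
* **LLOQ**: default $10^{m_j - 2 s_j}$, censoring ≈ 2% of baseline cells —
  enough to exercise the substitution path without dominating the data.
* **Covariates**: a Gaussian copula on the protein's latent normal
  achieves a target Spearman correlation without constraining the covariate
  marginal ($\rho_{\mathrm{normal}} = 2 \sin(\pi \rho_S / 6)$). Defaults tie
  newborn weight negatively to A2M and cord glucose / uterine-artery PI to
  adiponectin, echoing reported clinical correlations.
* **Outcomes**: Bernoulli draws from a known logistic model on engineered
  features of the *true* concentrations. Coefficients may be given on the
  raw scale or per-SD of the feature (the package derives raw coefficients
  from the feature's closed-form log-normal moments).
  `calibrate_outcome_slope()` sizes a single-feature effect for a target
  generating AUC by bisection on a large deterministic Monte-Carlo draw;
  `outcome_true_auc()` reports the generating model's population AUC, the
  ceiling any fitted classifier is judged against.

All randomness flows from one seed through fixed per-stage substreams, so
cohorts, transition tables, calibration series, and LLOQ substitutions are
individually and jointly reproducible; pipeline reruns with the same seed
produce byte-identical artifacts (checksummed in the run manifest).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: chromatographic peak shapes and integration
error, retention-time drift, between-protein correlation structure (the
panel is conditionally independent given group), batch effects,
missing-not-at-random metadata, and model misspecification of the outcome
(real outcomes are not generated by a logistic model on two proteins).
Recovery results on synthetic cohorts are best read as *software
correctness* and *procedure behavior under its own assumptions*, not as
clinical validation.

## 6. Numerical choices and degenerate inputs

* Weighted least squares via `stats::lm(weights = )`; the acceptance suite
  compares it to a direct normal-equations solve at $10^{-10}$ relative.
* All-tied two-group comparisons return $p = 1$ with a warning; identical
  groups give $d = 0$; constant covariates and single-class outcomes raise
  typed errors.
* Ratio-mode expansion requires strictly positive concentrations, which
  LLOQ substitution guarantees.
* Exact Mann–Whitney only for tie-free groups $\le 8$; otherwise the
  normal approximation with tie correction (continuity correction off, so
  the statistic matches the U/AUC identity).
* The stepwise and pruning tie-breaks (drop the later feature) make runs
  reproducible across platforms.
* `runif` never returns its endpoints, so substituted values are strictly
  inside $(0, \mathrm{LLOQ})$.

## 7. Problem sizes used by the test and acceptance suites

The suites were sized to run comfortably on one CPU: moment-fidelity checks
at $n = 10^4$–$2\times10^4$ draws; the weighting comparison over 500
simulated series; VIP recovery over 100 seeds at $n = 40$ samples × 50
features; cascade recovery over 50 seeds at $n = 50 + 50$ on a 10-protein
panel (65 quadratic features) with the outcome driven by A2M² sized for a
generating AUC of 0.9; and one full design-scale run (5×10 subjects, 125
proteins, 8,000-feature expansion) per suite. The 10-protein recovery panel
is a deliberate reduction: the recovery property concerns the cascade's
selection behavior, which is exercised by the grammar, not by the panel
width.

## 8. Known limitations

* Variable selection happens once on the full data; LOOCV refits
  coefficients only, so reported cross-validated performance is optimistic
  relative to fully nested resampling.
* At the design scale ($n = 10$ per group) separation is frequent; reports
  surface it, but coefficient magnitudes from separated fits are not
  interpretable.
* Wald intervals and p-values are asymptotic and degrade exactly where
  separation looms.
* The greedy backward AIC path is not guaranteed to reach the best subset;
  the suite compares it against the exhaustive optimum only for small
  designs.
* One transition per protein: transition-level interference detection, peak
  integration, and QC drift correction are upstream instrument-software
  concerns, out of scope here.
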