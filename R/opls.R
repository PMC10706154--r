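#' Autoscale a feature matrix
#'
#' Centers every column and scales it to unit sample SD (the usual OPLS-DA
#' preprocessing). Constant columns cannot be scaled; they are dropped and
#' recorded.
#'
#' @param X samples x features numeric matrix.
#' @return object of class `scaled_matrix`: `X` (scaled), `center`, `scale`,
#'   `dropped` (names of constant columns), `scaling = "autoscale"`.
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) {
    stop_mrm("need >= 2 samples to autoscale", class = "validation_error")
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  }
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    stop_mrm("all columns are constant", class = "validation_error")
  }
  Xs <- sweep(X[, keep, drop = FALSE], 2, ctr[keep], `-`)
  Xs <- sweep(Xs, 2, sds[keep], `/`)
  structure(
    list(X = Xs, center = ctr[keep], scale = sds[keep],
         dropped = colnames(X)[!keep], scaling = "autoscale"),
    class = "scaled_matrix"
  )
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary response: the class vector is encoded as a centered 0/1 dummy;
#' `n_orthogonal` components of X-variation orthogonal to the predictive
#' direction are removed one at a time (each orthogonal weight is the
#' X-loading residual after projecting out the predictive weight), then a
#' single predictive PLS component is fitted on the filtered matrix. With
#' `n_orthogonal = 0` this is exactly single-component PLS1. The predictive
#' weight is oriented so that cor(t, y) >= 0.
#'
#' @param Xs a `scaled_matrix` (or plain matrix, scaled as given).
#' @param y binary labels (two levels, each with >= 2 samples).
#' @param n_orthogonal number of orthogonal components to remove (default 1).
#' @return object of class `opls_model` with predictive weights `w` (unit
#'   norm), scores `t`, loadings `p`, y-loading `c`, per-component orthogonal
#'   `w_ortho`/`t_ortho`/`p_ortho` matrices, `n_orthogonal`, explained
#'   Y-variance `ssy_explained`, and the feature names.
#' @export
fit_opls_da <- function(Xs, y, n_orthogonal = 1) {
  X <- if (inherits(Xs, "scaled_matrix")) Xs$X else as.matrix(Xs)
  cls <- unique(y)
  if (length(cls) != 2) {
    stop_mrm("OPLS-DA needs exactly two classes (got %d)", length(cls),
             class = "validation_error")
  }
  if (min(table(y)) < 2) {
    stop_mrm("each class needs >= 2 samples", class = "validation_error")
  }
  yd <- as.numeric(y == cls[2])
  yd <- yd - mean(yd)
  n <- nrow(X)
  p <- ncol(X)
  if (n_orthogonal < 0 || n_orthogonal >= min(n - 1, p)) {
    stop_mrm("n_orthogonal must lie in [0, rank(X))", class = "validation_error")
  }
  feat <- colnames(X)
  Xf <- X
  w_o <- t_o <- p_o <- NULL
  n_removed <- 0L
  for (a in seq_len(n_orthogonal)) {
    w <- drop(crossprod(Xf, yd))
    w <- w / sqrt(sum(w^2))
    tt <- drop(Xf %*% w)
    pp <- drop(crossprod(Xf, tt)) / sum(tt^2)
    wo <- pp - sum(w * pp) * w
    nw <- sqrt(sum(wo^2))
    if (nw < 1e-12) break  # no orthogonal variation left
    wo <- wo / nw
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    w_o <- cbind(w_o, wo)
    t_o <- cbind(t_o, to)
    p_o <- cbind(p_o, po)
    n_removed <- n_removed + 1L
  }
  w <- drop(crossprod(Xf, yd))
  nw <- sqrt(sum(w^2))
  if (nw == 0) {
    stop_mrm("X carries no covariance with the class vector",
             class = "validation_error")
  }
  w <- w / nw
  tt <- drop(Xf %*% w)
  if (sum(tt * yd) < 0) {  # orient so cor(t, y) >= 0
    w <- -w
    tt <- -tt
  }
  pp <- drop(crossprod(Xf, tt)) / sum(tt^2)
  cc <- sum(yd * tt) / sum(tt^2)
  ssy <- sum(yd^2)
  ssy_expl <- cc^2 * sum(tt^2) / ssy
  structure(
    list(w = stats::setNames(w, feat), t = tt,
         p = stats::setNames(pp, feat), c = cc,
         w_ortho = w_o, t_ortho = t_o, p_ortho = p_o,
         n_orthogonal = n_removed,
         ssy_explained = ssy_expl,
         features = feat, y_encoded = yd),
    class = "opls_model"
  )
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA model: 1 predictive + %d orthogonal component(s), %d features, R2Y = %.3f\n",
    x$n_orthogonal, length(x$w), x$ssy_explained))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP over the predictive component(s):
#' `VIP_j = sqrt(p * sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a)`. With the
#' single predictive component fitted here this reduces to `sqrt(p) * |w_j|`,
#' so mean(VIP^2) = 1 and features above 1 carry more than an average share
#' of the discriminant direction.
#'
#' @param model an `opls_model`.
#' @return named vector of VIP scores (one per retained feature).
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  if (model$ssy_explained <= 0) {
    stop_mrm("model explains no Y-variance; VIP undefined",
             class = "validation_error")
  }
  p <- length(model$w)
  sqrt(p * model$w^2 / sum(model$w^2))
}
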