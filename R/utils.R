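# internal helpers shared across modules

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded draws inside the package never
#' disturb the caller's RNG stream.
#' @noRd
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-stage substream: small additive offset, kept inside the
# 32-bit integer range R requires of set.seed()
stage_seed <- function(seed, offset) {
  (as.numeric(seed) + offset) %% (.Machine$integer.max - 1L)
}

stop_mrm <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mrmcascade_error")))
}

check_prob <- function(p, what = "p-values") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_mrm("%s must lie in [0, 1]", what, class = "validation_error")
  }
  invisible(p)
}
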