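# internal helpers

.sigmoid <- function(x) 1 / (1 + exp(-x))

.clipProb <- function(p, delta = 1e-7) pmin(pmax(p, delta), 1 - delta)

# run expr under a local RNG state so callers' streams are untouched
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

.assertFraction <- function(x, name, allow_zero = TRUE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  if (any(!is.finite(x)) || any(x < lo) || any(x >= 1))
    stop("configuration error: '", name, "' must lie in [0, 1)", call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop("configuration error: '", name, "' must be an integer >= ", min,
         call. = FALSE)
  invisible(as.integer(x))
}

# sub-seed derivation that stays below 2^31
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629) + 1L
}
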