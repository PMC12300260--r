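# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is left untouched.  seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed (kept well below .Machine$integer.max).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 97L + as.integer(k)) %% 2000000011L
}

stop_if_negative_age <- function(age) {
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("`age` must be a finite, non-negative number of years", call. = FALSE)
  }
  invisible(age)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
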