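`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate code with a temporary RNG state; the caller's .Random.seed is
## untouched.  All randomness in the package flows through this helper so
## that seeds are explicit arguments, never global state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("pulsekin_invalid_argument", "error")))
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'", name, "' must be a single finite number")
  if (positive && x <= 0) stop_invalid("'", name, "' must be > 0")
  if (nonneg && x < 0) stop_invalid("'", name, "' must be >= 0")
  invisible(x)
}

## Centered moving average with window shrinking at the edges (odd window).
moving_average <- function(x, window) {
  if (is.null(window) || window <= 1L) return(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop_invalid("smoothing window must be odd")
  n <- length(x)
  half <- window %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}
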