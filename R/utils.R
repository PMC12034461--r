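# internal helpers shared across modules

# stop() with call.=FALSE and sprintf-style message
nq_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

nq_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar validators
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    nq_stop("'%s' must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    nq_stop("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    nq_stop("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    nq_stop("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min)
    nq_stop("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

# run-length encoding of a logical vector into half-open 0-based
# [onset, offset) frame intervals
logical_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & !is.na(r$values)
  cbind(onset = starts[keep], offset = ends[keep])
}

# merge half-open runs separated by <= gap frames; 'runs' is a 2-col matrix
# sorted by onset
merge_runs <- function(runs, gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1L, , drop = FALSE]
  for (i in seq(2L, nrow(runs))) {
    if (runs[i, 1L] - out[nrow(out), 2L] <= gap) {
      out[nrow(out), 2L] <- runs[i, 2L]
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

# run `code` under a temporary seed when `seed` is non-NULL, leaving the
# caller's RNG stream untouched
maybe_with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# deterministic derived seeds (keeps everything < 2^31)
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 9973) %% 2147483562) + 1L
}
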