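#  Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#  Run `code` under a temporary RNG state seeded with `seed`; the caller's
#  RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_tp <- function(..., class = "tp_error") {
  stop(errorCondition(sprintf(...), class = c(class, "tp_error")))
}

check_number <- function(x, name, positive = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_tp("`%s` must be a numeric vector of length %d", name, len)
  }
  if (positive && any(x <= 0)) stop_tp("`%s` must be > 0", name)
  invisible(x)
}

#  Normal draws truncated at `lower` by rejection; degenerates to the mean
#  when sd == 0. Used by the cohort simulator (MBF and hemodynamics cannot
#  be negative).
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (all(sd == 0)) return(rep_len(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  it <- 0L
  while (length(bad) > 0L && it < 1000L) {
    x[bad] <- stats::rnorm(length(bad), rep_len(mean, n)[bad], rep_len(sd, n)[bad])
    bad <- bad[x[bad] <= lower]
    it <- it + 1L
  }
  if (length(bad) > 0L) x[bad] <- lower + abs(x[bad] - lower)
  x
}

#  Guarded ratio: errors on non-positive denominators (contract violation),
#  returns NA for denominators below 1e-9 (numerically meaningless, never Inf).
guarded_ratio <- function(num, den, what = "ratio") {
  if (any(den <= 0, na.rm = TRUE)) {
    stop_tp("undefined %s: denominator <= 0", what, class = "tp_error_ratio")
  }
  out <- num / den
  out[!is.na(den) & den < 1e-9] <- NA_real_
  out
}

#  Ratio for vectorised cohort columns: NA-propagating, no error (table rows
#  with missing values stay missing).
safe_ratio <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den < 1e-9] <- NA_real_
  out
}
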