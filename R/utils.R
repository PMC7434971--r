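# Internal helpers shared across modules.

# Round half away from zero (IEC "half-up" for positive input), used for
# the ensemble transition index and tie aggregation.
round_half_up <- function(x) floor(x + 0.5)

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG
# stream.  All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Integer -> lowercase base-26 string ("a".."z","aa",..).  Word forms in
# the synthetic vocabulary must be purely alphabetic because the
# tokenizer splits on non-letter characters.
int2alpha <- function(i) {
  vapply(i, function(k) {
    stopifnot(k >= 1)
    out <- character(0)
    while (k > 0) {
      r <- (k - 1L) %% 26L
      out <- c(letters[r + 1L], out)
      k <- (k - 1L) %/% 26L
    }
    paste(out, collapse = "")
  }, character(1))
}

# Statistical mode with deterministic tie handling: if several values are
# equally frequent, fall back to the median of the tied values, rounded
# half-up.
mode_or_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_integer_)
  tab <- table(x)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1L) top else as.integer(round_half_up(stats::median(top)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
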