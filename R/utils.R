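# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ordinary least-squares fit of y on x with Pearson correlation.
# Returns slope, intercept, r, n. Degenerate x (zero variance) is an error;
# degenerate y yields slope 0 and r = NA with a warning.
.ols_xy <- function(x, y, what = "regression") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop(what, ": need at least 2 finite (x, y) pairs")
  if (stats::var(x) == 0) stop(what, ": predictor is constant (degenerate fit)")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  if (stats::var(y) == 0) {
    warning(what, ": response is constant; correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(x, y)
  }
  list(slope = slope, intercept = intercept, r = r, n = n)
}

.assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  invisible(x)
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# deterministic sub-seed derivation, kept well below .Machine$integer.max
.subseed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
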