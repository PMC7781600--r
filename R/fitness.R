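#' sgRNA frequencies from pooled-competition counts
#'
#' Converts an sgRNA count matrix to within-sample frequencies after adding a
#' pseudocount, so that guides driven extinct by selection keep a finite log
#' frequency.
#'
#' @param counts Numeric matrix, sgRNAs x samples, non-negative; a sample
#'   whose raw total is zero is an error.
#' @param pseudocount Added to every count before normalization (default 0.5).
#' @return Matrix of the same shape; each column sums to 1.
#' @export
to_frequencies <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  x <- counts + pseudocount
  sweep(x, 2, colSums(x), "/")
}

#' Relative fitness of each sgRNA variant at a chosen day
#'
#' The log2 fold-change of each guide's frequency at the target day relative
#' to the reference day (day 0, before editing is induced), computed per
#' replicate and averaged. Day 7 is the default readout: early days are
#' dominated by incompletely edited cells, late days by selection-driven
#' extinction of the weakest variants.
#'
#' @param freqs Frequency matrix from \code{\link{to_frequencies}} (sgRNAs x
#'   samples).
#' @param samples data.frame with \code{sample_id, day, replicate} describing
#'   the columns of \code{freqs}.
#' @param day Target day (default 7).
#' @param reference_day Reference day (default 0).
#' @return Object of class \code{"fitness_vector"}: named numeric (per sgRNA)
#'   with attributes \code{role = "observed_O"}, \code{day},
#'   \code{reference_day}, \code{n_replicates}.
#' @export
relative_fitness <- function(freqs, samples, day = 7, reference_day = 0) {
  stopifnot(all(c("sample_id", "day", "replicate") %in% names(samples)))
  samples <- samples[samples$sample_id %in% colnames(freqs), , drop = FALSE]
  reps <- sort(unique(samples$replicate))
  per_rep <- vapply(reps, function(rp) {
    sub <- samples[samples$replicate == rp, , drop = FALSE]
    id_t <- sub$sample_id[sub$day == day]
    id_0 <- sub$sample_id[sub$day == reference_day]
    if (length(id_t) != 1L || length(id_0) != 1L) {
      stop("replicate ", rp, ": need exactly one sample at day ", day,
           " and one at day ", reference_day, "; available days: ",
           paste(sort(unique(sub$day)), collapse = ", "))
    }
    log2(freqs[, id_t] / freqs[, id_0])
  }, numeric(nrow(freqs)))
  fit <- rowMeans(per_rep)
  structure(fit, class = "fitness_vector", role = "observed_O",
            day = day, reference_day = reference_day,
            n_replicates = length(reps))
}

#' @export
print.fitness_vector <- function(x, ...) {
  cat(sprintf("<fitness_vector> %s, day %s vs day %s, %d replicate(s), %d variants\n",
              attr(x, "role"), format(attr(x, "day")),
              format(attr(x, "reference_day")), attr(x, "n_replicates"),
              length(x)))
  print(unclass(x)[seq_len(min(length(x), 10L))])
  if (length(x) > 10L) cat("...\n")
  invisible(x)
}

#' Fitness time course across all sampled days
#'
#' @param counts sgRNA x sample count matrix.
#' @param samples data.frame with \code{sample_id, day, replicate}.
#' @param pseudocount Passed to \code{\link{to_frequencies}}.
#' @param reference_day Reference day (default 0); its column is identically 0.
#' @return Matrix, sgRNAs x days (columns named by day, ascending), of
#'   replicate-averaged log2 frequency fold-changes versus the reference day.
#' @export
fitness_timecourse <- function(counts, samples, pseudocount = 0.5, reference_day = 0) {
  days <- sort(unique(samples$day))
  if (length(days) < 2L) stop("need at least two time points")
  freqs <- to_frequencies(counts, pseudocount)
  out <- vapply(days, function(d) {
    as.numeric(relative_fitness(freqs, samples, day = d, reference_day = reference_day))
  }, numeric(nrow(counts)))
  dimnames(out) <- list(rownames(counts), as.character(days))
  out
}

#' Regression of relative fitness on wild-type expression
#'
#' Diagnostic fit asking whether highly expressed tRNA families are more
#' essential: OLS of per-family fitness on wild-type family expression, with
#' the Pearson correlation.
#'
#' @param expression Named numeric: wild-type expression per family.
#' @param fitness Named numeric or \code{fitness_vector}, aligned by name.
#' @return List: \code{slope, intercept, r, n}.
#' @export
expression_fitness_regression <- function(expression, fitness) {
  shared <- intersect(names(expression), names(fitness))
  if (length(shared) < 3L) stop("need at least 3 families shared between inputs")
  .ols_xy(as.numeric(expression[shared]), as.numeric(unclass(fitness)[shared]),
          what = "expression-fitness regression")
}
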