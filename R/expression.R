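#' Default mismatch expression-reduction penalties
#'
#' Relative expression-level reduction at each guide/target mismatch level
#' \eqn{s = 0, 1, 2, 3}: full knockdown for perfect matches, half for one
#' mismatch, one fifth for two, none for three or more.
#'
#' @return Numeric vector \code{c(1, 0.5, 0.2, 0)} named by mismatch level.
#' @export
default_penalties <- function() {
  stats::setNames(c(1, 0.5, 0.2, 0), paste0("s", 0:3))
}

#' Family-level normalized tRNA expression
#'
#' Scales each sample to a fixed library size (reads per million by default)
#' and sums the normalized per-gene counts over the members of each
#' isodecoder family. Replicates stay separate (one column per sample).
#'
#' @param counts Numeric matrix, genes x samples, non-negative; rownames are
#'   gene ids.
#' @param gene_families Named character vector mapping gene id to family id,
#'   or a list of \code{\link{trna_gene}} objects.
#' @param scale Library size to normalize to (default \code{1e6}, i.e. RPM).
#' @return Numeric matrix, families x samples.
#' @export
family_expression <- function(counts, gene_families, scale = 1e6) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.list(gene_families)) {
    gene_families <- stats::setNames(
      vapply(gene_families, `[[`, character(1), "family_id"),
      vapply(gene_families, `[[`, character(1), "gene_id"))
  }
  unknown <- setdiff(rownames(counts), names(gene_families))
  if (length(unknown)) {
    stop("gene ids without a family assignment: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning("excluding sample(s) with zero total reads: ",
            paste(colnames(counts)[totals == 0], collapse = ", "))
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  rpm <- sweep(counts, 2, totals, "/") * scale
  fam <- rowsum(rpm, group = gene_families[rownames(counts)])
  fam[order(rownames(fam)), , drop = FALSE]
}

#' Family log2 fold-change of treated versus wild-type expression
#'
#' Computes \code{log2((treated + pc) / (wt + pc))} per replicate pair
#' (columns are paired by position) and averages over replicates. The
#' pseudocount bounds fold-changes for families that drop to zero.
#'
#' @param treated,wt Numeric matrices, families x replicates, with identical
#'   rownames and the same number of columns.
#' @param pseudocount Added to both numerator and denominator (default 0.5,
#'   in the same normalized units as the input).
#' @return List with \code{log2_fc} (named numeric per family),
#'   \code{per_replicate} (families x replicates matrix) and
#'   \code{n_replicates}.
#' @export
family_log2_fc <- function(treated, wt, pseudocount = 0.5) {
  treated <- as.matrix(treated); wt <- as.matrix(wt)
  if (!identical(rownames(treated), rownames(wt))) {
    missing <- setdiff(rownames(treated), rownames(wt))
    stop("treated and WT family sets differ",
         if (length(missing)) paste0("; missing from WT: ", paste(missing, collapse = ", ")))
  }
  if (ncol(treated) != ncol(wt)) {
    stop("treated has ", ncol(treated), " replicates but WT has ", ncol(wt),
         "; replicate pairing requires equal counts")
  }
  per_rep <- log2((treated + pseudocount) / (wt + pseudocount))
  list(log2_fc = rowMeans(per_rep), per_replicate = per_rep,
       n_replicates = ncol(treated))
}

#' Fold-change table across conditions and days
#'
#' Applies \code{\link{family_log2_fc}} to every (condition, day) cell of a
#' family-expression matrix against the wild-type samples of the same day,
#' pairing replicates by replicate label.
#'
#' @param fam_expr Families x samples matrix (e.g. from
#'   \code{\link{family_expression}}).
#' @param samples data.frame with \code{sample_id, condition, day, replicate};
#'   wild-type samples carry \code{condition == wt_label}.
#' @param wt_label Condition label marking wild-type samples (default "WT").
#' @param pseudocount Passed to \code{\link{family_log2_fc}}.
#' @return Long data.frame: \code{family, condition, day, log2_fc,
#'   n_replicates}.
#' @export
fold_change_table <- function(fam_expr, samples, wt_label = "WT", pseudocount = 0.5) {
  stopifnot(all(c("sample_id", "condition", "day", "replicate") %in% names(samples)))
  samples <- samples[samples$sample_id %in% colnames(fam_expr), , drop = FALSE]
  wt <- samples[samples$condition == wt_label, , drop = FALSE]
  tr <- samples[samples$condition != wt_label, , drop = FALSE]
  combos <- unique(tr[, c("condition", "day")])
  missing_days <- setdiff(unique(tr$day), unique(wt$day))
  if (length(missing_days)) {
    stop("no wild-type samples for day(s): ", paste(missing_days, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cc <- combos$condition[i]; dd <- combos$day[i]
    t_ids <- tr$sample_id[tr$condition == cc & tr$day == dd][order(tr$replicate[tr$condition == cc & tr$day == dd])]
    w_ids <- wt$sample_id[wt$day == dd][order(wt$replicate[wt$day == dd])]
    k <- min(length(t_ids), length(w_ids))
    if (length(t_ids) != length(w_ids)) {
      warning("condition ", cc, " day ", dd, ": unequal replicate counts; using first ", k, " pairs")
    }
    fc <- family_log2_fc(fam_expr[, t_ids[seq_len(k)], drop = FALSE],
                         fam_expr[, w_ids[seq_len(k)], drop = FALSE],
                         pseudocount = pseudocount)
    data.frame(family = rownames(fam_expr), condition = cc, day = dd,
               log2_fc = unname(fc$log2_fc), n_replicates = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Edited-read fraction per family
#'
#' Sums indel-supporting reads near the cut site over all family members and
#' divides by the summed maximum local coverage, the family-level editing
#' efficiency. Families whose total coverage is zero get \code{NA} (undefined),
#' never 0.
#'
#' @param indel_reads Named numeric vector, per-gene indel-supporting read
#'   counts.
#' @param max_coverage Named numeric vector, per-gene maximum coverage in the
#'   cut-site vicinity; must dominate \code{indel_reads} gene-wise.
#' @param gene_families Named character vector gene id -> family id (or list
#'   of \code{\link{trna_gene}}).
#' @param wt_fraction Optional named numeric of wild-type fractions per
#'   family; when given, the ratio treated/WT is reported as well.
#' @return data.frame: \code{family, indel, coverage, edited_fraction}
#'   (and \code{ratio_to_wt} when \code{wt_fraction} is supplied).
#' @export
edited_read_fraction <- function(indel_reads, max_coverage, gene_families,
                                 wt_fraction = NULL) {
  if (is.list(gene_families)) {
    gene_families <- stats::setNames(
      vapply(gene_families, `[[`, character(1), "family_id"),
      vapply(gene_families, `[[`, character(1), "gene_id"))
  }
  genes <- names(indel_reads)
  stopifnot(!is.null(genes), identical(sort(genes), sort(names(max_coverage))))
  max_coverage <- max_coverage[genes]
  if (any(indel_reads > max_coverage)) {
    stop("indel reads exceed coverage for gene(s): ",
         paste(genes[indel_reads > max_coverage], collapse = ", "))
  }
  fam <- gene_families[genes]
  num <- tapply(indel_reads, fam, sum)
  den <- tapply(max_coverage, fam, sum)
  frac <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(family = names(num), indel = as.numeric(num),
                    coverage = as.numeric(den), edited_fraction = as.numeric(frac),
                    stringsAsFactors = FALSE)
  if (!is.null(wt_fraction)) {
    out$ratio_to_wt <- out$edited_fraction / as.numeric(wt_fraction[out$family])
  }
  rownames(out) <- NULL
  out
}

#' Regression of expression fold-change on mismatch count
#'
#' Ordinary least-squares fit of per-(guide, family) log2 expression
#' fold-change on the integer guide/family mismatch level (0-3), with the
#' Pearson correlation — the calibration behind the mismatch penalty scheme.
#'
#' @param log2_fc Numeric vector of log2 fold-changes.
#' @param mismatches Integer vector of mismatch levels, same length.
#' @return Object of class \code{"mismatch_fit"}: list with \code{slope},
#'   \code{intercept}, \code{r}, \code{n} and \code{level_means} (mean log2
#'   fold-change per observed level).
#' @export
fit_mismatch_regression <- function(log2_fc, mismatches) {
  keep <- is.finite(log2_fc) & !is.na(mismatches)
  log2_fc <- log2_fc[keep]; mismatches <- as.integer(mismatches[keep])
  if (length(unique(mismatches)) < 2L) {
    stop("all points share one mismatch level; the fit is degenerate")
  }
  fit <- .ols_xy(mismatches, log2_fc, what = "mismatch regression")
  fit$level_means <- tapply(log2_fc, mismatches, mean)
  class(fit) <- "mismatch_fit"
  fit
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("<mismatch_fit> log2 FC = %.3f * mismatches + %.3f (r = %s, n = %d)\n",
              x$slope, x$intercept,
              if (is.na(x$r)) "NA" else sprintf("%.3f", x$r), x$n))
  invisible(x)
}

#' Penalty vector from mean linear expression reductions
#'
#' Normalizes the mean linear expression reduction at each mismatch level by
#' the level-0 reduction, clips to [0, 1], projects onto the non-increasing
#' cone (pool-adjacent-violators via \code{\link[stats]{isoreg}}), and forces
#' the 3-mismatch penalty to 0.
#'
#' @param reductions Numeric vector of length 4: mean linear (not log) expression
#'   reduction at mismatch levels 0-3. Level 0 must be positive. \code{NA}
#'   entries fall back to the default vector with a warning.
#' @return Penalty vector \eqn{p_s}, named \code{s0..s3}.
#' @export
penalties_from_means <- function(reductions) {
  if (length(reductions) != 4L) stop("need one mean reduction per mismatch level 0-3")
  if (anyNA(reductions)) {
    warning("missing mismatch level(s); falling back to the default penalty vector")
    return(default_penalties())
  }
  if (reductions[1] <= 0) stop("level-0 mean reduction must be positive")
  p <- pmin(pmax(reductions / reductions[1], 0), 1)
  # L2 projection onto non-increasing sequences = -isotonic fit of -p
  p <- -stats::isoreg(seq_along(p), -p)$yf
  p[4] <- 0
  stats::setNames(p, paste0("s", 0:3))
}
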