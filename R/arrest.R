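#' Gate the top and bottom reporter fractions of a flow population
#'
#' Ranks events by the (size-normalized) reporter intensity and assigns the
#' top \code{fraction} to the high bin and the bottom \code{fraction} to the
#' low bin, mimicking a FACS top/bottom sort. Ties are broken by stable event
#' order.
#'
#' @param events data.frame with columns \code{mCherry} and \code{FSC} (and
#'   typically \code{variant}).
#' @param fraction Gated fraction per tail, in (0, 0.5); default 0.05.
#' @param normalize Use the per-event mCherry/FSC ratio (default TRUE); FALSE
#'   ranks raw mCherry.
#' @return Character vector per event: \code{"H"}, \code{"L"} or
#'   \code{"none"}. Exactly \code{floor(fraction * n)} events land in each
#'   bin.
#' @export
gate_top_bottom <- function(events, fraction = 0.05, normalize = TRUE) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 0.5) {
    stop("fraction must be a single number in (0, 0.5)")
  }
  ratio <- if (normalize) events$mCherry / events$FSC else events$mCherry
  n <- length(ratio)
  n_sel <- floor(fraction * n)
  if (n_sel < 1L) stop("too few events (", n, ") for a ", fraction, " gate")
  if (length(unique(ratio)) == 1L) {
    warning("all events share the same ratio; bins determined by event order")
  }
  ord <- order(ratio, seq_len(n))  # stable
  bins <- rep("none", n)
  bins[ord[seq_len(n_sel)]] <- "L"
  bins[ord[seq.int(n - n_sel + 1L, n)]] <- "H"
  bins
}

#' Sorted-bin sgRNA enrichment relative to the ancestor population
#'
#' log2 ratio of each guide's frequency in a sorted bin to its frequency in
#' the matched ancestor sample (the edited, untreated starting population),
#' computed per replicate and averaged per (treatment, bin).
#'
#' @param counts sgRNA x sample count matrix, including ancestor columns.
#' @param samples data.frame with \code{sample_id, treatment, bin, replicate,
#'   is_ancestor}.
#' @param pseudocount Passed to \code{\link{to_frequencies}}.
#' @return Matrix, sgRNAs x sorted conditions (columns named
#'   \code{treatment_bin}), of replicate-averaged log2 enrichments.
#' @export
bin_enrichment <- function(counts, samples, pseudocount = 0.5) {
  stopifnot(all(c("sample_id", "treatment", "bin", "replicate", "is_ancestor") %in% names(samples)))
  samples <- samples[samples$sample_id %in% colnames(counts), , drop = FALSE]
  anc <- samples[as.logical(samples$is_ancestor), , drop = FALSE]
  if (nrow(anc) == 0L) stop("no ancestor sample in the metadata")
  freqs <- to_frequencies(counts, pseudocount)
  sorted <- samples[!as.logical(samples$is_ancestor), , drop = FALSE]
  combos <- unique(sorted[, c("treatment", "bin")])
  out <- vapply(seq_len(nrow(combos)), function(i) {
    sub <- sorted[sorted$treatment == combos$treatment[i] &
                    sorted$bin == combos$bin[i], , drop = FALSE]
    per_rep <- vapply(seq_len(nrow(sub)), function(j) {
      anc_id <- anc$sample_id[anc$replicate == sub$replicate[j]]
      if (length(anc_id) != 1L) {
        stop("replicate ", sub$replicate[j], ": need exactly one ancestor sample")
      }
      log2(freqs[, sub$sample_id[j]] / freqs[, anc_id])
    }, numeric(nrow(counts)))
    rowMeans(per_rep)
  }, numeric(nrow(counts)))
  dimnames(out) <- list(rownames(counts),
                        paste(combos$treatment, combos$bin, sep = "_"))
  out
}

#' Two-way hierarchical clustering of an enrichment matrix
#'
#' Clusters guides (rows) and sorted samples (columns) independently.
#' Defaults: Euclidean distance with average linkage for rows, correlation
#' distance (1 - Pearson) with average linkage for columns. Zero-variance
#' rows/columns make the correlation distance undefined; those distances are
#' set to 0 with a warning and clustering proceeds.
#'
#' @param mat Numeric matrix with at least 2 rows and 2 columns.
#' @param row_metric,col_metric \code{"euclidean"} or \code{"correlation"}.
#' @param linkage Agglomeration method for \code{\link[stats]{hclust}}
#'   (default \code{"average"}).
#' @return List: \code{row} and \code{col} (\code{hclust} objects),
#'   \code{row_order}, \code{col_order}, and the configuration used.
#' @export
two_way_cluster <- function(mat, row_metric = c("euclidean", "correlation"),
                            col_metric = c("correlation", "euclidean"),
                            linkage = "average") {
  row_metric <- match.arg(row_metric)
  col_metric <- match.arg(col_metric)
  if (nrow(mat) < 2L || ncol(mat) < 2L) stop("need at least 2 rows and 2 columns")
  dist_of <- function(m, metric) {
    if (metric == "euclidean") return(stats::dist(m))
    cc <- suppressWarnings(stats::cor(t(m)))
    d <- 1 - cc
    if (anyNA(d)) {
      warning("zero-variance rows/columns: undefined correlation distances set to 0")
      d[is.na(d)] <- 0
    }
    stats::as.dist(d)
  }
  rd <- dist_of(mat, row_metric)
  cd <- dist_of(t(mat), col_metric)
  if (all(rd == 0) || all(cd == 0)) {
    warning("constant matrix: all pairwise distances are zero")
  }
  rh <- stats::hclust(rd, method = linkage)
  ch <- stats::hclust(cd, method = linkage)
  list(row = rh, col = ch, row_order = rh$order, col_order = ch$order,
       config = list(row_metric = row_metric, col_metric = col_metric,
                     linkage = linkage))
}

#' Fraction of high-reporter cells per variant, with a test against control
#'
#' Computes, per variant and replicate, the fraction of events whose raw
#' reporter intensity exceeds the threshold, and compares each variant to the
#' control variant with a Welch two-sample t-test across replicates.
#'
#' @param events data.frame with \code{variant, replicate, mCherry}.
#' @param threshold Intensity threshold (arbitrary fluorescence units;
#'   default 1700).
#' @param control Variant id of the non-targeting control.
#' @return data.frame, one row per variant: \code{variant, mean_fraction,
#'   n_replicates, t_stat, p_value} (\code{NA} test entries, with a warning,
#'   when fewer than 2 replicates are available).
#' @export
high_fraction_test <- function(events, threshold = 1700, control = "control") {
  stopifnot(all(c("variant", "replicate", "mCherry") %in% names(events)))
  if (!control %in% events$variant) stop("control variant '", control, "' not present")
  frac <- stats::aggregate(mCherry ~ variant + replicate, data = events,
                           FUN = function(x) mean(x > threshold))
  names(frac)[names(frac) == "mCherry"] <- "fraction"
  ctrl <- frac$fraction[frac$variant == control]
  variants <- unique(frac$variant)
  rows <- lapply(variants, function(v) {
    f <- frac$fraction[frac$variant == v]
    if (v == control || length(f) < 2L || length(ctrl) < 2L ||
        (stats::sd(f) == 0 && stats::sd(ctrl) == 0)) {
      if (v != control && (length(f) < 2L || length(ctrl) < 2L)) {
        warning("variant ", v, ": fewer than 2 replicates; test skipped")
      }
      tt <- list(statistic = NA_real_, p.value = NA_real_)
      if (v != control && length(f) >= 2L && length(ctrl) >= 2L &&
          all(f == ctrl)) {
        tt <- list(statistic = 0, p.value = 1)  # identical replicate fractions
      }
    } else {
      ht <- stats::t.test(f, ctrl)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(variant = v, mean_fraction = mean(f), n_replicates = length(f),
               t_stat = tt$statistic, p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify family essentiality across proliferative and arrest contexts
#'
#' A family is proliferation-essential when its fitness is at or below the
#' threshold in a majority of proliferative contexts; arrest-essential when
#' its high-bin depletion is at or below the arrest threshold; essential in
#' all contexts when both hold; dispensable when neither. Families with
#' missing scores are marked incomplete.
#'
#' @param fitness Numeric matrix, families x proliferative contexts (log2
#'   relative fitness; e.g. one column per cell line).
#' @param arrest Named numeric: per-family high-bin log2 depletion under the
#'   arrest treatments (more negative = more required for arrest entry).
#' @param theta_p,theta_a Log2 thresholds (default -1 each); a score counts
#'   when it is \code{<=} the threshold.
#' @return data.frame: one row per family with the context scores, the number
#'   of proliferative contexts below threshold, and \code{class} in
#'   \code{essential_all, proliferation_essential, arrest_essential,
#'   dispensable, incomplete}.
#' @export
classify_essentiality <- function(fitness, arrest, theta_p = -1, theta_a = -1) {
  fitness <- as.matrix(fitness)
  fams <- rownames(fitness)
  if (is.null(fams)) stop("fitness matrix must have family rownames")
  arrest <- arrest[fams]
  rows <- lapply(seq_along(fams), function(i) {
    fit <- fitness[i, ]
    arr <- arrest[i]
    if (anyNA(fit) || is.na(arr)) {
      cls <- "incomplete"
      n_hit <- NA_integer_
    } else {
      n_hit <- sum(fit <= theta_p)
      prolif <- n_hit > length(fit) / 2
      arrested <- arr <= theta_a
      cls <- if (prolif && arrested) "essential_all"
      else if (prolif) "proliferation_essential"
      else if (arrested) "arrest_essential"
      else "dispensable"
    }
    data.frame(family = fams[i], t(fit), arrest = unname(arr),
               n_proliferative_hits = n_hit, class = cls,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
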