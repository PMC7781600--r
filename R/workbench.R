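#' Run the full screen-analysis pipeline
#'
#' Executes the stages in dependency order: targeting profiles for every
#' guide x family pair, the expression-reduction matrix, relative fitness at
#' the readout day, off-target deconvolution, family expression fold-changes
#' (when tRNA-seq inputs are given), sorted-bin enrichment (when arrest
#' inputs are given), and the cross-context essentiality classification. The
#' run is deterministic given the inputs and configuration; tables are
#' optionally written as TSVs.
#'
#' @param inputs List with components \code{genes}, \code{guides} (objects or
#'   file paths readable by \code{\link{read_trna_fasta}} /
#'   \code{\link{read_guide_manifest}}), \code{sgrna_counts} +
#'   \code{sgrna_samples} (matrix + data.frame, or paths for
#'   \code{\link{read_count_table}}), and optionally \code{trnaseq_counts} +
#'   \code{trnaseq_samples}, \code{bin_counts} + \code{bin_samples},
#'   \code{extra_fitness} (named list of additional per-context fitness
#'   vectors for the classification).
#' @param penalties Penalty vector (default \code{\link{default_penalties}}).
#' @param day,reference_day Fitness readout convention (defaults 7 and 0).
#' @param pseudocount Count pseudocount used throughout (default 0.5).
#' @param score_cutoff,pam_mode Targeting-profile settings.
#' @param theta_p,theta_a Classification thresholds (default -1 log2).
#' @param outdir Optional directory; when given, every table is written as a
#'   TSV there.
#' @return Object of class \code{"trnascreen_report"}: list of stage outputs
#'   (\code{profiles}, \code{on_off}, \code{M}, \code{fitness},
#'   \code{deconvolution}, \code{consistency}, and where inputs allow
#'   \code{expression_fc}, \code{enrichment}, \code{clustering},
#'   \code{classification}), plus the echoed configuration and a run log.
#' @export
run_pipeline <- function(inputs, penalties = default_penalties(),
                         day = 7, reference_day = 0, pseudocount = 0.5,
                         score_cutoff = 50, pam_mode = c("NGG", "none"),
                         theta_p = -1, theta_a = -1, outdir = NULL) {
  pam_mode <- match.arg(pam_mode)
  t0 <- Sys.time()
  log_lines <- character()
  note <- function(...) {
    line <- sprintf("[%.1fs] %s", as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    paste0(...))
    log_lines <<- c(log_lines, line)
  }

  need <- c("genes", "guides", "sgrna_counts", "sgrna_samples")
  missing <- setdiff(need, names(inputs))
  if (length(missing)) stop("missing required input(s): ", paste(missing, collapse = ", "))
  genes <- if (is.character(inputs$genes)) read_trna_fasta(inputs$genes) else inputs$genes
  guides <- if (is.character(inputs$guides)) read_guide_manifest(inputs$guides) else inputs$guides
  if (is.character(inputs$sgrna_counts)) {
    ct <- read_count_table(inputs$sgrna_counts, inputs$sgrna_samples)
    sg_counts <- ct$counts; sg_samples <- ct$samples
  } else {
    sg_counts <- as.matrix(inputs$sgrna_counts); sg_samples <- inputs$sgrna_samples
  }
  families <- families_from_genes(genes)
  note("validated inputs: ", length(genes), " genes, ", length(families),
       " families, ", length(guides), " guides, ", ncol(sg_counts), " competition samples")

  profiles <- do.call(rbind, lapply(guides, function(gd) {
    do.call(rbind, lapply(families, function(fam) {
      build_targeting_profile(gd, fam, genes, score_cutoff = score_cutoff,
                              pam_mode = pam_mode)
    }))
  }))
  rownames(profiles) <- NULL
  on_off <- suppressWarnings(
    classify_on_off(guides, genes, families, score_cutoff = score_cutoff,
                    pam_mode = pam_mode))
  note("targeting profiles: ", nrow(profiles), " guide x family pairs")

  fam_order <- vapply(guides, `[[`, character(1), "intended_family")
  M <- build_reduction_matrix(profiles, penalties,
                              families = unname(fam_order),
                              guides = vapply(guides, `[[`, character(1), "guide_id"))
  note("reduction matrix ", nrow(M), " x ", ncol(M))

  freqs <- to_frequencies(sg_counts, pseudocount)
  fitness <- relative_fitness(freqs, sg_samples, day = day,
                              reference_day = reference_day)
  timecourse <- fitness_timecourse(sg_counts, sg_samples, pseudocount,
                                   reference_day = reference_day)
  dec <- deconvolve(fitness[colnames(M)], M)
  consistency <- consistency_report(fitness[colnames(M)], dec)
  note("fitness + deconvolution done (solver = ", dec$solver, ")")

  report <- list(profiles = profiles, on_off = on_off, M = M,
                 fitness = fitness, timecourse = timecourse,
                 deconvolution = dec, consistency = consistency)

  if (!is.null(inputs$trnaseq_counts)) {
    if (is.character(inputs$trnaseq_counts)) {
      ct <- read_count_table(inputs$trnaseq_counts, inputs$trnaseq_samples)
      tc <- ct$counts; ts <- ct$samples
    } else {
      tc <- as.matrix(inputs$trnaseq_counts); ts <- inputs$trnaseq_samples
    }
    fam_expr <- family_expression(tc, genes)
    report$expression_fc <- fold_change_table(fam_expr, ts, pseudocount = pseudocount)
    note("expression fold-changes: ", nrow(report$expression_fc), " rows")
  }

  if (!is.null(inputs$bin_counts)) {
    if (is.character(inputs$bin_counts)) {
      ct <- read_count_table(inputs$bin_counts, inputs$bin_samples)
      bc <- ct$counts; bs <- ct$samples
    } else {
      bc <- as.matrix(inputs$bin_counts); bs <- inputs$bin_samples
    }
    report$enrichment <- bin_enrichment(bc, bs, pseudocount)
    report$clustering <- two_way_cluster(report$enrichment)
    note("sorted-bin enrichment: ", ncol(report$enrichment), " sorted conditions")

    # classification: proliferative contexts = deconvolved/observed fitness
    # (+ any extra contexts); arrest = mean high-bin enrichment per family
    guide_to_fam <- stats::setNames(unname(fam_order),
                                    vapply(guides, `[[`, character(1), "guide_id"))
    fit_ctx <- c(list(primary = stats::setNames(as.numeric(fitness[names(guide_to_fam)]),
                                                guide_to_fam)),
                 inputs$extra_fitness %||% list())
    fams_all <- unname(fam_order)
    fit_mat <- vapply(fit_ctx, function(v) as.numeric(v[fams_all]),
                      numeric(length(fams_all)))
    rownames(fit_mat) <- fams_all
    h_cols <- grep("_H$", colnames(report$enrichment), value = TRUE)
    h_cols <- setdiff(h_cols, "U_H")
    arrest_score <- rowMeans(report$enrichment[, h_cols, drop = FALSE])
    arrest_by_fam <- stats::setNames(
      as.numeric(arrest_score[names(guide_to_fam)]), guide_to_fam)
    report$classification <- classify_essentiality(fit_mat, arrest_by_fam,
                                                   theta_p = theta_p,
                                                   theta_a = theta_a)
    note("essentiality classification: ",
         paste(names(table(report$classification$class)), collapse = "/"))
  }

  report$config <- list(penalties = penalties, day = day,
                        reference_day = reference_day,
                        pseudocount = pseudocount, score_cutoff = score_cutoff,
                        pam_mode = pam_mode, theta_p = theta_p, theta_a = theta_a)
  report$log <- log_lines
  class(report) <- "trnascreen_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.table(x, file.path(outdir, f), sep = "\t",
                                            quote = FALSE, row.names = FALSE)
    wr(profiles, "profiles.tsv")
    wr(data.frame(family = rownames(M), unclass(M), check.names = FALSE), "reduction_matrix.tsv")
    wr(data.frame(guide = names(fitness), fitness_log2 = as.numeric(fitness)), "fitness.tsv")
    wr(data.frame(family = names(dec$R), estimated_R = as.numeric(dec$R)), "real_fitness.tsv")
    if (!is.null(report$expression_fc)) wr(report$expression_fc, "expression_fc.tsv")
    if (!is.null(report$enrichment)) {
      wr(data.frame(sgRNA = rownames(report$enrichment), report$enrichment,
                    check.names = FALSE), "enrichment.tsv")
    }
    if (!is.null(report$classification)) wr(report$classification, "classes.tsv")
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  report
}

#' @export
print.trnascreen_report <- function(x, ...) {
  cat("<trnascreen_report>\n")
  for (ln in x$log) cat(" ", ln, "\n")
  invisible(x)
}

#' Pairwise cross-context fitness comparisons
#'
#' For every pair of per-context fitness tables, reports the overall Pearson
#' correlation and, per tRNA class, the OLS slope and intercept of one
#' context on the other (columns ordered as listed).
#'
#' @param fitness_list Named list (>= 2) of named numeric vectors: per-family
#'   log2 fitness in each context.
#' @param classes Named character vector: family -> class label
#'   (\code{proliferation} / \code{differentiation} / ...).
#' @param min_shared Minimum shared families per class for a class fit
#'   (default 3).
#' @return data.frame: \code{context_x, context_y, class} ("all" for the
#'   pooled correlation row), \code{slope, intercept, r, n}.
#' @export
cross_context_compare <- function(fitness_list, classes, min_shared = 3L) {
  stopifnot(length(fitness_list) >= 2L, !is.null(names(fitness_list)))
  ctx <- names(fitness_list)
  pairs <- utils::combn(ctx, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pp) {
    x <- fitness_list[[pp[1]]]; y <- fitness_list[[pp[2]]]
    shared <- intersect(names(x), names(y))
    if (length(shared) < min_shared) {
      stop("contexts ", pp[1], "/", pp[2], ": fewer than ", min_shared, " shared families")
    }
    all_fit <- .ols_xy(as.numeric(x[shared]), as.numeric(y[shared]),
                       what = paste(pp, collapse = " vs "))
    out <- data.frame(context_x = pp[1], context_y = pp[2], class = "all",
                      slope = all_fit$slope, intercept = all_fit$intercept,
                      r = all_fit$r, n = all_fit$n, stringsAsFactors = FALSE)
    for (cl in intersect(unique(classes[shared]),
                         c("proliferation", "differentiation"))) {
      fams <- shared[classes[shared] == cl]
      if (length(fams) >= min_shared) {
        fit <- .ols_xy(as.numeric(x[fams]), as.numeric(y[fams]),
                       what = paste(cl, "class fit"))
        out <- rbind(out, data.frame(context_x = pp[1], context_y = pp[2],
                                     class = cl, slope = fit$slope,
                                     intercept = fit$intercept, r = fit$r,
                                     n = fit$n, stringsAsFactors = FALSE))
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group comparison of screen statistics
#'
#' Wilcoxon rank-sum (default) or Welch t-test between two labeled groups of
#' values, e.g. expression of perfectly versus imperfectly matched families,
#' or fitness of proliferation versus differentiation families.
#'
#' @param values Numeric vector.
#' @param groups Factor/character of the same length with exactly two levels.
#' @param test \code{"rank_sum"} or \code{"t_test"}.
#' @return List: \code{test, statistic, p_value, n1, n2}.
#' @export
group_comparison <- function(values, groups, test = c("rank_sum", "t_test")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("need exactly two groups, got ", length(lv))
  a <- values[groups == lv[1]]; b <- values[groups == lv[2]]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values (got ", length(a), " and ", length(b), ")")
  }
  ht <- if (test == "rank_sum") stats::wilcox.test(a, b) else stats::t.test(a, b)
  list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
       n1 = length(a), n2 = length(b))
}
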