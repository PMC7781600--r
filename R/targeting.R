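#' Best ungapped match of a guide against a tRNA gene
#'
#' Scans every ungapped window of the gene sequence on both strands and
#' returns the hit with the fewest mismatches to the protospacer (Hamming
#' distance; \code{N} always counts as a mismatch). With
#' \code{pam_mode = "NGG"} only windows with an NGG protospacer-adjacent
#' motif on the matched strand are considered, the convention for S. pyogenes
#' Cas9. Distances above \code{max_mismatch} collapse to an untargeted hit.
#'
#' Coordinates are 0-based, half-open, local to the supplied sequence (gene
#' body plus flanks) on the top strand; minus-strand hits are reported by
#' their top-strand window. Ties are broken by fewest mismatches, then plus
#' strand first, then smallest offset.
#'
#' @param guide A \code{\link{guide_rna}} (or bare protospacer string).
#' @param gene A \code{\link{trna_gene}} (or bare DNA string).
#' @param pam_mode \code{"NGG"} (default) to require the PAM, \code{"none"} to
#'   scan all windows.
#' @param max_mismatch Mismatch cap; windows beyond it are untargeted
#'   (default 3).
#' @return A one-row data.frame of class \code{"target_hit"} with columns
#'   \code{guide_id, gene_id, mismatches, strand, offset, pam_ok}.
#'   \code{mismatches} is \code{NA} (untargeted sentinel) when no window is
#'   within the cap; \code{strand}/\code{offset} are then \code{NA} too.
#' @export
min_mismatch_hit <- function(guide, gene, pam_mode = c("NGG", "none"),
                             max_mismatch = 3L) {
  pam_mode <- match.arg(pam_mode)
  spacer <- if (inherits(guide, "guide_rna")) guide$protospacer else toupper(guide)
  guide_id <- if (inherits(guide, "guide_rna")) guide$guide_id else NA_character_
  seqstr <- if (inherits(gene, "trna_gene")) gene$sequence else toupper(gene)
  gene_id <- if (inherits(gene, "trna_gene")) gene$gene_id else NA_character_
  .assert_dna(spacer, "protospacer")
  .assert_dna(seqstr, "gene sequence")

  L <- nchar(spacer)
  n <- nchar(seqstr)
  if (n < L) stop("gene sequence shorter than the protospacer")

  s <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  g <- strsplit(spacer, "", fixed = TRUE)[[1]]
  g_rc <- strsplit(.revcomp(spacer), "", fixed = TRUE)[[1]]
  offs <- 0:(n - L)
  idx <- seq_len(L)

  # a base matches only if identical and not N
  dist_to <- function(pattern) {
    vapply(offs, function(o) {
      w <- s[o + idx]
      sum(w != pattern | w == "N" | pattern == "N")
    }, integer(1))
  }
  d_plus <- dist_to(g)          # protospacer on top strand; PAM 3' of window
  d_minus <- dist_to(g_rc)      # protospacer on bottom strand; window = revcomp

  # PAM NGG at 0-based [o+L, o+L+3) on the plus strand; the two Gs are
  # 1-based indices o+L+2 and o+L+3
  pam_plus <- offs + L + 3L <= n &
    s[pmin(offs + L + 2L, n)] == "G" & s[pmin(offs + L + 3L, n)] == "G"
  pam_minus <- offs - 3L >= 0L &
    s[pmax(offs - 2L, 1L)] == "C" & s[pmax(offs - 1L, 1L)] == "C"

  cand <- data.frame(
    offset = rep(offs, 2L),
    strand = rep(c("+", "-"), each = length(offs)),
    mismatches = c(d_plus, d_minus),
    pam = c(pam_plus, pam_minus),
    stringsAsFactors = FALSE
  )
  if (pam_mode == "NGG") cand <- cand[cand$pam, , drop = FALSE]
  cand <- cand[cand$mismatches <= max_mismatch, , drop = FALSE]

  if (nrow(cand) == 0L) {
    out <- data.frame(guide_id = guide_id, gene_id = gene_id,
                      mismatches = NA_integer_, strand = NA_character_,
                      offset = NA_integer_, pam_ok = NA,
                      stringsAsFactors = FALSE)
  } else {
    ord <- order(cand$mismatches, cand$strand != "+", cand$offset)
    best <- cand[ord[1L], ]
    out <- data.frame(guide_id = guide_id, gene_id = gene_id,
                      mismatches = as.integer(best$mismatches),
                      strand = best$strand, offset = as.integer(best$offset),
                      pam_ok = best$pam, stringsAsFactors = FALSE)
  }
  class(out) <- c("target_hit", class(out))
  out
}

#' Is a hit untargeted?
#' @param hit A \code{target_hit} row.
#' @return Logical.
#' @export
is_untargeted <- function(hit) is.na(hit$mismatches)

#' Family targeting profile for a guide
#'
#' Fractions \eqn{f_s} of considered family members whose best hit to the
#' guide has exactly \eqn{s} mismatches, for \eqn{s = 0,\dots,3}. Members with
#' no window within the cap contribute to the untargeted remainder, so
#' \eqn{\sum_s f_s \le 1}. Only members with \code{trna_score > score_cutoff}
#' are considered, except in pseudogene families, which are exempt from the
#' score filter.
#'
#' @param guide A \code{\link{guide_rna}}.
#' @param family A \code{\link{trna_family}}.
#' @param genes Named list of \code{\link{trna_gene}} covering the members.
#' @param score_cutoff Score threshold (strict \code{>}); default 50.
#' @param pam_mode Passed to \code{\link{min_mismatch_hit}}.
#' @return One-row data.frame of class \code{"targeting_profile"} with columns
#'   \code{guide_id, family_id, f0, f1, f2, f3, n_considered}.
#' @export
build_targeting_profile <- function(guide, family, genes, score_cutoff = 50,
                                    pam_mode = c("NGG", "none")) {
  pam_mode <- match.arg(pam_mode)
  members <- genes[family$member_gene_ids]
  if (any(vapply(members, is.null, logical(1)))) {
    stop("family ", family$family_id, ": member gene(s) missing from the gene set")
  }
  if (family$class_label != "pseudo") {
    scores <- vapply(members, `[[`, numeric(1), "trna_score")
    members <- members[!is.na(scores) & scores > score_cutoff]
  }
  if (length(members) == 0L) {
    stop("family ", family$family_id, ": no member passes trna_score > ",
         score_cutoff, " (and family is not pseudo)")
  }
  mm <- vapply(members, function(g) {
    min_mismatch_hit(guide, g, pam_mode = pam_mode)$mismatches
  }, integer(1))
  f <- vapply(0:3, function(s) mean(!is.na(mm) & mm == s), numeric(1))
  out <- data.frame(guide_id = guide$guide_id, family_id = family$family_id,
                    f0 = f[1], f1 = f[2], f2 = f[3], f3 = f[4],
                    n_considered = length(members), stringsAsFactors = FALSE)
  class(out) <- c("targeting_profile", class(out))
  out
}

#' ON/OFF-target classification of a guide library against a family set
#'
#' For every guide x family pair, reports the family-level minimum mismatch
#' count over considered members. The pair (guide, intended family) is the
#' ON-target; any other family reached at 0 mismatches is flagged as a
#' full-match OFF-target (with a warning), and a guide whose intended family
#' has no 0-mismatch member triggers a warning but not an error.
#'
#' @param library Named list of \code{\link{guide_rna}}.
#' @param genes Named list of \code{\link{trna_gene}}.
#' @param families Optional named list of \code{\link{trna_family}}; derived
#'   from \code{genes} when omitted.
#' @param score_cutoff,pam_mode As in \code{\link{build_targeting_profile}}.
#' @return data.frame with one row per guide x family:
#'   \code{guide_id, family_id, min_mismatch} (NA = untargeted),
#'   \code{n_considered, is_on_target, full_match_off}.
#' @export
classify_on_off <- function(library, genes, families = NULL,
                            score_cutoff = 50, pam_mode = c("NGG", "none")) {
  pam_mode <- match.arg(pam_mode)
  families <- families %||% families_from_genes(genes)
  if (length(library) == 0L) {
    return(data.frame(guide_id = character(), family_id = character(),
                      min_mismatch = integer(), n_considered = integer(),
                      is_on_target = logical(), full_match_off = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(library, function(gd) {
    per_fam <- lapply(families, function(fam) {
      prof <- build_targeting_profile(gd, fam, genes,
                                      score_cutoff = score_cutoff,
                                      pam_mode = pam_mode)
      f <- c(prof$f0, prof$f1, prof$f2, prof$f3)
      mm <- if (all(f == 0)) NA_integer_ else which(f > 0)[1L] - 1L
      data.frame(guide_id = gd$guide_id, family_id = fam$family_id,
                 min_mismatch = mm, n_considered = prof$n_considered,
                 is_on_target = fam$family_id == gd$intended_family,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_fam)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$full_match_off <- !out$is_on_target & !is.na(out$min_mismatch) &
    out$min_mismatch == 0L
  if (any(out$full_match_off)) {
    hits <- out[out$full_match_off, ]
    warning("full-match OFF-target(s): ",
            paste(paste0(hits$guide_id, "->", hits$family_id), collapse = ", "))
  }
  on <- out[out$is_on_target, ]
  bad_on <- on[is.na(on$min_mismatch) | on$min_mismatch != 0L, ]
  if (nrow(bad_on)) {
    warning("guide(s) without a 0-mismatch member in their intended family: ",
            paste(bad_on$guide_id, collapse = ", "))
  }
  out
}

#' Choose the best guide for a family
#'
#' Returns the candidate that fully matches (0 mismatches) the largest number
#' of considered family members; ties are broken by highest
#' \code{design_score}, then lexicographically smallest \code{guide_id}. The
#' result is invariant to the order of the candidates.
#'
#' @param candidates List of \code{\link{guide_rna}} (length >= 1).
#' @param family A \code{\link{trna_family}}.
#' @param genes Named list of \code{\link{trna_gene}}.
#' @param score_cutoff,pam_mode As in \code{\link{build_targeting_profile}}.
#' @return The selected \code{\link{guide_rna}}.
#' @export
select_family_guide <- function(candidates, family, genes, score_cutoff = 50,
                                pam_mode = c("NGG", "none")) {
  pam_mode <- match.arg(pam_mode)
  if (length(candidates) == 0L) stop("no candidate guides supplied")
  cover <- vapply(candidates, function(gd) {
    prof <- build_targeting_profile(gd, family, genes,
                                    score_cutoff = score_cutoff, pam_mode = pam_mode)
    round(prof$f0 * prof$n_considered)
  }, numeric(1))
  score <- vapply(candidates, function(gd) {
    if (is.na(gd$design_score)) -Inf else gd$design_score
  }, numeric(1))
  ids <- vapply(candidates, `[[`, character(1), "guide_id")
  ord <- order(-cover, -score, ids)
  candidates[[ord[1L]]]
}

#' Overlap of a hit with annotated tRNA functional elements
#'
#' Intersects the protospacer-matched window with the gene's annotated A box,
#' B box and anticodon-loop intervals, and reports which gene-body positions
#' the window covers (for position-coverage histograms of a guide library).
#'
#' @param hit A \code{target_hit} row (must not be untargeted).
#' @param gene The \code{\link{trna_gene}} the hit refers to.
#' @param spacer_length Window length (default 20).
#' @return List with \code{flags} (named logical per annotated element) and
#'   \code{covered} (0-based gene-body positions under the window).
#' @export
element_overlap <- function(hit, gene, spacer_length = 20L) {
  if (is_untargeted(hit)) stop("hit is untargeted; no window to intersect")
  if (!is.na(hit$gene_id) && hit$gene_id != gene$gene_id) {
    stop("hit refers to gene ", hit$gene_id, ", not ", gene$gene_id)
  }
  body_len <- nchar(gene$sequence) - 2L * gene$flank
  w_start <- hit$offset - gene$flank          # window in gene-body coordinates
  w_end <- w_start + spacer_length
  flags <- vapply(gene$elements, function(iv) {
    max(w_start, iv[1]) < min(w_end, iv[2])
  }, logical(1))
  covered <- seq.int(max(w_start, 0L), min(w_end, body_len) - 1L)
  if (length(covered) && (max(w_start, 0L) >= min(w_end, body_len))) covered <- integer(0)
  list(flags = flags, covered = covered)
}

#' Per-nucleotide coverage of gene bodies by a guide library
#'
#' Sums, over all (guide, gene) best hits within the mismatch cap, how many
#' guides cover each gene-body position — the data behind a
#' position-along-the-tRNA coverage histogram.
#'
#' @param library Named list of \code{\link{guide_rna}}.
#' @param genes Named list of \code{\link{trna_gene}}.
#' @param pam_mode Passed to \code{\link{min_mismatch_hit}}.
#' @return Named list per gene of integer coverage vectors (one entry per
#'   gene-body position).
#' @export
coverage_histogram <- function(library, genes, pam_mode = c("NGG", "none")) {
  pam_mode <- match.arg(pam_mode)
  out <- lapply(genes, function(g) {
    body_len <- nchar(g$sequence) - 2L * g$flank
    cov <- integer(body_len)
    for (gd in library) {
      hit <- min_mismatch_hit(gd, g, pam_mode = pam_mode)
      if (!is_untargeted(hit)) {
        ov <- element_overlap(hit, g, spacer_length = nchar(gd$protospacer))
        cov[ov$covered + 1L] <- cov[ov$covered + 1L] + 1L
      }
    }
    cov
  })
  names(out) <- names(genes)
  out
}
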