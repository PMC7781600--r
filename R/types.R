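#' tRNA gene record
#'
#' A tRNA gene as used throughout the package: the genomic top-strand sequence
#' of the gene body plus fixed-length flanks, its isodecoder family label
#' (amino acid + anticodon, e.g. \code{"LeuTAG"}), a tRNAscan-SE-style quality
#' score, optional functional-element intervals, and a classification label.
#'
#' Element intervals (\code{a_box}, \code{b_box}, \code{anticodon}) are
#' 0-based, half-open, local to the gene body (i.e. position 0 is the first
#' base after the upstream flank).
#'
#' @param gene_id Character identifier, unique within a gene set.
#' @param family_id Isodecoder family label shared by all family members.
#' @param sequence DNA string over A, C, G, T, N (top strand, 5'->3').
#' @param trna_score Numeric quality score (dimensionless); genes scoring at or
#'   below the profile cutoff are excluded from family fractions unless the
#'   family is a pseudogene family.
#' @param class_label One of \code{"proliferation"}, \code{"differentiation"},
#'   \code{"other"}, \code{"pseudo"}.
#' @param flank Length (nt) of flanking sequence included on each side of the
#'   gene body. Default 10, enough to make PAM sites at the gene edge scannable.
#' @param elements Named list of integer intervals \code{c(start, end)}
#'   (0-based, half-open, gene-body-local), typically \code{a_box},
#'   \code{b_box}, \code{anticodon}. May be empty.
#' @return An object of class \code{"trna_gene"}.
#' @export
trna_gene <- function(gene_id, family_id, sequence, trna_score = NA_real_,
                      class_label = c("other", "proliferation", "differentiation", "pseudo"),
                      flank = 10L, elements = list()) {
  class_label <- match.arg(class_label)
  sequence <- toupper(sequence)
  .assert_dna(sequence, paste0("gene ", gene_id))
  body_len <- nchar(sequence) - 2L * flank
  if (body_len < 1L) stop("gene ", gene_id, ": sequence shorter than twice the flank length")
  for (el in names(elements)) {
    iv <- elements[[el]]
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > body_len || iv[1] >= iv[2]) {
      stop("gene ", gene_id, ": element '", el, "' interval outside the gene body")
    }
  }
  structure(
    list(gene_id = as.character(gene_id), family_id = as.character(family_id),
         sequence = sequence, trna_score = as.numeric(trna_score),
         class_label = class_label, flank = as.integer(flank),
         elements = elements),
    class = "trna_gene"
  )
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(sprintf("<trna_gene> %s [%s, %s] score=%s, %d nt (+%d nt flanks)\n",
              x$gene_id, x$family_id, x$class_label, format(x$trna_score),
              nchar(x$sequence) - 2L * x$flank, x$flank))
  invisible(x)
}

#' tRNA isodecoder family
#'
#' Groups member genes under a family label. All members must carry the same
#' \code{family_id} and member ids must be unique.
#'
#' @param family_id Family label.
#' @param member_gene_ids Character vector of member gene ids (ordered).
#' @param class_label Classification label shared by the family.
#' @return An object of class \code{"trna_family"}.
#' @export
trna_family <- function(family_id, member_gene_ids,
                        class_label = c("other", "proliferation", "differentiation", "pseudo")) {
  class_label <- match.arg(class_label)
  member_gene_ids <- as.character(member_gene_ids)
  if (anyDuplicated(member_gene_ids)) stop("family ", family_id, ": duplicated member gene ids")
  if (length(member_gene_ids) < 1L) stop("family ", family_id, ": no members")
  structure(list(family_id = as.character(family_id),
                 member_gene_ids = member_gene_ids,
                 class_label = class_label),
            class = "trna_family")
}

#' Derive families from a gene collection
#'
#' @param genes List of \code{\link{trna_gene}} objects.
#' @return Named list of \code{\link{trna_family}} objects, one per distinct
#'   \code{family_id}, members in input order.
#' @export
families_from_genes <- function(genes) {
  fam_ids <- vapply(genes, `[[`, character(1), "family_id")
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  cls <- vapply(genes, `[[`, character(1), "class_label")
  out <- lapply(unique(fam_ids), function(f) {
    sel <- fam_ids == f
    labs <- unique(cls[sel])
    if (length(labs) > 1L) {
      stop("family ", f, ": members carry conflicting class labels (",
           paste(labs, collapse = ", "), ")")
    }
    trna_family(f, gene_ids[sel], labs)
  })
  names(out) <- unique(fam_ids)
  out
}

#' Guide RNA record
#'
#' @param guide_id Character identifier.
#' @param protospacer DNA string; its length must equal \code{spacer_length}.
#' @param intended_family Family the guide was designed against.
#' @param design_score Optional dimensionless design score used only for
#'   tie-breaking in \code{\link{select_family_guide}}.
#' @param spacer_length Configured spacer length (default 20).
#' @return An object of class \code{"guide_rna"}.
#' @export
guide_rna <- function(guide_id, protospacer, intended_family,
                      design_score = NA_real_, spacer_length = 20L) {
  protospacer <- toupper(protospacer)
  .assert_dna(protospacer, paste0("guide ", guide_id))
  if (nchar(protospacer) != spacer_length) {
    stop("guide ", guide_id, ": protospacer length ", nchar(protospacer),
         " != configured spacer length ", spacer_length)
  }
  structure(list(guide_id = as.character(guide_id), protospacer = protospacer,
                 intended_family = as.character(intended_family),
                 design_score = as.numeric(design_score)),
            class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s -> %s: %s\n", x$guide_id, x$intended_family, x$protospacer))
  invisible(x)
}

# ---- I/O -------------------------------------------------------------------

#' Read tRNA genes from FASTA
#'
#' Header convention: \code{>gene_id|family_id|score|class_label}. Element
#' annotations can be supplied as a BED-like TSV with columns
#' \code{gene_id, element, start, end} (0-based, half-open, gene-body-local).
#'
#' @param fasta Path to a FASTA file.
#' @param elements Optional path to the element TSV.
#' @param flank Flank length included in each record (nt).
#' @return Named list of \code{\link{trna_gene}} objects.
#' @export
read_trna_fasta <- function(fasta, elements = NULL, flank = 10L) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  el_tab <- NULL
  if (!is.null(elements)) {
    el_tab <- utils::read.delim(elements, stringsAsFactors = FALSE)
    need <- c("gene_id", "element", "start", "end")
    if (!all(need %in% names(el_tab))) {
      stop("element table must have columns: ", paste(need, collapse = ", "))
    }
  }
  genes <- lapply(seq_along(seqs), function(i) {
    parts <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]]
    if (length(parts) != 4L) {
      stop("FASTA header '", names(seqs)[i],
           "' does not follow gene_id|family_id|score|class_label")
    }
    els <- list()
    if (!is.null(el_tab)) {
      rows <- el_tab[el_tab$gene_id == parts[1], , drop = FALSE]
      els <- stats::setNames(
        lapply(seq_len(nrow(rows)), function(j) c(rows$start[j], rows$end[j])),
        rows$element)
    }
    trna_gene(parts[1], parts[2], as.character(seqs[[i]]),
              trna_score = suppressWarnings(as.numeric(parts[3])),
              class_label = parts[4], flank = flank, elements = els)
  })
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  genes
}

#' Write tRNA genes to FASTA (and optionally their element annotations)
#'
#' @param genes Named list of \code{\link{trna_gene}} objects.
#' @param fasta Output FASTA path.
#' @param elements Optional output path for the element TSV.
#' @return Invisibly, the FASTA path.
#' @export
write_trna_fasta <- function(genes, fasta, elements = NULL) {
  seqs <- Biostrings::DNAStringSet(vapply(genes, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(genes, function(g) {
    paste(g$gene_id, g$family_id, format(g$trna_score), g$class_label, sep = "|")
  }, character(1))
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(elements)) {
    rows <- do.call(rbind, lapply(genes, function(g) {
      if (length(g$elements) == 0L) return(NULL)
      data.frame(gene_id = g$gene_id, element = names(g$elements),
                 start = vapply(g$elements, `[`, numeric(1), 1),
                 end = vapply(g$elements, `[`, numeric(1), 2),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, elements, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Read a guide manifest
#'
#' TSV with columns \code{guide_id, protospacer, intended_family} and
#' optionally \code{design_score}.
#'
#' @param path Path to the TSV.
#' @param spacer_length Expected protospacer length.
#' @return Named list of \code{\link{guide_rna}} objects.
#' @export
read_guide_manifest <- function(path, spacer_length = 20L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("guide_id", "protospacer", "intended_family")
  if (!all(need %in% names(tab))) {
    stop("guide manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$design_score)) tab$design_score <- NA_real_
  guides <- lapply(seq_len(nrow(tab)), function(i) {
    guide_rna(tab$guide_id[i], tab$protospacer[i], tab$intended_family[i],
              tab$design_score[i], spacer_length = spacer_length)
  })
  names(guides) <- tab$guide_id
  guides
}

#' Read a count table with its sample metadata sidecar
#'
#' The count TSV has feature ids in the first column and one column per
#' sample; the sidecar maps \code{sample_id} to experimental covariates.
#'
#' @param counts Path to the count TSV.
#' @param samples Path to the sample metadata TSV (must contain
#'   \code{sample_id} matching the count columns).
#' @return List with \code{counts} (numeric matrix, features x samples) and
#'   \code{samples} (data.frame).
#' @export
read_count_table <- function(counts, samples) {
  ct <- utils::read.delim(counts, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(ct[, -1, drop = FALSE])
  rownames(mat) <- ct[[1]]
  storage.mode(mat) <- "numeric"
  if (any(mat < 0, na.rm = TRUE)) stop("count table contains negative values")
  meta <- utils::read.delim(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("sample metadata must contain sample_id")
  missing <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing)) stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  list(counts = mat, samples = meta)
}
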