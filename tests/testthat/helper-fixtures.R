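# shared fixtures and independent oracles

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

make_gene <- function(sequence, gene_id = "g1", family_id = "FamX", score = 70,
                      class_label = "other", flank = 0L, elements = list()) {
  trna_gene(gene_id, family_id, sequence, trna_score = score,
            class_label = class_label, flank = flank, elements = elements)
}

make_guide <- function(protospacer, guide_id = "sg1", family = "FamX", score = NA) {
  guide_rna(guide_id, protospacer, family, design_score = score)
}

# brute-force minimum-mismatch oracle: plain double loop over every window on
# both strands, written independently of the package's scanner
bf_mm_count <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

bf_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]), collapse = "")
}

bf_min_mismatch <- function(spacer, seqstr, pam = "NGG", cap = 3L) {
  L <- nchar(spacer)
  n <- nchar(seqstr)
  best <- Inf
  for (i in 0:(n - L)) {                       # i = 0-based window offset
    w <- substr(seqstr, i + 1, i + L)
    ok_plus <- pam == "none" ||
      (i + L + 3 <= n && substr(seqstr, i + L + 2, i + L + 3) == "GG")
    if (ok_plus) best <- min(best, bf_mm_count(w, spacer))
    ok_minus <- pam == "none" ||
      (i - 2 >= 1 && substr(seqstr, i - 2, i - 1) == "CC")
    if (ok_minus) best <- min(best, bf_mm_count(bf_revcomp(w), spacer))
  }
  if (best > cap) NA_integer_ else as.integer(best)
}

# plant a spacer (with optional substitutions and a plus-strand NGG PAM) into
# a random background at a given 0-based offset
plant_site <- function(background, spacer, offset, n_sub = 0L, pam = TRUE) {
  chars <- strsplit(background, "", fixed = TRUE)[[1]]
  sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
  if (n_sub > 0L) {
    pos <- sample(seq_along(sp), n_sub)
    for (p in pos) sp[p] <- setdiff(c("A", "C", "G", "T"), sp[p])[1]
  }
  chars[offset + seq_along(sp)] <- sp
  if (pam) {
    chars[offset + length(sp) + 2L] <- "G"
    chars[offset + length(sp) + 3L] <- "G"
  }
  paste(chars, collapse = "")
}

# four-member synthetic family in which `n_exact` members carry the spacer
# verbatim and the rest carry it with `sub_levels` substitutions each
make_family_fixture <- function(spacer, levels, family_id = "FamX",
                                class_label = "other", score = 70) {
  genes <- lapply(seq_along(levels), function(k) {
    bg <- rand_seq(60)
    seqstr <- if (is.na(levels[k])) bg else {
      chars <- strsplit(bg, "", fixed = TRUE)[[1]]
      sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
      if (levels[k] > 0) {
        for (p in c(2, 5, 8, 11, 14)[seq_len(levels[k])]) {
          sp[p] <- setdiff(c("A", "C", "G", "T"), sp[p])[1]
        }
      }
      chars[10 + seq_along(sp)] <- sp
      chars[10 + 22] <- "G"; chars[10 + 23] <- "G"
      paste(chars, collapse = "")
    }
    make_gene(seqstr, gene_id = paste0(family_id, "-", k), family_id = family_id,
              score = score, class_label = class_label)
  })
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  genes
}
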