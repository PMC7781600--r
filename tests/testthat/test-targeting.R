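test_that("min_mismatch_hit finds verbatim and reverse-complement sites", {
  set.seed(101)
  spacer <- rand_seq(20)
  gene_plus <- plant_site(rand_seq(60), spacer, offset = 15)
  hit <- min_mismatch_hit(spacer, gene_plus, pam_mode = "NGG")
  expect_identical(hit$mismatches, 0L)
  expect_identical(hit$strand, "+")
  expect_identical(hit$offset, 15L)

  # plant the site on the minus strand: embed revcomp(spacer) preceded by CC
  bg <- strsplit(rand_seq(60), "", fixed = TRUE)[[1]]
  rc <- strsplit(bf_revcomp(spacer), "", fixed = TRUE)[[1]]
  bg[20 + seq_along(rc)] <- rc
  bg[18] <- "C"; bg[19] <- "C"
  hit_m <- min_mismatch_hit(spacer, paste(bg, collapse = ""), pam_mode = "NGG")
  expect_identical(hit_m$mismatches, 0L)
  expect_identical(hit_m$strand, "-")
  expect_identical(hit_m$offset, 20L)
})

test_that("planted substitutions are counted exactly and ties prefer plus strand / smaller offset", {
  set.seed(102)
  for (i in 1:10) {
    spacer <- rand_seq(20)
    gene <- plant_site(rand_seq(80), spacer, offset = 30, n_sub = 2)
    hit <- min_mismatch_hit(spacer, gene, pam_mode = "NGG")
    expect_identical(hit$mismatches, bf_min_mismatch(spacer, gene))
    expect_identical(hit$mismatches, 2L)
  }
  # same site planted twice: the smaller offset wins
  spacer <- rand_seq(20)
  gene2 <- plant_site(plant_site(rand_seq(100), spacer, offset = 50), spacer, offset = 10)
  hit2 <- min_mismatch_hit(spacer, gene2, pam_mode = "NGG")
  expect_identical(hit2$offset, 10L)
  expect_identical(hit2$strand, "+")
})

test_that("mismatch scanning equals the brute-force oracle on random pairs", {
  set.seed(103)
  for (pam in c("NGG", "none")) {
    for (i in 1:120) {
      spacer <- rand_seq(20)
      n_sub <- sample(0:5, 1)
      gene <- if (i %% 3 == 0) rand_seq(60) else {
        plant_site(rand_seq(60), spacer, offset = sample(0:35, 1),
                   n_sub = n_sub, pam = sample(c(TRUE, FALSE), 1))
      }
      expect_identical(min_mismatch_hit(spacer, gene, pam_mode = pam)$mismatches,
                       bf_min_mismatch(spacer, gene, pam = pam),
                       info = paste("pam", pam, "iter", i))
    }
  }
})

test_that("invalid characters error and N counts as a mismatch", {
  expect_error(min_mismatch_hit(rand_seq(20), paste0(rand_seq(30), "X", rand_seq(10))),
               "outside")
  spacer <- rand_seq(20)
  gene <- plant_site(rand_seq(60), spacer, offset = 10)
  chars <- strsplit(gene, "", fixed = TRUE)[[1]]
  chars[10 + 3] <- "N"
  hit <- min_mismatch_hit(spacer, paste(chars, collapse = ""), pam_mode = "NGG")
  expect_identical(hit$mismatches, 1L)
})

test_that("targeting profiles reproduce planted member fractions", {
  set.seed(104)
  spacer <- rand_seq(20)
  # 3 exact + 1 single-substitution member
  genes <- make_family_fixture(spacer, levels = c(0, 0, 0, 1))
  fam <- trna_family("FamX", names(genes))
  guide <- make_guide(spacer)
  prof <- build_targeting_profile(guide, fam, genes)
  expect_equal(c(prof$f0, prof$f1, prof$f2, prof$f3), c(0.75, 0.25, 0, 0))
  expect_identical(prof$n_considered, 4L)

  # unrelated family: all fractions zero
  genes_u <- make_family_fixture(spacer, levels = rep(NA, 3))
  prof_u <- build_targeting_profile(guide, trna_family("FamX", names(genes_u)), genes_u)
  expect_equal(c(prof_u$f0, prof_u$f1, prof_u$f2, prof_u$f3), c(0, 0, 0, 0))

  # 2 full, 2 at two mismatches, 1 at five (untargeted)
  genes_m <- make_family_fixture(spacer, levels = c(0, 0, 2, 2, 5))
  prof_m <- build_targeting_profile(guide, trna_family("FamX", names(genes_m)), genes_m)
  expect_equal(c(prof_m$f0, prof_m$f1, prof_m$f2, prof_m$f3), c(0.4, 0, 0.4, 0))
  expect_true(prof_m$f0 + prof_m$f1 + prof_m$f2 + prof_m$f3 <= 1)
})

test_that("score filtering excludes weak genes except in pseudo families", {
  set.seed(105)
  spacer <- rand_seq(20)
  genes <- make_family_fixture(spacer, levels = c(0, 0, 1))
  genes[[3]]$trna_score <- 40       # below cutoff: dropped from fractions
  fam <- trna_family("FamX", names(genes))
  prof <- build_targeting_profile(make_guide(spacer), fam, genes)
  expect_identical(prof$n_considered, 2L)
  expect_equal(prof$f0, 1)

  # pseudo family: same scores, but all members considered
  genes_p <- make_family_fixture(spacer, levels = c(0, 0, 1),
                                 family_id = "PseuX", class_label = "pseudo",
                                 score = 30)
  fam_p <- trna_family("PseuX", names(genes_p), class_label = "pseudo")
  prof_p <- build_targeting_profile(make_guide(spacer, family = "PseuX"), fam_p, genes_p)
  expect_identical(prof_p$n_considered, 3L)

  genes[[1]]$trna_score <- 10; genes[[2]]$trna_score <- 10
  expect_error(build_targeting_profile(make_guide(spacer), fam, genes), "no member passes")
})

test_that("classify_on_off flags full-match OFF-targets and handles an empty library", {
  set.seed(106)
  spacer_a <- rand_seq(20)
  spacer_b <- rand_seq(20)
  genes <- c(make_family_fixture(spacer_a, levels = c(0, 0), family_id = "FamA"),
             make_family_fixture(spacer_b, levels = c(0, 0), family_id = "FamB"),
             make_family_fixture(spacer_a, levels = c(0), family_id = "FamC"))
  guides <- list(sgA = make_guide(spacer_a, "sgA", "FamA"),
                 sgB = make_guide(spacer_b, "sgB", "FamB"))
  expect_warning(tab <- classify_on_off(guides, genes), "full-match OFF-target")
  expect_true(tab$full_match_off[tab$guide_id == "sgA" & tab$family_id == "FamC"])
  expect_identical(tab$min_mismatch[tab$guide_id == "sgA" & tab$family_id == "FamA"], 0L)
  expect_true(is.na(tab$min_mismatch[tab$guide_id == "sgB" & tab$family_id == "FamC"]))

  empty <- classify_on_off(list(), genes)
  expect_identical(nrow(empty), 0L)
})

test_that("select_family_guide maximizes full-match coverage with deterministic tie-breaks", {
  set.seed(107)
  spacer_a <- rand_seq(20)
  spacer_b <- rand_seq(20)
  genes <- c(make_family_fixture(spacer_a, levels = c(0, 0, 0, 0, 0), family_id = "FamX"),
             make_family_fixture(spacer_b, levels = c(0, 0, 0), family_id = "FamY"))
  # FamX genes 4-5 replaced so candidate B only matches 3 of 6
  genes <- c(genes[1:5],
             make_family_fixture(spacer_b, levels = c(0), family_id = "FamX")["FamX-1"])
  names(genes)[6] <- "FamX-6"; genes[[6]]$gene_id <- "FamX-6"
  fam <- trna_family("FamX", names(genes)[c(1:5, 6)])
  cand <- list(make_guide(spacer_a, "cA"), make_guide(spacer_b, "cB"))
  expect_identical(select_family_guide(cand, fam, genes)$guide_id, "cA")
  expect_identical(select_family_guide(rev(cand), fam, genes)$guide_id, "cA")

  # equal coverage: higher design score wins, then lexicographic id
  cand2 <- list(make_guide(spacer_a, "cA", score = 1), make_guide(spacer_a, "cB", score = 5))
  expect_identical(select_family_guide(cand2, fam, genes)$guide_id, "cB")
  cand3 <- list(make_guide(spacer_a, "cB"), make_guide(spacer_a, "cA"))
  expect_identical(select_family_guide(cand3, fam, genes)$guide_id, "cA")

  expect_error(select_family_guide(list(), fam, genes), "no candidate")
})

test_that("element overlap flags intervals correctly and coverage counts conserve", {
  set.seed(108)
  spacer <- rand_seq(20)
  seqstr <- plant_site(rand_seq(92), spacer, offset = 30)  # flank 10 + body offset 20
  gene <- trna_gene("g1", "FamX", seqstr, trna_score = 70, flank = 10L,
                    elements = list(a_box = c(12, 23), b_box = c(52, 62),
                                    anticodon = c(30, 37)))
  hit <- min_mismatch_hit(make_guide(spacer), gene)
  ov <- element_overlap(hit, gene)
  expect_true(ov$flags[["anticodon"]])   # window [20, 40) covers [30, 37)
  expect_false(ov$flags[["b_box"]])
  expect_identical(ov$covered, 20:39)

  hit_up <- hit; hit_up$offset <- 0L     # window fully in the upstream flank + body start
  ov_up <- element_overlap(hit_up, gene)
  expect_false(any(ov_up$flags))

  # conservation: summed per-nucleotide counts equal summed overlap lengths
  guides <- list(g1 = make_guide(spacer, "s1", "FamX"))
  cov <- coverage_histogram(guides, list(g1 = gene))
  expect_identical(sum(cov$g1), length(ov$covered))

  expect_error(element_overlap(hit, trna_gene("g2", "FamX", seqstr, flank = 10L)),
               "refers to gene")
})
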