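test_that("top/bottom gating selects exact tail fractions with stable ties", {
  set.seed(601)
  ev <- data.frame(mCherry = runif(100, 100, 5000), FSC = runif(100, 50, 150))
  bins <- gate_top_bottom(ev, fraction = 0.05)
  expect_identical(sum(bins == "H"), 5L)
  expect_identical(sum(bins == "L"), 5L)
  expect_identical(sum(bins == "H" & bins == "L"), 0L)
  # H bin really is the top of the ratio distribution
  ratio <- ev$mCherry / ev$FSC
  expect_true(min(ratio[bins == "H"]) >= max(ratio[bins == "none"]))
  expect_true(max(ratio[bins == "L"]) <= min(ratio[bins == "none"]))

  ev_tie <- data.frame(mCherry = rep(1000, 40), FSC = rep(100, 40))
  expect_warning(bt <- gate_top_bottom(ev_tie, 0.05), "same ratio")
  expect_identical(which(bt == "L"), 1:2)
  expect_identical(which(bt == "H"), 39:40)

  # planted bimodal ratios: H contains only the high mode
  ev_bi <- data.frame(mCherry = c(rep(300, 90), rep(3000, 10)), FSC = 100)
  bb <- gate_top_bottom(ev_bi, 0.05)
  expect_true(all(which(bb == "H") > 90))

  expect_error(gate_top_bottom(ev, 0.6), "fraction")
  expect_error(gate_top_bottom(ev, 0), "fraction")
  expect_error(gate_top_bottom(ev[1:5, ], 0.05), "too few")
})

test_that("bin enrichment is ancestor-normalized, finite, and depth-invariant", {
  counts <- cbind(Q_H_r1 = c(100, 100, 100), Q_L_r1 = c(50, 100, 150),
                  anc_r1 = c(100, 100, 100))
  rownames(counts) <- paste0("v", 1:3)
  samples <- data.frame(sample_id = colnames(counts),
                        treatment = c("Q", "Q", "ancestor"),
                        bin = c("H", "L", "none"), replicate = 1,
                        is_ancestor = c(FALSE, FALSE, TRUE))
  en <- bin_enrichment(counts, samples, pseudocount = 0)
  expect_equal(unname(en[, "Q_H"]), c(0, 0, 0))

  # variant absent from a bin: strongly negative but finite with pseudocounts
  counts2 <- counts; counts2["v1", "Q_H_r1"] <- 0
  en2 <- bin_enrichment(counts2, samples, pseudocount = 0.5)
  expect_true(is.finite(en2["v1", "Q_H"]))
  expect_equal(en2["v1", "Q_H"],
               log2((0.5 / 201.5) / (100.5 / 301.5)), tolerance = 1e-12)

  # doubling a bin's sequencing depth leaves enrichment unchanged
  counts3 <- counts; counts3[, "Q_H_r1"] <- counts3[, "Q_H_r1"] * 2
  en3 <- bin_enrichment(counts3, samples, pseudocount = 0)
  expect_equal(en3[, "Q_H"], en[, "Q_H"], tolerance = 1e-12)

  expect_error(bin_enrichment(counts, transform(samples, is_ancestor = FALSE)),
               "ancestor")
})

test_that("two-way clustering is deterministic and recovers planted structure", {
  set.seed(602)
  base <- matrix(rnorm(40), nrow = 10,
                 dimnames = list(paste0("v", 1:10), c("a", "b", "c", "d")))
  base[, "b"] <- base[, "a"]          # identical columns merge first
  cl <- two_way_cluster(base, col_metric = "euclidean")
  first <- cl$col$merge[1, ]
  expect_setequal(colnames(base)[-first], c("a", "b"))

  # planted two-group sample structure: the top split separates the groups
  grp <- cbind(g1a = c(rep(5, 5), rep(0, 5)), g1b = c(rep(5, 5), rep(0, 5)) + rnorm(10, 0, 0.1),
               g2a = c(rep(0, 5), rep(5, 5)), g2b = c(rep(0, 5), rep(5, 5)) + rnorm(10, 0, 0.1))
  rownames(grp) <- paste0("v", 1:10)
  cl2 <- two_way_cluster(grp, col_metric = "euclidean")
  k2 <- stats::cutree(cl2$col, k = 2)
  expect_identical(unname(k2["g1a"]), unname(k2["g1b"]))
  expect_identical(unname(k2["g2a"]), unname(k2["g2b"]))
  expect_false(k2[["g1a"]] == k2[["g2a"]])

  # permutation equivariance: same merge heights, same memberships
  perm <- sample(nrow(grp))
  cl3 <- two_way_cluster(grp[perm, ], col_metric = "euclidean")
  expect_equal(sort(cl3$row$height), sort(cl2$row$height), tolerance = 1e-12)
  k_orig <- stats::cutree(cl2$row, k = 2)
  k_perm <- stats::cutree(cl3$row, k = 2)[names(k_orig)]
  expect_identical(unname(k_orig == k_orig[1]), unname(k_perm == k_perm[1]))

  expect_warning(expect_warning(two_way_cluster(matrix(1, 3, 3)), "zero-variance"),
                 "constant matrix")
  expect_error(two_way_cluster(matrix(1, 1, 3)), "at least 2")
})

test_that("high-reporter fractions and the control comparison behave as designed", {
  ev_all <- data.frame(variant = "v1", replicate = rep(1:3, each = 10),
                       mCherry = 5000)
  ctrl <- data.frame(variant = "control", replicate = rep(1:3, each = 10),
                     mCherry = rep(c(5000, 100), 15))
  res <- high_fraction_test(rbind(ev_all, ctrl), threshold = 1700)
  expect_equal(res$mean_fraction[res$variant == "v1"], 1)

  # identical replicate fractions give a null test
  same <- rbind(transform(ctrl, variant = "v2"), ctrl)
  res2 <- high_fraction_test(same, threshold = 1700)
  expect_equal(res2$t_stat[res2$variant == "v2"], 0)
  expect_equal(res2$p_value[res2$variant == "v2"], 1)

  # planted responder-probability shift is recovered within binomial error
  set.seed(603)
  n <- 2000
  mk <- function(v, p) data.frame(
    variant = v, replicate = rep(1:3, each = n),
    mCherry = ifelse(rbinom(3 * n, 1, p) == 1, 3000, 300))
  res3 <- high_fraction_test(rbind(mk("hi", 0.8), mk("control", 0.5)),
                             threshold = 1700)
  diff_hat <- res3$mean_fraction[res3$variant == "hi"] -
    res3$mean_fraction[res3$variant == "control"]
  expect_lt(abs(diff_hat - 0.3), 4 * sqrt(0.25 / (3 * n)) * 2)
  expect_lt(res3$p_value[res3$variant == "hi"], 0.05)

  single <- data.frame(variant = c("v9", "control"), replicate = 1,
                       mCherry = c(5000, 100))
  expect_warning(res4 <- high_fraction_test(single, threshold = 1700), "fewer than 2")
  expect_true(is.na(res4$t_stat[res4$variant == "v9"]))
  expect_error(high_fraction_test(ev_all, control = "nope"), "not present")
})

test_that("essentiality classification recovers the four archetypes and is monotone", {
  fitness <- rbind(
    ess_all = c(-5, -4, -6),
    prolif = c(-5, -3, -2),
    arrest = c(0, -0.2, 0.1),
    disp = c(-0.1, 0, -0.5),
    incomplete = c(NA, -2, -2))
  colnames(fitness) <- c("HeLa", "WI38_fast", "WI38_slow")
  arrest <- c(ess_all = -3, prolif = 1, arrest = -2.5, disp = -0.4, incomplete = -3)
  cls <- classify_essentiality(fitness, arrest)
  got <- setNames(cls$class, cls$family)
  expect_identical(unname(got[c("ess_all", "prolif", "arrest", "disp", "incomplete")]),
                   c("essential_all", "proliferation_essential",
                     "arrest_essential", "dispensable", "incomplete"))

  # monotonicity: making any score more negative never leaves the essential classes
  rank_of <- c(dispensable = 0, proliferation_essential = 1,
               arrest_essential = 1, essential_all = 2)
  set.seed(604)
  for (i in 1:25) {
    f <- matrix(runif(6, -3, 1), nrow = 2,
                dimnames = list(c("fA", "fB"), c("c1", "c2", "c3")))
    a <- c(fA = runif(1, -3, 1), fB = runif(1, -3, 1))
    base_cls <- classify_essentiality(f, a)
    f2 <- f - matrix(runif(6, 0, 2), nrow = 2)
    a2 <- a - runif(2, 0, 2)
    harder <- classify_essentiality(f2, a2)
    expect_true(all(rank_of[harder$class] >= rank_of[base_cls$class]))
  }
})
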