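test_that("simulation output is byte-identical for identical config and seed", {
  cfg <- sim_config(seed = 11, n_families = 6L)
  a <- simulate_family_set(cfg)
  b <- simulate_family_set(cfg)
  expect_identical(a, b)
  ca <- simulate_competition(cfg, a$truth$M)
  cb <- simulate_competition(cfg, b$truth$M)
  expect_identical(ca, cb)
  expect_identical(simulate_arrest(cfg, a), simulate_arrest(cfg, b))
  expect_identical(simulate_trnaseq(cfg, a), simulate_trnaseq(cfg, b))
})

test_that("planted mismatch spectra are realized exactly by the measured profiles", {
  cfg <- sim_config(seed = 12, n_families = 8L,
                    own_spectrum = c(list(c(0.75, 0.25, 0, 0)),
                                     rep(list(c(1, 0, 0, 0)), 7)))
  fs <- simulate_family_set(cfg)
  prof1 <- build_targeting_profile(fs$guides[[1]], fs$families[[1]], fs$genes)
  expect_equal(c(prof1$f0, prof1$f1, prof1$f2, prof1$f3), c(0.75, 0.25, 0, 0))

  # zero divergence: every other family fully matched by its own guide
  prof2 <- build_targeting_profile(fs$guides[[2]], fs$families[[2]], fs$genes)
  expect_equal(prof2$f0, 1)

  # planted cross-family off-targets are seen by the classifier at the planted level
  tab <- suppressWarnings(classify_on_off(fs$guides, fs$genes, fs$families))
  ot <- cfg$offtargets
  for (r in seq_len(nrow(ot))) {
    row <- tab[tab$guide_id == names(fs$guides)[ot$guide_family[r]] &
                 tab$family_id == cfg$family_ids[ot$target_family[r]], ]
    expect_identical(row$min_mismatch, as.integer(ot$s[r]))
  }

  # measured reduction matrix equals the generating one exactly
  prof <- do.call(rbind, lapply(fs$guides, function(gd) {
    do.call(rbind, lapply(fs$families, function(fam) {
      build_targeting_profile(gd, fam, fs$genes)
    }))
  }))
  M <- build_reduction_matrix(prof, families = cfg$family_ids,
                              guides = names(fs$guides))
  expect_equal(unclass(M), unclass(fs$truth$M))
})

test_that("infeasible spectra are rejected at configuration time", {
  expect_error(sim_config(seed = 1, members_per_family = 3L,
                          own_spectrum = list(c(0.75, 0.25, 0, 0))),
               "not expressible")
  expect_error(sim_config(seed = 1, offtargets = data.frame(
    guide_family = 1L, target_family = 2L, s = 1L, fraction = 0.3)),
    "not expressible")
  expect_error(sim_config(seed = 1, offtargets = data.frame(
    guide_family = c(1L, 3L), target_family = c(2L, 2L), s = 1L, fraction = 0.5)),
    "one planted off-target")
})

test_that("null competitions read out near-zero fitness and planted deficits follow the model", {
  # all-zero fitness: realized fitness within multinomial error of 0
  cfg0 <- sim_config(seed = 13, R_raw = rep(0, 20))
  fs0 <- simulate_family_set(cfg0)
  comp0 <- simulate_competition(cfg0, fs0$truth$M)
  fit0 <- relative_fitness(to_frequencies(comp0$counts), comp0$samples, day = 7)
  expect_lt(max(abs(as.numeric(fit0))), 0.05)

  # diagonal system, one planted deficit: expected day-t change is rate * t
  cfg1 <- sim_config(seed = 14, n_families = 5L, offtargets = data.frame(
    guide_family = integer(), target_family = integer(), s = integer(),
    fraction = numeric()),
    own_spectrum = rep(list(c(1, 0, 0, 0)), 5),
    R_raw = c(-3, 0, 0, 0, 0), depth = 1e6)
  fs1 <- simulate_family_set(cfg1)
  expect_true(all(unclass(fs1$truth$M) == diag(5)))
  comp1 <- simulate_competition(cfg1, fs1$truth$M)
  fit1 <- relative_fitness(to_frequencies(comp1$counts), comp1$samples, day = 7)
  expect_equal(unname(fit1["sgFam01"]), comp1$truth$expected_O[["sgFam01"]],
               tolerance = 0.02)
  # trajectory along days follows rate * t up to the compositional normalizer
  tc <- fitness_timecourse(comp1$counts, comp1$samples)
  expect_true(all(diff(tc["sgFam01", ]) < 0))

  # noise-free mode: deconvolution recovers the centered truth to 1e-9
  cfg2 <- sim_config(seed = 15, depth = Inf)
  fs2 <- simulate_family_set(cfg2)
  comp2 <- simulate_competition(cfg2, fs2$truth$M)
  fit2 <- relative_fitness(to_frequencies(comp2$counts, pseudocount = 0),
                           comp2$samples, day = 7)
  dec2 <- deconvolve(fit2, fs2$truth$M)
  expect_lt(max(abs(as.numeric(dec2$R) - comp2$truth$R_true)), 1e-9)
})

test_that("tRNA-seq simulation matches its analytic trajectories", {
  cfg <- sim_config(seed = 16, trnaseq_depth = Inf, trnaseq_families = c(1L, 17L, 20L))
  fs <- simulate_family_set(cfg)
  ts <- simulate_trnaseq(cfg, fs)
  fe <- family_expression(ts$counts, fs$genes)
  fc <- fold_change_table(fe, ts$samples, pseudocount = 0)

  for (cond in names(ts$truth$expected_fc)) {
    for (d in cfg$trnaseq_days[-1]) {
      got <- fc[fc$condition == cond & fc$day == d, ]
      want <- ts$truth$expected_fc[[cond]][got$family, as.character(d)]
      expect_equal(got$log2_fc, unname(want), tolerance = 1e-9,
                   info = paste(cond, "day", d))
    }
  }

  # untargeted (penalty-0) genes keep their exact relative proportions across
  # the time course: their trajectories are flat up to the within-sample
  # normalizer (family shares drift only by the ON-target's lost mass)
  s_cols <- grep("^Fam20_", colnames(ts$counts), value = TRUE)
  ratio <- ts$counts["Fam05-1", s_cols] / ts$counts["Fam06-1", s_cols]
  expect_true(all(abs(ratio - ratio[1]) < 1e-9))
  fc20 <- fc[fc$condition == "Fam20" & fc$family == "Fam05", ]
  expect_true(all(abs(fc20$log2_fc) < 0.2))

  # the ON-target fold-change dips and then recovers (minimum at an interior day)
  on1 <- fc[fc$condition == "Fam01" & fc$family == "Fam01", ]
  on1 <- on1[order(on1$day), ]
  expect_lt(which.min(on1$log2_fc), nrow(on1))
  expect_gt(which.min(on1$log2_fc), 1)
})

test_that("arrest simulation depletes non-responders from high bins as expected", {
  # all variants respond: high-bin composition matches the ancestor
  cfg1 <- sim_config(seed = 17, n_families = 6L)
  fs1 <- simulate_family_set(cfg1)
  pr <- matrix(0.9, nrow = 7, ncol = 3,
               dimnames = list(c(names(fs1$guides), "control"), c("U", "Q", "S")))
  cfg1 <- sim_config(seed = 17, n_families = 6L, responder_prob = pr)
  ar1 <- simulate_arrest(cfg1, fs1)
  en1 <- bin_enrichment(ar1$counts, ar1$samples)
  expect_lt(max(abs(en1[, "Q_H"])), 0.5)

  # one variant that never responds: strong high-bin depletion
  pr0 <- pr; pr0["sgFam02", c("Q", "S")] <- 0
  cfg2 <- sim_config(seed = 18, n_families = 6L, responder_prob = pr0)
  ar2 <- simulate_arrest(cfg2, simulate_family_set(cfg2))
  en2 <- bin_enrichment(ar2$counts, ar2$samples)
  expect_lt(en2["sgFam02", "Q_H"], -2)
  expect_lt(en2["sgFam02", "S_H"], -2)

  # emitted tables pass the consuming validators
  expect_true(all(abs(colSums(to_frequencies(ar2$counts)) - 1) < 1e-12))
  expect_identical(nrow(ar2$counts), 7L)
  expect_true(all(ar2$events$mCherry >= 0 & ar2$events$FSC >= 0))
})
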