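#' Simulation configuration
#'
#' Bundles every knob of the synthetic screen generator with validated
#' defaults chosen to emulate the study design: 20 isodecoder families (9
#' proliferation, 10 differentiation, 1 pseudo), one guide per family, a
#' planted off-target spectrum at 1-3 mismatches, exponential competition
#' over days 0-14 read at day 7 with 2 replicates at depth 1e6, a
#' rise-then-recovery editing time course, and bimodal
#' responder/non-responder reporter distributions under arrest treatments.
#'
#' @param seed Integer seed (mandatory); every downstream generator derives
#'   its RNG stream from it.
#' @param n_families Number of families (default 20).
#' @param members_per_family Members per family, scalar or vector (default 4).
#' @param body_length,flank Gene-body and flank lengths in nt.
#' @param class_labels Character vector per family; default 9 proliferation,
#'   then differentiation, last family pseudo (when \code{n_families >= 3}).
#' @param own_spectrum List (per family) of mismatch-fraction vectors
#'   \code{c(f0, f1, f2, f3)} for the family's own guide; fractions must be
#'   expressible with the member count. Default: full match everywhere except
#'   every fifth family at \code{c(0.75, 0.25, 0, 0)}.
#' @param offtargets data.frame \code{guide_family, target_family, s,
#'   fraction}: planted cross-family off-targets (at most one row per target
#'   family). Default plants 1-, 2- and 3-mismatch off-targets between six
#'   family pairs.
#' @param R_raw Requested per-family log2 fitness contributions; default
#'   spans strong costs for proliferation families, mild for differentiation,
#'   a small benefit for the pseudo family. See
#'   \code{\link{simulate_competition}} for how these are centered.
#' @param penalties Mismatch penalty vector (default
#'   \code{\link{default_penalties}}).
#' @param depth,days,replicates,t_ref Competition sequencing depth, sampled
#'   days, replicate count and readout day.
#' @param trnaseq_days,trnaseq_depth,trnaseq_replicates,trnaseq_families
#'   tRNA-seq time course settings; \code{trnaseq_families} indexes which
#'   families get a treated population (default the first 4).
#' @param edit_rate,edit_max,edit_lag Editing kinetics: saturating rise rate
#'   (per day), plateau edited fraction, and the delay (days) before
#'   selection starts eroding the edited subpopulation.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline expression.
#' @param treatments Arrest treatment labels (untreated, quiescence,
#'   senescence).
#' @param responder_prob Optional variants x treatments matrix of responder
#'   probabilities; built from \code{arrest_required} when NULL.
#' @param arrest_required Family indices whose loss blocks arrest entry
#'   (their variants respond like untreated cells); default the last 4
#'   differentiation families.
#' @param base_responder Baseline responder probabilities per treatment.
#' @param events_per_variant,arrest_replicates,bin_fraction,arrest_depth
#'   Flow/sort settings.
#' @param mcherry_lo_meanlog,mcherry_hi_meanlog,mcherry_sdlog,fsc_meanlog,fsc_sdlog
#'   Log-normal reporter and forward-scatter parameters.
#' @return Validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed,
                       n_families = 20L,
                       members_per_family = 4L,
                       body_length = 72L,
                       flank = 10L,
                       class_labels = NULL,
                       own_spectrum = NULL,
                       offtargets = NULL,
                       R_raw = NULL,
                       penalties = default_penalties(),
                       depth = 1e6,
                       days = c(0, 3, 7, 10, 14),
                       replicates = 2L,
                       t_ref = 7,
                       trnaseq_days = c(0, 4, 8, 12),
                       trnaseq_depth = 1e6,
                       trnaseq_replicates = 2L,
                       trnaseq_families = NULL,
                       edit_rate = 0.4,
                       edit_max = 0.85,
                       edit_lag = 4,
                       baseline_meanlog = log(200),
                       baseline_sdlog = 0.7,
                       treatments = c("U", "Q", "S"),
                       responder_prob = NULL,
                       arrest_required = NULL,
                       base_responder = c(U = 0.05, Q = 0.7, S = 0.85),
                       events_per_variant = 400L,
                       arrest_replicates = 3L,
                       bin_fraction = 0.05,
                       arrest_depth = 1e5,
                       mcherry_lo_meanlog = log(300),
                       mcherry_hi_meanlog = log(3000),
                       mcherry_sdlog = 0.4,
                       fsc_meanlog = log(100),
                       fsc_sdlog = 0.2) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  n <- as.integer(n_families)
  m <- rep_len(as.integer(members_per_family), n)
  if (any(m < 1L)) stop("each family needs at least one member")
  if (is.null(class_labels)) {
    class_labels <- if (n >= 3L) {
      c(rep("proliferation", max(1L, round(n * 9 / 20))),
        rep("differentiation", n - max(1L, round(n * 9 / 20)) - 1L),
        "pseudo")
    } else rep("proliferation", n)
  }
  class_labels <- rep_len(class_labels, n)
  if (!all(class_labels %in% c("proliferation", "differentiation", "other", "pseudo"))) {
    stop("invalid class label(s)")
  }
  fam_ids <- sprintf("Fam%02d", seq_len(n))
  if (is.null(own_spectrum)) {
    own_spectrum <- lapply(seq_len(n), function(i) {
      if (i %% 5L == 0L && m[i] %% 4L == 0L) c(0.75, 0.25, 0, 0) else c(1, 0, 0, 0)
    })
  }
  own_spectrum <- rep_len(own_spectrum, n)
  for (i in seq_len(n)) .levels_from_fractions(own_spectrum[[i]], m[i])  # feasibility
  if (is.null(offtargets)) {
    cand <- data.frame(
      guide_family = c(1L, 4L, 7L, 10L, 13L, 16L),
      target_family = c(2L, 5L, 8L, 11L, 14L, 17L),
      s = c(1L, 1L, 1L, 2L, 2L, 3L),
      fraction = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
    )
    offtargets <- cand[cand$guide_family <= n & cand$target_family <= n, , drop = FALSE]
  }
  if (nrow(offtargets)) {
    if (anyDuplicated(offtargets$target_family)) {
      stop("at most one planted off-target per target family")
    }
    if (any(offtargets$s < 1L | offtargets$s > 3L)) stop("off-target s must be 1-3")
    if (any(offtargets$fraction <= 0 | offtargets$fraction > 1)) {
      stop("off-target fractions must be in (0, 1]")
    }
    for (i in seq_len(nrow(offtargets))) {
      k <- offtargets$fraction[i] * m[offtargets$target_family[i]]
      if (abs(k - round(k)) > 1e-8) {
        stop("off-target fraction ", offtargets$fraction[i],
             " not expressible with ", m[offtargets$target_family[i]], " members")
      }
    }
  }
  if (is.null(R_raw)) {
    R_raw <- numeric(n)
    R_raw[class_labels == "proliferation"] <-
      seq(-6, -2, length.out = sum(class_labels == "proliferation"))
    R_raw[class_labels == "differentiation"] <-
      seq(-2.5, -0.25, length.out = max(1L, sum(class_labels == "differentiation")))[
        seq_len(sum(class_labels == "differentiation"))]
    R_raw[class_labels == "other"] <- -0.5
    R_raw[class_labels == "pseudo"] <- 0.5
  }
  R_raw <- stats::setNames(rep_len(R_raw, n), fam_ids)
  if (is.null(arrest_required)) {
    diffs <- which(class_labels == "differentiation")
    arrest_required <- utils::tail(diffs, 4L)
  }
  stopifnot(length(penalties) == 4L, all(penalties >= 0), all(penalties <= 1),
            edit_rate > 0, edit_max > 0, edit_max <= 1,
            bin_fraction > 0, bin_fraction < 0.5,
            all(base_responder >= 0), all(base_responder <= 1),
            t_ref %in% days)
  cfg <- list(seed = as.integer(seed), n_families = n, members_per_family = m,
              body_length = as.integer(body_length), flank = as.integer(flank),
              family_ids = fam_ids, class_labels = class_labels,
              own_spectrum = own_spectrum, offtargets = offtargets,
              R_raw = R_raw, penalties = penalties,
              depth = depth, days = days, replicates = as.integer(replicates),
              t_ref = t_ref,
              trnaseq_days = trnaseq_days, trnaseq_depth = trnaseq_depth,
              trnaseq_replicates = as.integer(trnaseq_replicates),
              trnaseq_families = trnaseq_families %||% seq_len(min(4L, n)),
              edit_rate = edit_rate, edit_max = edit_max, edit_lag = edit_lag,
              baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
              treatments = treatments, responder_prob = responder_prob,
              arrest_required = arrest_required,
              base_responder = base_responder,
              events_per_variant = as.integer(events_per_variant),
              arrest_replicates = as.integer(arrest_replicates),
              bin_fraction = bin_fraction, arrest_depth = arrest_depth,
              mcherry_lo_meanlog = mcherry_lo_meanlog,
              mcherry_hi_meanlog = mcherry_hi_meanlog,
              mcherry_sdlog = mcherry_sdlog,
              fsc_meanlog = fsc_meanlog, fsc_sdlog = fsc_sdlog)
  class(cfg) <- "sim_config"
  cfg
}

# integer per-member mismatch levels realizing a fraction vector;
# NA marks untargeted members (the <= 1 remainder)
.levels_from_fractions <- function(f, m) {
  if (length(f) != 4L || any(f < 0) || sum(f) > 1 + 1e-8) {
    stop("own-guide spectrum must be 4 fractions with sum <= 1")
  }
  counts <- f * m
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("fractions ", paste(f, collapse = "/"),
         " not expressible with ", m, " members")
  }
  counts <- as.integer(round(counts))
  c(rep(0:3, counts), rep(NA_integer_, m - sum(counts)))
}

.BASES <- c("A", "C", "G", "T")
.SUB <- c(A = "C", C = "G", G = "T", T = "A")
# substitution positions inside the protospacer: PAM-distal (5') side, so the
# planted mismatch count, not PAM loss, drives the spectrum
.MM_POS <- c(2L, 5L, 8L)

#' Simulate a family/guide set with a planted mismatch structure
#'
#' Generates random tRNA-like genes in which each family's guide protospacer
#' (followed by an NGG PAM) is planted with a deterministic number of
#' substitutions per member, realizing the configured own-guide spectrum
#' exactly; cross-family off-targets are planted the same way at a second
#' locus. Measured targeting profiles therefore match the generating spectrum
#' exactly, and the generating reduction matrix is returned as ground truth.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{genes}, \code{families}, \code{guides} (named lists),
#'   and \code{truth} with the generating reduction matrix \code{M}, the
#'   planted per-gene mismatch levels (genes x guides, NA = untargeted) and
#'   the spectra.
#' @export
simulate_family_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.subseed(config$seed, 1L))
  n <- config$n_families
  flank <- config$flank
  body <- config$body_length
  slot1 <- 20L   # body-local start of the own protospacer (PAM at [40, 43))
  slot2 <- 44L   # body-local start of planted cross off-targets
  stopifnot(body >= slot2 + 23L)

  spacers <- vapply(seq_len(n), function(i) {
    paste(sample(.BASES, 20L, replace = TRUE), collapse = "")
  }, character(1))
  guide_ids <- paste0("sg", config$family_ids)

  plant <- function(chars, body_start, spacer, s) {
    pos <- flank + body_start + seq_len(20L)
    sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
    if (s > 0L) {
      for (p in .MM_POS[seq_len(s)]) sp[p] <- .SUB[[sp[p]]]
    }
    chars[pos] <- sp
    chars[flank + body_start + 21L] <- sample(.BASES, 1L)
    chars[flank + body_start + 22L] <- "G"
    chars[flank + body_start + 23L] <- "G"
    chars
  }

  genes <- list()
  gene_ids_by_fam <- vector("list", n)
  levels_own <- vector("list", n)
  for (i in seq_len(n)) {
    m <- config$members_per_family[i]
    lv <- .levels_from_fractions(config$own_spectrum[[i]], m)
    levels_own[[i]] <- lv
    ids <- sprintf("%s-%d", config$family_ids[i], seq_len(m))
    gene_ids_by_fam[[i]] <- ids
    for (k in seq_len(m)) {
      chars <- sample(.BASES, 2L * flank + body, replace = TRUE)
      if (!is.na(lv[k])) chars <- plant(chars, slot1, spacers[i], lv[k])
      g <- trna_gene(ids[k], config$family_ids[i],
                     paste(chars, collapse = ""),
                     trna_score = if (config$class_labels[i] == "pseudo") 30 else 70,
                     class_label = config$class_labels[i], flank = flank,
                     elements = list(a_box = c(8L, 19L), b_box = c(52L, 62L),
                                     anticodon = c(30L, 37L)))
      genes[[ids[k]]] <- g
    }
  }

  # planted per-gene mismatch levels to every guide (NA = untargeted)
  all_ids <- names(genes)
  gene_levels <- matrix(NA_integer_, nrow = length(all_ids), ncol = n,
                        dimnames = list(all_ids, guide_ids))
  for (i in seq_len(n)) {
    gene_levels[gene_ids_by_fam[[i]], i] <- levels_own[[i]]
  }

  ot <- config$offtargets
  if (nrow(ot)) {
    for (r in seq_len(nrow(ot))) {
      gi <- ot$guide_family[r]; ti <- ot$target_family[r]
      k <- as.integer(round(ot$fraction[r] * config$members_per_family[ti]))
      ids <- gene_ids_by_fam[[ti]][seq_len(k)]
      for (id in ids) {
        chars <- strsplit(genes[[id]]$sequence, "", fixed = TRUE)[[1]]
        chars <- plant(chars, slot2, spacers[gi], ot$s[r])
        genes[[id]]$sequence <- paste(chars, collapse = "")
        gene_levels[id, gi] <- ot$s[r]
      }
    }
  }

  families <- families_from_genes(genes)
  guides <- lapply(seq_len(n), function(i) {
    guide_rna(guide_ids[i], spacers[i], config$family_ids[i])
  })
  names(guides) <- guide_ids

  # generating reduction matrix from the planted spectra
  M <- matrix(0, n, n, dimnames = list(config$family_ids, guide_ids))
  p <- as.numeric(config$penalties)
  for (i in seq_len(n)) {
    M[i, i] <- sum(p * config$own_spectrum[[i]])
  }
  if (nrow(ot)) {
    for (r in seq_len(nrow(ot))) {
      M[ot$target_family[r], ot$guide_family[r]] <- p[ot$s[r] + 1L] * ot$fraction[r]
    }
  }
  list(genes = genes, families = families, guides = guides,
       truth = list(M = structure(M, class = c("reduction_matrix", "matrix", "array")),
                    gene_levels = gene_levels,
                    own_spectrum = config$own_spectrum,
                    offtargets = ot))
}

#' Simulate a pooled competition with additive ON/OFF fitness costs
#'
#' Each guide-carrying variant grows exponentially with a log2 rate set by
#' the additive model: the day-\code{t_ref} log2 frequency change of variant
#' \eqn{j} equals \eqn{\sum_i coeff_{ij} R_i}. Because frequencies in a
#' closed competition sum to 1, fitness is identified only up to the
#' population-mean growth; the requested \code{R_raw} is therefore centered
#' onto the compositional manifold (a common shift of the observed vector)
#' and the centered vector \code{R_true} is reported as ground truth, making
#' exact recovery well-posed. Sequencing draws multinomial counts at the
#' configured depth; \code{depth = Inf} emits noise-free expected counts.
#'
#' @param config A \code{\link{sim_config}}.
#' @param M Reduction matrix (families x guides), e.g. the generating matrix
#'   from \code{\link{simulate_family_set}}.
#' @param R_raw Requested per-family fitness contributions (default from the
#'   config).
#' @return List: \code{counts} (guides x samples), \code{samples} metadata,
#'   and \code{truth} with \code{R_true}, \code{R_raw}, \code{expected_O},
#'   \code{M}, \code{rates} (log2/day) and \code{expected_freqs}.
#' @export
simulate_competition <- function(config, M, R_raw = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.subseed(config$seed, 2L))
  M <- unclass(M)
  R_raw <- R_raw %||% config$R_raw
  stopifnot(ncol(M) == length(R_raw))
  A <- t(M)                                   # guide-major equations
  f0 <- rep(1 / ncol(M), ncol(M))
  O_raw <- as.numeric(A %*% R_raw)
  shift <- log2(sum(f0 * 2^O_raw))            # compositional centering
  O_true <- O_raw - shift
  R_true <- solve(A, O_true)
  names(R_true) <- rownames(M)
  rates <- O_true / config$t_ref

  guide_ids <- colnames(M)
  samples <- expand.grid(day = config$days, replicate = seq_len(config$replicates),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("d%g_r%d", samples$day, samples$replicate)
  samples$cell_line <- "sim"
  samples <- samples[, c("sample_id", "cell_line", "day", "replicate")]

  expected_freqs <- vapply(config$days, function(t) {
    w <- f0 * 2^(rates * t)
    w / sum(w)
  }, numeric(length(f0)))
  dimnames(expected_freqs) <- list(guide_ids, as.character(config$days))

  counts <- vapply(seq_len(nrow(samples)), function(i) {
    p <- expected_freqs[, as.character(samples$day[i])]
    if (is.finite(config$depth)) {
      as.numeric(stats::rmultinom(1, size = config$depth, prob = p))
    } else {
      p * 1e9
    }
  }, numeric(length(guide_ids)))
  dimnames(counts) <- list(guide_ids, samples$sample_id)

  list(counts = counts, samples = samples,
       truth = list(R_true = R_true, R_raw = R_raw, expected_O = stats::setNames(O_true, guide_ids),
                    M = M, rates = stats::setNames(rates, guide_ids), shift = shift,
                    expected_freqs = expected_freqs))
}

# edited fraction: saturating rise, then selection against edited cells at
# the family's per-day fitness rate; selection only acts once editing has
# had time to accumulate (lag), matching the observed early-editing window
.edited_fraction <- function(t, edit_max, edit_rate, rate_per_day, lag = 4) {
  e0 <- edit_max * (1 - exp(-edit_rate * t))
  w <- e0 * 2^(rate_per_day * pmax(0, t - lag))
  w / (w + (1 - e0))
}

#' Simulate family-targeted tRNA-seq time courses
#'
#' For each treated population (one per configured family), the edited
#' fraction rises with saturating kinetics and then recedes under selection
#' proportional to the family's fitness cost; each gene's expression scales
#' as baseline x (1 - penalty(s) x edited fraction), where s is the gene's
#' planted mismatch level to the population's guide. Wild-type samples carry
#' baseline expression. Counts are multinomial over genes at the configured
#' depth (\code{Inf} = noise-free).
#'
#' @param config A \code{\link{sim_config}}.
#' @param family_set Output of \code{\link{simulate_family_set}}.
#' @return List: \code{counts} (genes x samples), \code{samples} metadata
#'   (\code{sample_id, condition, day, replicate}; wild-type condition "WT"),
#'   and \code{truth} with per-population edited fractions and the analytic
#'   family log2 fold-change trajectories (computed compositionally, i.e.
#'   on within-sample shares, as the expression pipeline measures them).
#' @export
simulate_trnaseq <- function(config, family_set) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.subseed(config$seed, 3L))
  genes <- family_set$genes
  gene_ids <- names(genes)
  fam_of <- vapply(genes, `[[`, character(1), "family_id")
  base <- stats::rlnorm(length(genes), config$baseline_meanlog, config$baseline_sdlog)
  names(base) <- gene_ids
  p <- as.numeric(config$penalties)
  lv <- family_set$truth$gene_levels
  fams <- config$family_ids[config$trnaseq_families]
  guide_ids <- colnames(lv)[config$trnaseq_families]

  days <- config$trnaseq_days
  reps <- seq_len(config$trnaseq_replicates)
  conds <- c("WT", fams)
  samples <- expand.grid(condition = conds, day = days, replicate = reps,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_d%g_r%d", samples$condition, samples$day, samples$replicate)
  samples <- samples[, c("sample_id", "condition", "day", "replicate")]

  rate_per_day <- config$R_raw / config$t_ref
  expr_of <- function(cond, day) {
    if (cond == "WT") return(base)
    gid <- guide_ids[match(cond, fams)]
    e <- .edited_fraction(day, config$edit_max, config$edit_rate,
                          rate_per_day[[cond]], config$edit_lag)
    pen <- ifelse(is.na(lv[, gid]), 0, p[lv[, gid] + 1L])
    base * (1 - pen * e)
  }

  counts <- vapply(seq_len(nrow(samples)), function(i) {
    ex <- expr_of(samples$condition[i], samples$day[i])
    if (is.finite(config$trnaseq_depth)) {
      as.numeric(stats::rmultinom(1, size = config$trnaseq_depth, prob = ex / sum(ex)))
    } else {
      ex / sum(ex) * 1e6
    }
  }, numeric(length(gene_ids)))
  dimnames(counts) <- list(gene_ids, samples$sample_id)

  all_fams <- sort(unique(fam_of))
  edited <- sapply(fams, function(f) {
    vapply(days, .edited_fraction, numeric(1),
           edit_max = config$edit_max, edit_rate = config$edit_rate,
           rate_per_day = rate_per_day[[f]], lag = config$edit_lag)
  })
  expected_fc <- lapply(stats::setNames(fams, fams), function(f) {
    out <- vapply(days, function(d) {
      ex <- expr_of(f, d)
      share_t <- tapply(ex / sum(ex), fam_of, sum)
      share_w <- tapply(base / sum(base), fam_of, sum)
      log2(share_t / share_w)[all_fams]
    }, numeric(length(all_fams)))
    dimnames(out) <- list(all_fams, as.character(days))
    out
  })
  list(counts = counts, samples = samples,
       truth = list(baseline = base,
                    edited_fraction = matrix(edited, nrow = length(days),
                                             dimnames = list(as.character(days), fams)),
                    expected_fc = expected_fc))
}

#' Simulate flow events and FACS-sorted sgRNA bins under arrest treatments
#'
#' Per variant and treatment, cells respond (activate the arrest reporter)
#' with a configured probability; responders draw the reporter intensity from
#' a high-location log-normal, non-responders from a low one, with a shared
#' log-normal forward scatter. Each treatment population is gated into
#' top/bottom reporter bins and bin compositions are sequenced multinomially
#' against an equal-composition ancestor.
#'
#' @param config A \code{\link{sim_config}}.
#' @param family_set Output of \code{\link{simulate_family_set}} (for guide
#'   ids); a non-targeting "control" variant is added.
#' @return List: \code{events} (variant, treatment, replicate, mCherry, FSC),
#'   \code{counts} (variants x sorted+ancestor samples), \code{samples}
#'   metadata (\code{sample_id, treatment, bin, replicate, is_ancestor}),
#'   and \code{truth} with the responder-probability matrix and per-event
#'   responder flags.
#' @export
simulate_arrest <- function(config, family_set) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.subseed(config$seed, 4L))
  variants <- c(names(family_set$guides), "control")
  nv <- length(variants)
  pr <- config$responder_prob
  if (is.null(pr)) {
    pr <- matrix(rep(config$base_responder[config$treatments], each = nv),
                 nrow = nv, dimnames = list(variants, config$treatments))
    blocked <- names(family_set$guides)[config$arrest_required]
    pr[blocked, setdiff(config$treatments, "U")] <- 0.05
  }
  stopifnot(identical(rownames(pr), variants), all(pr >= 0), all(pr <= 1))

  ev_list <- list()
  count_cols <- list()
  samp_rows <- list()
  for (rp in seq_len(config$arrest_replicates)) {
    for (tr in config$treatments) {
      n_ev <- config$events_per_variant
      resp <- unlist(lapply(variants, function(v) stats::rbinom(n_ev, 1L, pr[v, tr])))
      mul <- ifelse(resp == 1L, config$mcherry_hi_meanlog, config$mcherry_lo_meanlog)
      ev <- data.frame(
        variant = rep(variants, each = n_ev),
        treatment = tr, replicate = rp,
        mCherry = stats::rlnorm(nv * n_ev, mul, config$mcherry_sdlog),
        FSC = stats::rlnorm(nv * n_ev, config$fsc_meanlog, config$fsc_sdlog),
        responder = resp == 1L,
        stringsAsFactors = FALSE)
      ev_list[[paste(tr, rp)]] <- ev
      bins <- gate_top_bottom(ev, fraction = config$bin_fraction)
      for (b in c("H", "L")) {
        tab <- table(factor(ev$variant[bins == b], levels = variants))
        cnt <- as.numeric(stats::rmultinom(1, size = config$arrest_depth,
                                           prob = as.numeric(tab) / sum(tab)))
        sid <- sprintf("%s_%s_r%d", tr, b, rp)
        count_cols[[sid]] <- cnt
        samp_rows[[sid]] <- data.frame(sample_id = sid, treatment = tr, bin = b,
                                       replicate = rp, is_ancestor = FALSE,
                                       stringsAsFactors = FALSE)
      }
    }
    sid <- sprintf("ancestor_r%d", rp)
    cnt <- as.numeric(stats::rmultinom(1, size = config$arrest_depth,
                                       prob = rep(1 / nv, nv)))
    count_cols[[sid]] <- cnt
    samp_rows[[sid]] <- data.frame(sample_id = sid, treatment = "ancestor",
                                   bin = "none", replicate = rp,
                                   is_ancestor = TRUE, stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, count_cols)
  dimnames(counts) <- list(variants, names(count_cols))
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL
  list(events = events[, c("variant", "treatment", "replicate", "mCherry", "FSC")],
       counts = counts,
       samples = do.call(rbind, c(samp_rows, list(make.row.names = FALSE))),
       truth = list(responder_prob = pr, responder = events$responder))
}
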