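test_that("the limit of blank follows the interpolated 95th percentile", {
  e <- matrix(1:20, 20, 1, dimnames = list(paste0("CM", 1:20), "s1"))
  expect_equal(unname(estimate_lob(e, rownames(e))), 19.05)

  ec <- matrix(7, 15, 2, dimnames = list(paste0("CM", 1:15), c("a", "b")))
  expect_equal(unname(estimate_lob(ec, rownames(ec))), c(7, 7))

  ## Gaussian blanks: LOB ~ mu + 1.645 sigma
  set.seed(10)
  g <- matrix(rnorm(10000, 4, 0.8), 10000, 1,
              dimnames = list(paste0("CM", 1:10000), "s1"))
  expect_equal(unname(estimate_lob(g, rownames(g))),
               4 + qnorm(0.95) * 0.8, tolerance = 0.05 * 0.8 / (4 + 1.316))

  expect_error(estimate_lob(e, character(0)), "undefined")
  expect_error(estimate_lob(e, c("CM1", "nope")), "absent")
})

test_that("95% of blank values lie at or below the LOB in every sample", {
  fx <- cached_study()
  blanks <- fx$revised$complete_mismatch_set_ids
  lob <- estimate_lob(fx$expr_ff, blanks)
  bl <- fx$expr_ff[blanks, , drop = FALSE]
  frac <- colMeans(sweep(bl, 2, lob, `<=`))
  expect_true(all(abs(frac - 0.95) <= 1 / length(blanks) + 1e-9))
})

test_that("present calls count probe sets above the LOB, excluding blanks", {
  e <- matrix(c(1, 2, 3, 10), 4, 1,
              dimnames = list(c("A", "B", "C", "CM1"), "s1"))
  pc <- present_calls(e, lob = 100, blank_set_ids = "CM1")
  expect_equal(unname(pc$percent_present), 0)
  pc2 <- present_calls(e, lob = 1.5, blank_set_ids = "CM1")
  expect_equal(unname(pc2$percent_present), 100 * 2 / 3)

  ## invariant under a joint monotone affine rescale
  fx <- cached_study()
  blanks <- fx$revised$complete_mismatch_set_ids
  lob <- estimate_lob(fx$expr_ff, blanks)
  p1 <- present_calls(fx$expr_ff, lob, blanks)
  sc <- fx$expr_ff * 3 + 2
  p2 <- present_calls(sc, estimate_lob(sc, blanks), blanks)
  expect_equal(p1$percent_present, p2$percent_present)
  expect_equal(p1$percent_above_lob, p2$percent_above_lob)
})

test_that("silencing half the genes halves the present calls", {
  cfg <- small_config(seed = 61, n_genes = 60, frac_de_genes = 0,
                      frac_silent_genes = 0.5, frac_nonmatching_probes = 0,
                      frac_crosshyb_probes = 0, n_complete_mismatch_sets = 25,
                      kit_profiles = list(k = degradation_profile("k")))
  st <- simulate_study(cfg)
  rd <- revise_design(st$design, st$reference)
  rd <- with_complete_mismatch_sets(rd, st$design, st$reference)
  ei <- expression_index(st$cohort$ff, rd)
  lob <- estimate_lob(ei$expression, rd$complete_mismatch_set_ids)
  pc <- present_calls(ei$expression, lob, rd$complete_mismatch_set_ids)
  ## expressed baselines sit well above background, so percent present
  ## tracks the non-silent fraction (QC control sets are always expressed)
  expect_true(all(abs(pc$percent_present - 50) < 12))
})

test_that("zero degradation leaves per-sample present calls identical to FF", {
  cfg <- small_config(seed = 62, n_complete_mismatch_sets = 20,
                      kit_profiles = list(perfect = degradation_profile("perfect")))
  st <- simulate_study(cfg)
  rd <- revise_design(st$design, st$reference)
  rd <- with_complete_mismatch_sets(rd, st$design, st$reference)
  e_ff <- expression_index(st$cohort$ff, rd)$expression
  e_fp <- expression_index(st$cohort$ffpet$perfect, rd)$expression
  blanks <- rd$complete_mismatch_set_ids
  p_ff <- present_calls(e_ff, estimate_lob(e_ff, blanks), blanks)
  p_fp <- present_calls(e_fp, estimate_lob(e_fp, blanks), blanks)
  expect_identical(unname(p_ff$percent_present), unname(p_fp$percent_present))
  expect_identical(p_ff$percent_above_lob, p_fp$percent_above_lob)
})

test_that("probe-set consistency separates coherent from incoherent genes", {
  set.seed(11)
  base <- rnorm(16, 8, 1)
  e <- rbind(g1a = base, g1b = base + 0.2,
             g2a = rnorm(16), g2b = rnorm(16),
             g3a = rnorm(16))
  map <- data.frame(probe_set_id = rownames(e),
                    gene_id = c("g1", "g1", "g2", "g2", "g3"))
  cons <- probe_set_consistency(e, map)
  ## the single-set gene g3 is excluded from the denominator
  expect_identical(cons$n_genes, 2L)
  d <- cons$detail
  expect_false(d$inconsistent[d$gene_id == "g1"])
  expect_equal(d$median_r[d$gene_id == "g1"], 1, tolerance = 1e-12)

  ## Pearson location invariance: shifting each probe-set vector by a
  ## constant leaves every pairwise correlation unchanged
  shifted <- e + rnorm(nrow(e), 0, 3)
  expect_equal(probe_set_consistency(shifted, map)$detail$median_r,
               cons$detail$median_r, tolerance = 1e-10)

  ## null genes (independent second probe set) are flagged at the expected
  ## rate: under independence P(r <= 0.5) at n = 16 is ~0.97
  set.seed(12)
  en <- do.call(rbind, lapply(1:200, function(i) {
    rbind(rnorm(16), rnorm(16))
  }))
  rownames(en) <- paste0("s", seq_len(400))
  mapn <- data.frame(probe_set_id = rownames(en),
                     gene_id = rep(paste0("g", 1:200), each = 2))
  consn <- probe_set_consistency(en, mapn)
  expect_gt(consn$percent_inconsistent, 90)

  ## zero-variance vector -> pair dropped with a warning
  ez <- rbind(a1 = rep(5, 16), a2 = rnorm(16))
  mapz <- data.frame(probe_set_id = c("a1", "a2"), gene_id = "a")
  expect_warning(cz <- probe_set_consistency(ez, mapz), "undefined")
  expect_identical(cz$n_genes, 0L)
})

test_that("matched-pair correlation is 1 for identical cohorts and decays with noise", {
  fx <- cached_study()
  sheet <- fx$study$cohort$sheet
  e_ff <- fx$expr_ff
  ## FFPET identical to FF: rename columns to the nugen samples
  e_fp <- e_ff
  colnames(e_fp) <- sub("_FF$", "_nugen", colnames(e_fp))
  pc <- pair_correlation(e_ff, e_fp, sheet)
  expect_equal(pc$pairs$r, rep(1, nrow(pc$pairs)), tolerance = 1e-12)
  expect_equal(pc$median_r, 1, tolerance = 1e-12)

  ## increasing noise monotonically lowers the median pair correlation
  set.seed(13)
  meds <- vapply(c(0.3, 1, 3), function(s) {
    noisy <- e_fp + matrix(rnorm(length(e_fp), 0, s), nrow(e_fp))
    pair_correlation(e_ff, noisy, sheet)$median_r
  }, numeric(1))
  expect_true(all(diff(meds) < 0))

  ## unpaired samples are excluded with a warning
  expect_warning(pair_correlation(e_ff[, -1], e_fp, sheet), "unpaired")
  ## constant column errors
  e_bad <- e_fp
  e_bad[, 1] <- 0
  expect_error(pair_correlation(e_ff, e_bad, sheet), "constant")
})

test_that("the in-silico 3'/5' ratio matches the degradation closed form", {
  ## decay grid within the unsaturated regime (the 5' signal stays above
  ## the optical background floor)
  lambdas <- c(0, 5e-4, 1e-3, 2e-3, 4e-3)
  profiles <- lapply(lambdas, function(l) {
    degradation_profile(paste0("k", l * 10000), three_prime_decay = l)
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "kit_label")
  cfg <- small_config(seed = 71, n_genes = 30, n_complete_mismatch_sets = 5,
                      kit_profiles = profiles)
  st <- simulate_study(cfg)
  ctrl <- st$truth$control

  ratios <- vapply(names(profiles), function(k) {
    mean(three_prime_ratio(st$cohort$ffpet[[k]], st$design,
                           ctrl$transcript_id, ctrl$length))
  }, numeric(1))

  ## intact RNA: ratio ~ 1
  expect_lt(abs(ratios[["k0"]] - 1), 0.1)

  ## closed form of the degradation model: each tercile's mean linear
  ## signal decays probe-wise by 2^(-lambda * d) over a constant background
  probes <- st$design[!is.na(st$design$target_transcript) &
                        st$design$target_transcript == ctrl$transcript_id, ]
  p3 <- probes$probe_id[probes$d3prime < ctrl$length / 3]
  p5 <- probes$probe_id[probes$d3prime >= 2 * ctrl$length / 3]
  d3 <- probes$d3prime[match(p3, probes$probe_id)]
  d5 <- probes$d3prime[match(p5, probes$probe_id)]
  v0 <- st$cohort$ffpet$k0$values
  w3 <- rowMeans(v0[p3, ]) - cfg$background_mean
  w5 <- rowMeans(v0[p5, ]) - cfg$background_mean
  for (k in names(profiles)[-1]) {
    lam <- profiles[[k]]$three_prime_decay
    pred <- (mean(w3 * 2^(-lam * d3)) + cfg$background_mean) /
      (mean(w5 * 2^(-lam * d5)) + cfg$background_mean)
    expect_lt(abs(ratios[[k]] - pred) / pred, 0.05)
  }
  ## strictly increasing in the decay rate over this grid
  expect_true(all(diff(ratios) > 0))
})

test_that("three_prime_ratio validates its inputs", {
  fx <- cached_study()
  st <- fx$study
  ctrl <- st$truth$control
  r <- three_prime_ratio(st$cohort$ff, st$design, ctrl$transcript_id,
                         ctrl$length)
  expect_length(r, ncol(st$cohort$ff$values))
  expect_true(all(r > 0))
  ## too few probes in a terminal third
  expect_error(
    three_prime_ratio(st$cohort$ff, st$design[1:22, ], ctrl$transcript_id,
                      ctrl$length),
    ">= 2 probes")
})

test_that("qc_report bundles the cohort metrics", {
  fx <- cached_study()
  st <- fx$study
  ctrl <- st$truth$control
  rep <- qc_report(fx$expr_ff, fx$revised, intensities = st$cohort$ff,
                   raw_design = st$design,
                   control_transcript = ctrl$transcript_id,
                   transcript_length = ctrl$length)
  expect_true(all(c("lob", "percent_present", "percent_above_lob",
                    "percent_inconsistent_genes", "three_prime_ratio")
                  %in% names(rep)))
  expect_true(all(rep$percent_present >= 0 & rep$percent_present <= 100))
  expect_true(rep$percent_above_lob >= 0 && rep$percent_above_lob <= 100)
})
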