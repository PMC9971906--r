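test_that("bootstrap SD of a proportion behaves like the binomial SE", {
  # all-ones: zero spread
  expect_equal(bootstrap_fraction(rep(1, 30), seed = 1)$sd, 0)
  # p = 0.5, n = 100: SD ~ sqrt(p(1-p)/n) = 0.050 within 15%
  flags <- rep(c(0, 1), 50)
  bs <- bootstrap_fraction(flags, n_boot = 1000, seed = 2)
  expect_equal(bs$fraction, 0.5)
  expect_lt(abs(bs$sd - 0.05) / 0.05, 0.15)
  # convergence to the binomial SE at large n_boot (within 5%)
  bs2 <- bootstrap_fraction(flags, n_boot = 10000, seed = 3)
  expect_lt(abs(bs2$sd - 0.05) / 0.05, 0.05)
  # determinism under a fixed seed
  expect_identical(bootstrap_fraction(flags, seed = 7)$sd,
                   bootstrap_fraction(flags, seed = 7)$sd)
  expect_error(bootstrap_fraction(numeric(0)), "empty")
  expect_error(bootstrap_fraction(c(0, 2)), "indicators")
})

test_that("initiation fraction reproduces printed cohort counts", {
  all_go <- initiation_fraction(n_translocating = 20, n_total = 20)
  expect_equal(all_go$fraction, 1)
  expect_equal(all_go$sd, 0)
  expect_equal(round(100 * initiation_fraction(
    n_translocating = 86, n_total = 111)$fraction), 77)
  expect_equal(round(100 * initiation_fraction(
    n_translocating = 34, n_total = 182)$fraction), 19)
  expect_error(initiation_fraction(n_translocating = 5, n_total = 0),
               "denominator")
  # from a movement_filter partition
  part <- list(translocating = 1:3, static = 4)
  expect_equal(initiation_fraction(part)$fraction, 0.75)
})

test_that("all printed count percentages reproduce exactly", {
  counts <- list(c(97, 112, 87), c(22, 34, 65), c(86, 111, 77),
                 c(83, 133, 62), c(34, 182, 19), c(67, 81, 83),
                 c(131, 145, 90), c(42, 94, 45), c(5, 42, 12),
                 c(68, 82, 83))
  for (x in counts) {
    got <- fraction_from_counts(x[1], x[2], percent = TRUE)
    expect_equal(round(got$fraction), x[3])
  }
})

test_that("colocalization scores proximity dwell and is directional", {
  fr <- 0:49
  mk <- function(id, pos) data.frame(molecule_id = id, frame = fr,
                                     position_bp = pos)
  # identical positions: fraction 1
  a <- mk("a1", 20000); b <- mk("b1", 20000)
  r <- colocalize(a, b, seed = 1)
  expect_equal(r$fraction, 1)
  expect_equal(r$n_colocalized, 1)
  # far apart: 0
  expect_equal(colocalize(mk("a1", 5000), mk("b1", 40000),
                          seed = 1)$fraction, 0)
  # brief crossing below the dwell requirement does not count
  cross <- mk("b2", c(rep(40000, 47), rep(20500, 3)))
  expect_equal(colocalize(a, cross, min_overlap_frames = 5,
                          seed = 1)$fraction, 0)
  # asymmetry: two A molecules near one B vs the reverse
  a2 <- rbind(mk("a1", 20000), mk("a2", 20600))
  b2 <- mk("b1", 20300)
  fwd <- colocalize(a2, b2, seed = 1)
  rev <- colocalize(b2, a2, seed = 1)
  expect_equal(fwd$fraction, 1)         # both A near the single B
  expect_equal(rev$fraction, 1)         # the B is near an A
  a3 <- rbind(mk("a1", 20000), mk("a2", 45000))
  fwd3 <- colocalize(a3, b2, seed = 1)
  expect_equal(fwd3$fraction, 0.5)      # only one A near B
  expect_equal(colocalize(b2, a3, seed = 1)$fraction, 1)
})

test_that("chance colocalization matches the geometric overlap probability", {
  L <- 48502; d <- 1000
  p_analytic <- (2 * d * L - d^2) / L^2
  set.seed(31)
  n <- 1000
  hit <- logical(n)
  for (i in seq_len(n)) {
    pa <- runif(1, 0, L); pb <- runif(1, 0, L)
    a <- data.frame(molecule_id = "a", frame = 0:9, position_bp = pa)
    b <- data.frame(molecule_id = "b", frame = 0:9, position_bp = pb)
    hit[i] <- colocalize(a, b, threshold_bp = d, n_boot = 1,
                         seed = 1)$fraction == 1
  }
  se <- sqrt(p_analytic * (1 - p_analytic) / n)
  expect_lt(abs(mean(hit) - p_analytic), 3 * se)
})

test_that("group comparison matches hand-computed Welch statistics", {
  a <- c(12, 15, 11, 14, 13, 16)
  b <- c(9, 10, 8, 11, 12)
  res <- compare_groups(a, b)
  # hand-computed Welch t and df
  se2 <- var(a) / length(a) + var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 6)^2 / 5 + (var(b) / 5)^2 / 4)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  # pooled-variance variant
  sp2 <- (5 * var(a) + 4 * var(b)) / 9
  t_pooled <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 5))
  expect_equal(compare_groups(a, b, var_equal = TRUE)$t, t_pooled,
               tolerance = 1e-10)
  # identical groups: exact-equality shortcut
  same <- compare_groups(c(3, 3, 3), c(3, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")
  expect_error(compare_groups(1, c(2, 3)), ">= 2")
})

test_that("type-I error of the comparison is near nominal", {
  set.seed(12)
  rej <- replicate(1000, {
    compare_groups(rnorm(15), rnorm(15))$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("significance stars follow the figure-legend bins", {
  expect_equal(curtaintrack:::p_stars(0.2), "ns")
  expect_equal(curtaintrack:::p_stars(0.04), "*")
  expect_equal(curtaintrack:::p_stars(0.005), "**")
  expect_equal(curtaintrack:::p_stars(5e-4), "***")
  expect_equal(curtaintrack:::p_stars(5e-5), "****")
})

test_that("fold change reproduces the printed ratios", {
  expect_equal(round(unclass(fold_change(18, 9)), 1), 2.0)
  expect_equal(round(unclass(fold_change(18, 13)), 1), 1.4)
  expect_equal(unclass(fold_change(7, 7)), 1.0)
  expect_error(fold_change(1, 0), "zero")
})

test_that("GC profile handles degenerate and mixed sequences", {
  expect_equal(gc_profile(strrep("G", 2000), 500)$gc, rep(1, 4))
  expect_equal(gc_profile(strrep("AT", 1000), 500)$gc, rep(0, 4))
  expect_equal(gc_profile(strrep("GC", 1000), 500)$gc, rep(1, 4))
  expect_warning(p <- gc_profile(paste0(strrep("G", 499), "N"), 500),
                 "non-ACGT")
  expect_equal(p$gc, 499 / 500)
  expect_error(gc_profile("ACGT", 500), "shorter")
})

test_that("pause-GC association is null-calibrated on uniform sequences", {
  # uniform-GC substrate, uniform pause placement: p-values ~ Uniform(0,1)
  set.seed(5)
  seqchar <- paste(sample(c("A", "C", "G", "T"), 48502, replace = TRUE),
                   collapse = "")
  prof <- gc_profile(seqchar, 500)
  pvals <- vapply(1:200, function(i) {
    pauses <- runif(8, 0, 48000)
    pause_gc_association(pauses, prof, seed = 1000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("cohort summary aggregates a kinetics table", {
  kin <- data.frame(
    molecule_id = 1:10,
    velocity_bp_s = c(rep(NA, 3), 15, 18, 20, 22, 17, 19, 21),
    velocity_stderr = 0.5,
    processivity_kb = c(rep(NA, 3), 12, 18, 20, 15, 17, 19, 21),
    n_pauses = c(rep(0, 3), 0, 1, 0, 0, 2, 0, 0),
    bound_lifetime_s = c(rep(3600, 3), 500, 900, 3600, 3600, 1200, 700, 3600),
    censored = c(rep(TRUE, 3), FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    dissociated_within_horizon = NA,
    translocating = c(rep(FALSE, 3), rep(TRUE, 7)))
  s <- cohort_summary(kin, condition = "test", seed = 3)
  expect_equal(s$n_molecules, 10)
  expect_equal(s$n_translocating, 7)
  expect_equal(s$initiation_fraction, 0.7)
  expect_equal(s$velocity_mean, mean(c(15, 18, 20, 22, 17, 19, 21)))
  expect_equal(s$frac_no_pause, 5 / 7)
  expect_equal(s$frac_ge1_pause, 2 / 7)
  expect_equal(s$frac_ge2_pause, 1 / 7)
  expect_equal(s$dissociation_fraction, 0.4)
  expect_gt(s$initiation_sd, 0)
})
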