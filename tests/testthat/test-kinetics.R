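test_that("velocity fit is exact on collinear data and zero when static", {
  flat <- toy_traj(duration = 100, v = 0)
  expect_equal(unname(compute_velocity(flat)["velocity_bp_s"]), 0)
  line <- toy_traj(duration = 400, v = 18, start_bp = 1000)
  v <- compute_velocity(line)
  expect_equal(unname(v["velocity_bp_s"]), 18, tolerance = 1e-10)
  expect_equal(unname(v["stderr"]), 0, tolerance = 1e-8)
  # movers toward the anchor report positive velocity too
  down <- toy_traj(duration = 400, v = -18)
  expect_equal(unname(compute_velocity(down)["velocity_bp_s"]), 18,
               tolerance = 1e-10)
  expect_error(compute_velocity(line[1:3, ]), ">= 5")
})

test_that("velocity CI covers the truth at the nominal rate", {
  # slope 10, 300 bp noise, 200 frames: the OLS CI should cover 10 in
  # >= 93/100 seeded replicates
  hits <- 0L
  for (s in 1:100) {
    tr <- toy_traj(duration = 398, dt = 2, v = 10, start_bp = 2000,
                   noise_sd = 300, seed = s)
    v <- compute_velocity(tr, resolution_bp = 500)
    ci <- v["velocity_bp_s"] + c(-1, 1) * qt(0.975, 198) * v["stderr"]
    if (ci[1] <= 10 && 10 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 93)
})

test_that("processivity measures maximum excursion in kb", {
  expect_equal(compute_processivity(toy_traj(duration = 100, v = 0)), 0)
  run <- toy_traj(duration = 1000, v = -15, start_bp = 20000)
  expect_equal(compute_processivity(run), 15)
  # mid-course pause, truth 12.4 kb net, with localization-scale noise
  tr <- toy_traj(duration = 1400, v = -10, start_bp = 40000,
                 pauses = list(c(400, 160)), noise_sd = 35, seed = 9)
  truth <- 10 * (1400 - 160) / 1000
  expect_equal(truth, 12.4)
  expect_equal(compute_processivity(tr), 12.4, tolerance = 0.2 / 12.4)
  # path-length mode over-counts noise, net mode does not
  expect_gte(compute_processivity(tr, mode = "path"), 12.4)
})

test_that("time reversal negates the slope and preserves processivity", {
  tr <- toy_traj(duration = 600, v = -12, start_bp = 30000, noise_sd = 30,
                 seed = 2)
  rev_tr <- tr
  rev_tr$position_bp <- rev(tr$position_bp)
  v_fwd <- curtaintrack:::ols_slope(tr$time_s, tr$position_bp)["slope"]
  v_rev <- curtaintrack:::ols_slope(rev_tr$time_s, rev_tr$position_bp)["slope"]
  expect_equal(unname(v_fwd), -unname(v_rev), tolerance = 1e-10)
  expect_equal(compute_processivity(tr), compute_processivity(rev_tr),
               tolerance = 0.02)
})

test_that("pause detector matches injected ground truth", {
  # single 60 s stall in a 10 bp/s run: one pause, duration 60 +/- 4 s
  tr <- toy_traj(duration = 800, v = -10, start_bp = 45000,
                 pauses = list(c(300, 60)), noise_sd = 30, seed = 1)
  pz <- detect_pauses(tr)
  expect_equal(nrow(pz), 1)
  expect_lt(abs(pz$duration - 60), 4 + 1e-9)
  expect_lt(abs(pz$t_start - 300), 10)
  expect_lt(abs(pz$prepause_velocity - (-10)), 1)
  expect_lt(abs(pz$postpause_velocity - (-10)), 1)
  # pure mover: no pauses
  expect_equal(nrow(detect_pauses(
    toy_traj(duration = 800, v = -10, noise_sd = 30, seed = 2))), 0)
  # 20 s stall is below threshold
  expect_equal(nrow(detect_pauses(
    toy_traj(duration = 800, v = -10, pauses = list(c(300, 20)),
             noise_sd = 30, seed = 3))), 0)
  # short trace flag
  short <- toy_traj(duration = 20, v = -10)
  out <- detect_pauses(short)
  expect_equal(nrow(out), 0)
  expect_true(attr(out, "short_trace"))
})

test_that("two well-separated pauses are both found", {
  tr <- toy_traj(duration = 1600, v = -10, start_bp = 45000,
                 pauses = list(c(300, 80), c(900, 60)), noise_sd = 30,
                 seed = 4)
  pz <- detect_pauses(tr)
  expect_equal(nrow(pz), 2)
  expect_true(all(diff(pz$t_start) > 0))
  expect_lt(abs(pz$duration[1] - 80), 8)
  expect_lt(abs(pz$duration[2] - 60), 8)
  # events do not overlap
  expect_true(all(pz$t_start[-1] >= pz$t_end[-nrow(pz)]))
})

test_that("pause calls are stable under noise well below resolution", {
  base <- toy_traj(duration = 1000, v = -12, start_bp = 45000,
                   pauses = list(c(400, 70)))
  for (s in 1:8) {
    noisy <- base
    set.seed(100 + s)
    noisy$position_bp <- base$position_bp + rnorm(nrow(base), 0, 80)
    pz <- detect_pauses(noisy)
    expect_equal(nrow(pz), 1)
    expect_lt(abs(pz$duration - 70), 16)
  }
})

test_that("pause_summary reports cohort fractions with counts", {
  kin <- data.frame(n_pauses = c(1, 1, 1), translocating = TRUE)
  ps <- pause_summary(kin)
  expect_equal(unname(ps$fractions), c(0, 1, 0))
  kin2 <- data.frame(n_pauses = c(0, 0, 1, 2), translocating = TRUE)
  ps2 <- pause_summary(kin2)
  expect_equal(unname(ps2$counts), c(2, 2, 1))
  expect_equal(unname(ps2$fractions), c(0.5, 0.5, 0.25))
  expect_error(pause_summary(data.frame(n_pauses = 1,
                                        translocating = FALSE)),
               "translocating")
  # simulated cohort with pause_rate 0 -> all pause-free
  kin3 <- data.frame(n_pauses = rep(0, 20), translocating = TRUE)
  expect_equal(unname(pause_summary(kin3)$fractions["no_pause"]), 1)
})

test_that("survival fit matches the two-point log-linear closed form", {
  lt <- c(100, 300)
  fit <- fit_survival(lt)
  # S(100) = 0.5, S(300) = 0 (dropped); through-origin log-linear:
  k_closed <- -sum(100 * log(0.5)) / sum(100^2)
  expect_equal(fit$k, k_closed, tolerance = 1e-12)
  expect_equal(fit$half_life_s, log(2) / k_closed)
  expect_equal(fit$n, 2)
  expect_error(fit_survival(c(10, 20), c(TRUE, TRUE)), "censored")
})

test_that("survival fit recovers the rate from exponential samples", {
  set.seed(17)
  lt <- rexp(1000, 0.001)
  fit <- fit_survival(lt)
  expect_lt(abs(fit$k - 0.001) / 0.001, 0.10)
  # 50% random right-censoring at a fixed horizon: bias < 15%
  horizon <- quantile(lt, 0.5)
  cens <- lt > horizon
  lt2 <- pmin(lt, horizon)
  fit2 <- fit_survival(lt2, cens)
  expect_lt(abs(fit2$k - 0.001) / 0.001, 0.15)
  # the censoring-aware MLE agrees
  fit3 <- fit_survival(lt2, cens, method = "mle")
  expect_lt(abs(fit3$k - 0.001) / 0.001, 0.10)
})

test_that("dissociation fraction follows the exponential closed form", {
  expect_equal(dissociation_fraction(rep(2000, 5), 1800)$fraction, 0)
  expect_equal(dissociation_fraction(rep(100, 5), 1800)$fraction, 1)
  set.seed(23)
  k <- 6.9e-4
  lt <- rexp(200, k)
  expected <- 1 - exp(-1800 * k)        # ~0.71
  res <- dissociation_fraction(lt, 1800)
  se <- sqrt(expected * (1 - expected) / 200)
  expect_lt(abs(res$fraction - expected), 3 * se)
  expect_error(dissociation_fraction(numeric(0)), "no lifetimes")
})

test_that("analyze_trajectories assembles per-molecule kinetics", {
  tr1 <- toy_traj(duration = 800, v = -20, start_bp = 45000, noise_sd = 30,
                  seed = 5)
  tr1$molecule_id <- 1L
  tr2 <- toy_traj(duration = 800, v = 0, start_bp = 30000, noise_sd = 30,
                  seed = 6)
  tr2$molecule_id <- 2L
  traj <- rbind(tr1, tr2)
  res <- analyze_trajectories(traj, translocating_ids = 1L, n_frames = 401,
                              frame_interval = 2)
  k <- res$kinetics
  expect_equal(nrow(k), 2)
  expect_true(k$translocating[k$molecule_id == 1])
  expect_false(k$translocating[k$molecule_id == 2])
  expect_equal(k$velocity_bp_s[1], 20, tolerance = 0.05)
  expect_equal(k$n_pauses, c(0, 0))
  expect_true(all(k$censored))          # both span the whole movie
  expect_equal(k$bound_lifetime_s, c(802, 802))
})
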