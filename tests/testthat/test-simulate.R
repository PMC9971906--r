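test_that("motor path honors identity and forced-displacement cases", {
  acq <- small_acq(n_frames = 51)   # times 0..100 s at 2 s
  te <- std_tether()
  # zero rates: position constant
  p0 <- motor_params(initial_position_bp = 12000)
  tr0 <- simulate_motor_path(p0, acq, te, seed = 1)
  expect_true(all(tr0$frames$position_bp == 12000))
  expect_true(all(tr0$frames$bound))
  expect_equal(nrow(tr0$pauses), 0)
  # pure drift: 10 bp/s over 100 s -> exactly 1000 bp
  p1 <- motor_params(initial_position_bp = 1000, velocity_bp_s = 10)
  tr1 <- simulate_motor_path(p1, acq, te, seed = 1)
  expect_equal(diff(range(tr1$frames$position_bp)), 1000)
  expect_equal(tr1$frames$position_bp[51], 2000)
})

test_that("motor path rejects invalid inputs", {
  acq <- small_acq(n_frames = 10)
  te <- std_tether()
  expect_error(motor_params(pause_rate = -1), "pause_rate")
  expect_error(motor_params(dissociation_rate = -0.1), "dissociation_rate")
  expect_error(
    simulate_motor_path(motor_params(initial_position_bp = 6e4), acq, te),
    "beyond")
})

test_that("stochastic pauses match an independent event-queue replay", {
  acq <- small_acq(n_frames = 400)
  te <- std_tether()
  p <- motor_params(initial_position_bp = 45000, velocity_bp_s = -20,
                    pause_rate = 1 / 300, pause_duration_mean = 60)
  for (seed in c(3L, 11L, 29L)) {
    tr <- simulate_motor_path(p, acq, te, seed = seed)
    ev <- oracle_pause_events(p, acq, seed)
    # clip the oracle to the (uncensored) bound lifetime like the simulator
    horizon <- acq$n_frames * acq$frame_interval
    ev <- ev[ev$t_start < horizon, , drop = FALSE]
    ev$t_end <- pmin(ev$t_end, horizon)
    expect_equal(tr$pauses$t_start, ev$t_start, tolerance = 1e-12)
    expect_equal(tr$pauses$t_end, ev$t_end, tolerance = 1e-12)
  }
})

test_that("scheduled pauses freeze the position for their duration", {
  acq <- small_acq(n_frames = 300)
  te <- std_tether()
  p <- motor_params(initial_position_bp = 45000, velocity_bp_s = -30,
                    pause_schedule = data.frame(t_start = 200,
                                                duration = 60))
  tr <- simulate_motor_path(p, acq, te, seed = 2)
  fr <- tr$frames
  inside <- fr$time_s >= 200 & fr$time_s <= 260
  expect_equal(nrow(tr$pauses), 1)
  expect_equal(tr$pauses$t_end - tr$pauses$t_start, 60)
  expect_equal(diff(range(fr$position_bp[inside])), 0)
  before <- fr$position_bp[fr$time_s == 198]
  after <- fr$position_bp[fr$time_s == 262]
  expect_equal(before - after, 30 * 4)  # only the 4 moving seconds count
})

test_that("blinking duty cycle converges to on/(on+off)", {
  acq <- acquisition_config(n_frames = 10000, image_shape = c(16L, 16L))
  te <- std_tether()
  p <- motor_params(initial_position_bp = 10000,
                    blink_on_rate = 0.3, blink_off_rate = 0.1)
  tr <- simulate_motor_path(p, acq, te, seed = 4)
  dt <- acq$frame_interval
  p_on <- 1 - exp(-0.3 * dt); p_off <- 1 - exp(-0.1 * dt)
  duty <- p_on / (p_on + p_off)     # stationary prob of the sampled chain
  obs <- mean(tr$frames$emitting)
  se <- sqrt(duty * (1 - duty) / 10000)
  # 3 SE with a correlation inflation factor for the Markov chain
  rho <- 1 - p_on - p_off
  neff <- 10000 * (1 - rho) / (1 + rho)
  expect_lt(abs(obs - duty), 3 * sqrt(duty * (1 - duty) / neff))
})

test_that("empirical pause counts match the pause rate", {
  acq <- acquisition_config(n_frames = 3000, image_shape = c(16L, 16L))
  te <- std_tether()
  rate <- 1 / 500
  p <- motor_params(initial_position_bp = 100, velocity_bp_s = 1,
                    pause_rate = rate, pause_duration_mean = 20)
  counts <- vapply(1:40, function(s) {
    nrow(simulate_motor_path(p, acq, te, seed = s)$pauses)
  }, numeric(1))
  # moving time per movie ~ horizon - n_pauses*20; expected count ~
  # rate * moving_time; use total horizon with the duty correction
  horizon <- 3000 * 2
  expected_rate <- rate / (1 + rate * 20)        # renewal-process rate
  expected <- expected_rate * horizon
  se <- sqrt(expected / 40)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("rendering conserves photons and reproduces pure noise", {
  acq <- small_acq(n_frames = 3, background = 150, read_noise_sd = 8)
  te <- std_tether()
  # no tracks: mean pixel ~ background within 3 SE
  rs0 <- render_stack(list(), te, acq, seed = 9)
  px <- as.vector(rs0$stacks[[1]])
  se <- sd(px) / sqrt(length(px))
  expect_lt(abs(mean(px) - 150), 3 * se)
  # one stationary emitter, no noise/blinking: summed signal = integrated
  # amplitude within 0.5% (grid truncation), against direct summation of
  # the analytic Gaussian over the full pixel grid
  p <- motor_params(initial_position_bp = 20000, amplitude_photons = 1234,
                    psf_sigma_px = 1.1)
  tr <- simulate_motor_path(p, acq, te, seed = 1)
  rs <- render_stack(list(tr), te, acq, seed = 1, noise = FALSE)
  for (f in 1:3) {
    expect_equal(sum(rs$stacks[[1]][, , f]), 1234, tolerance = 0.005)
  }
  xy <- rs$truth[1, c("true_x_px", "true_y_px")]
  # render truncates the patch at ~5 sigma; allow that tail
  oracle <- sum(gauss_frame(40, 128, xy[[1]], xy[[2]], A = 1234))
  expect_equal(sum(rs$stacks[[1]][, , 1]), oracle, tolerance = 1e-6)
})

test_that("acquisition cadence gives 1800 frames per hour", {
  acq <- acquisition_config(frame_interval = 2, exposure = 0.2,
                            duration_s = 3600)
  expect_identical(acq$n_frames, 1800L)
})

test_that("rendering is deterministic and flow stop recoils only DNA", {
  acq <- small_acq(n_frames = 30, flow_stop = c(10L, 19L))
  te <- std_tether()
  mover <- simulate_motor_path(
    motor_params(initial_position_bp = 40000), acq, te, seed = 2,
    molecule_id = "m")
  decoy <- simulate_motor_path(
    motor_params(initial_position_bp = 20000, attachment = "surface"),
    acq, te, seed = 3, molecule_id = "d")
  rs1 <- render_stack(list(mover, decoy), te, acq, seed = 5)
  rs2 <- render_stack(list(mover, decoy), te, acq, seed = 5)
  expect_identical(rs1$stacks[[1]], rs2$stacks[[1]])
  expect_identical(rs1$truth, rs2$truth)
  tru <- rs1$truth
  m_flow <- tru$true_x_px[tru$molecule_id == "m" & tru$frame == 0]
  m_stop <- tru$true_x_px[tru$molecule_id == "m" & tru$frame == 15]
  d_flow <- tru$true_x_px[tru$molecule_id == "d" & tru$frame == 0]
  d_stop <- tru$true_x_px[tru$molecule_id == "d" & tru$frame == 15]
  # DNA-bound molecule collapses to 20% of its anchor distance
  expect_equal(m_stop - 8, 0.2 * (m_flow - 8), tolerance = 1e-9)
  expect_equal(d_stop, d_flow)
})

test_that("fixture suite is complete, ground-truthed and reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  acq <- acquisition_config(n_frames = 150, image_shape = c(40L, 128L),
                            flow_stop = c(20L, 35L))
  suite <- make_fixture_suite(dir1, acq = acq, seed = 7)
  expect_gte(length(suite$fixtures), 7)
  truth <- read.csv(suite$truth_csv)
  for (nm in names(suite$fixtures)) {
    expect_true(all(file.exists(suite$fixtures[[nm]]$tiff)))
    expect_gt(sum(truth$fixture == nm), 0)
  }
  # two channels for the colocalized pair
  expect_length(suite$fixtures$colocalized_pair$tiff, 2)
  # pausing fixture: exactly one pause >= 30 s in the sidecar schedule
  make_fixture_suite(dir2, acq = acq, seed = 7)
  expect_identical(readBin(suite$truth_csv, "raw", 1e7),
                   readBin(file.path(dir2, "ground_truth.csv"), "raw", 1e7))
})

test_that("pausing-mover fixture carries one pause >= 30 s", {
  acq <- acquisition_config(n_frames = 200, image_shape = c(40L, 128L))
  te <- std_tether()
  p <- motor_params(initial_position_bp = 45000, velocity_bp_s = -30,
                    pause_schedule = data.frame(t_start = 150,
                                                duration = 60))
  tr <- simulate_motor_path(p, acq, te, seed = 7)
  expect_equal(nrow(tr$pauses), 1)
  expect_gte(tr$pauses$t_end - tr$pauses$t_start, 30)
})
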