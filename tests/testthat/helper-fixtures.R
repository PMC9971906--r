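# Shared fixtures, built in code at test time.

small_acq <- function(n_frames = 200, ...) {
  acquisition_config(n_frames = n_frames, image_shape = c(40L, 128L), ...)
}

std_tether <- function() {
  dna_tether(anchor_px = c(8, 20), axis_direction = c(1, 0),
             extension_px = 100)
}

# render a single noiseless integrated Gaussian into a blank frame
gauss_frame <- function(nr = 21, nc = 21, x0 = 10, y0 = 10, A = 2000,
                        sigma = 1.1, b = 0) {
  xs <- 0:(nc - 1); ys <- 0:(nr - 1)
  gx <- pnorm((xs + 0.5 - x0) / sigma) - pnorm((xs - 0.5 - x0) / sigma)
  gy <- pnorm((ys + 0.5 - y0) / sigma) - pnorm((ys - 0.5 - y0) / sigma)
  b + A * (gy %o% gx)
}

# clean analytic trajectory: velocity v bp/s with optional pause windows
# (list of c(t_start, duration)), sampled every dt seconds plus noise
toy_traj <- function(duration = 800, dt = 2, v = -10, start_bp = 45000,
                     pauses = list(), noise_sd = 0, seed = 1) {
  tt <- seq(0, duration, by = dt)
  paused <- rep(0, length(tt))
  for (p in pauses) {
    paused <- paused + pmax(0, pmin(tt, p[1] + p[2]) - p[1])
  }
  pos <- start_bp + v * (tt - paused)
  if (noise_sd > 0) {
    set.seed(seed)
    pos <- pos + rnorm(length(tt), 0, noise_sd)
  }
  data.frame(frame = seq_along(tt) - 1L, time_s = tt, position_bp = pos,
             molecule_id = 1L)
}

# independent event-queue replay of the documented RNG draw order in
# simulate_motor_path (dissociation first, then alternating move/pause)
oracle_pause_events <- function(params, acq, seed) {
  set.seed(seed)
  horizon <- acq$n_frames * acq$frame_interval
  if (params$dissociation_rate > 0) rexp(1, params$dissociation_rate)
  ev <- data.frame(t_start = numeric(0), t_end = numeric(0))
  t <- 0
  while (t < horizon) {
    t <- t + rexp(1, params$pause_rate)
    if (t >= horizon) break
    dur <- rexp(1, 1 / params$pause_duration_mean)
    ev <- rbind(ev, data.frame(t_start = t, t_end = t + dur))
    t <- t + dur
  }
  ev
}
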