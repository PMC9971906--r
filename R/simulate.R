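#' Simulate the true path of one motor on a DNA tether
#'
#' Event-queue simulation of a single molecule: constant-velocity
#' translocation interrupted by exponentially distributed pauses (zero
#' velocity), optional exponential dissociation or dissociation after a fixed
#' ground-truth run length, Brownian velocity jitter while moving, and
#' two-state telegraph blinking sampled at frame boundaries.
#'
#' Random draws are consumed in a documented, reproducible order: (1) the
#' dissociation time, (2) alternating move-segment and pause durations,
#' (3) per-frame blinking transitions, (4) per-frame jitter increments. This
#' order is part of the function contract so that independent event-queue
#' oracles can replay it from the same seed.
#'
#' @param params A [motor_params()].
#' @param acq An [acquisition_config()].
#' @param tether A [dna_tether()].
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param molecule_id,channel Identifiers carried into the output.
#' @return An object of class `ground_truth_track`: a list with `frames`
#'   (data.frame: frame, time_s, position_bp, emitting, bound), `pauses`
#'   (data.frame: t_start, t_end), `dissociation_time` (`NA` if the molecule
#'   is still bound at the movie end, i.e. right-censored), `censored`,
#'   `molecule_id`, `channel`, `attachment` and the originating `params`.
#' @examples
#' acq <- acquisition_config(n_frames = 50)
#' p <- motor_params(initial_position_bp = 40000, velocity_bp_s = -20)
#' tr <- simulate_motor_path(p, acq, dna_tether(), seed = 1)
#' head(tr$frames)
#' @export
simulate_motor_path <- function(params, acq, tether, seed = acq$rng_seed,
                                molecule_id = 1L, channel = 0L) {
  stopifnot(inherits(params, "motor_params"),
            inherits(acq, "acquisition_config"),
            inherits(tether, "dna_tether"))
  if (acq$n_frames < 1) stop("zero-length acquisition", call. = FALSE)
  if (params$initial_position_bp > tether$total_bp) {
    stop("initial_position_bp beyond tether end", call. = FALSE)
  }
  with_seed(seed, {
    dt <- acq$frame_interval
    times <- (seq_len(acq$n_frames) - 1) * dt
    horizon <- acq$n_frames * dt

    # (1) dissociation clock (runs over total bound time, pauses included)
    t_diss <- if (params$dissociation_rate > 0) {
      stats::rexp(1, params$dissociation_rate)
    } else Inf

    # (2) pause process: scheduled pauses override the stochastic queue
    pauses <- data.frame(t_start = numeric(0), t_end = numeric(0))
    moving <- params$initiates && params$velocity_bp_s != 0
    if (moving && !is.null(params$pause_schedule)) {
      ps <- params$pause_schedule
      pauses <- data.frame(t_start = ps$t_start,
                           t_end = ps$t_start + ps$duration)
      pauses <- pauses[order(pauses$t_start), , drop = FALSE]
    } else if (moving && params$pause_rate > 0) {
      t <- 0
      while (t < horizon) {
        seg <- stats::rexp(1, params$pause_rate)      # moving segment
        t <- t + seg
        if (t >= horizon) break
        dur <- stats::rexp(1, 1 / params$pause_duration_mean)
        pauses <- rbind(pauses, data.frame(t_start = t, t_end = t + dur))
        t <- t + dur
      }
    }

    # moving time elapsed at each frame time (pauses subtracted)
    paused_before <- function(tt) {
      if (nrow(pauses) == 0) return(rep(0, length(tt)))
      out <- numeric(length(tt))
      for (i in seq_len(nrow(pauses))) {
        out <- out + pmax(0, pmin(tt, pauses$t_end[i]) - pauses$t_start[i])
      }
      out
    }
    mv_time <- if (moving) times - paused_before(times) else rep(0, length(times))

    # dissociation from run-length cap (ground-truth processivity)
    if (moving && !is.na(params$stop_after_bp) &&
        abs(params$velocity_bp_s) > 0) {
      mv_needed <- params$stop_after_bp / abs(params$velocity_bp_s)
      # wall-clock time at which moving time reaches mv_needed
      grid <- seq(0, horizon, by = dt / 4)
      mt <- grid - paused_before(grid)
      hit <- which(mt >= mv_needed)
      t_cap <- if (length(hit)) grid[hit[1]] else Inf
      t_diss <- min(t_diss, t_cap)
    }
    bound_end <- min(t_diss, horizon)
    censored <- !(t_diss < horizon)
    bound <- times < bound_end

    pos <- params$initial_position_bp + params$velocity_bp_s * mv_time

    # (3) blinking telegraph, sampled per frame, starts emitting
    n <- length(times)
    emit <- rep(TRUE, n)
    if (params$blink_off_rate > 0 || params$blink_on_rate > 0) {
      p_off <- 1 - exp(-params$blink_off_rate * dt)
      p_on <- 1 - exp(-params$blink_on_rate * dt)
      u <- stats::runif(n)
      state <- TRUE
      for (i in seq_len(n)) {
        emit[i] <- state
        state <- if (state) u[i] >= p_off else u[i] < p_on
      }
    }

    # (4) Brownian jitter accrues only while moving
    if (params$velocity_noise_sd > 0 && moving) {
      d_mv <- diff(c(0, mv_time))
      pos <- pos + cumsum(stats::rnorm(n, 0, params$velocity_noise_sd *
                                            sqrt(pmax(d_mv, 0))))
    }
    pos <- clamp(pos, 0, tether$total_bp)
    pos[!bound] <- NA_real_

    # clip pauses to the bound lifetime, drop empty ones
    if (nrow(pauses)) {
      pauses$t_end <- pmin(pauses$t_end, bound_end)
      pauses <- pauses[pauses$t_end > pauses$t_start &
                         pauses$t_start < bound_end, , drop = FALSE]
      rownames(pauses) <- NULL
    }

    structure(list(
      molecule_id = molecule_id, channel = as.integer(channel),
      frames = data.frame(
        frame = seq_len(n) - 1L, time_s = times, position_bp = pos,
        emitting = emit & bound, bound = bound),
      pauses = pauses,
      dissociation_time = if (censored) NA_real_ else t_diss,
      censored = censored,
      attachment = params$attachment,
      params = params
    ), class = "ground_truth_track")
  })
}

#' @export
print.ground_truth_track <- function(x, ...) {
  nb <- sum(x$frames$bound)
  cat(sprintf("<ground_truth_track> molecule %s ch%d: %d/%d bound frames, %d pause(s)%s\n",
              format(x$molecule_id), x$channel, nb, nrow(x$frames),
              nrow(x$pauses), if (x$censored) ", censored" else ""))
  invisible(x)
}

# map a bp coordinate on a tether to (x, y) pixels
bp_to_px <- function(position_bp, tether) {
  s <- position_bp / tether$bp_per_px
  cbind(tether$anchor_px[1] + s * tether$axis_direction[1],
        tether$anchor_px[2] + s * tether$axis_direction[2])
}

# integrated symmetric 2D Gaussian on an integer pixel grid (0-based centers)
add_psf_patch <- function(img, x0, y0, amplitude, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  half <- ceiling(4 * sigma) + 1
  cx <- round(x0); cy <- round(y0)
  cols <- max(0, cx - half):min(nc - 1, cx + half)
  rows <- max(0, cy - half):min(nr - 1, cy + half)
  if (!length(cols) || !length(rows)) return(img)
  gx <- stats::pnorm((cols + 0.5 - x0) / sigma) -
        stats::pnorm((cols - 0.5 - x0) / sigma)
  gy <- stats::pnorm((rows + 0.5 - y0) / sigma) -
        stats::pnorm((rows - 0.5 - y0) / sigma)
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] +
    amplitude * (gy %o% gx)
  img
}

#' Render synthetic image stacks from ground-truth tracks
#'
#' Rasterizes simulated molecules into a per-channel movie: each emitting
#' molecule contributes an integrated symmetric 2D Gaussian at its mapped
#' subpixel position; optional global stage drift shifts every emitter;
#' during a flow-stop window DNA-tethered molecules recoil toward their
#' anchor (axial distance compressed by `recoil_factor`) while surface-stuck
#' decoys stay put; finally Poisson shot noise on signal + background and
#' Gaussian read noise are applied.
#'
#' @param tracks List of [simulate_motor_path()] outputs.
#' @param tethers A single [dna_tether()] (recycled) or a list parallel to
#'   `tracks`.
#' @param acq An [acquisition_config()].
#' @param seed Integer seed for the noise draws.
#' @param drift_px Optional `n_frames x 2` matrix of global (dx, dy) pixel
#'   offsets per frame (frame 0 should be (0, 0)).
#' @param recoil_factor Fraction of the anchor distance removed during flow
#'   stop (default 0.8: molecules collapse to 20% of their distance).
#' @param noise Logical; `FALSE` renders noiseless, background-free frames.
#' @return A list with `stacks` (list over channels of `[rows, cols, frames]`
#'   arrays), `truth` (data.frame: molecule_id, channel, frame, time_s,
#'   true_position_bp, emitting, bound, true_x_px, true_y_px) and the `acq`
#'   used. The truth positions include recoil and drift, i.e. they are what a
#'   perfect localizer would report.
#' @export
render_stack <- function(tracks, tethers, acq, seed = acq$rng_seed,
                         drift_px = NULL, recoil_factor = 0.8,
                         noise = TRUE) {
  stopifnot(inherits(acq, "acquisition_config"))
  if (inherits(tracks, "ground_truth_track")) tracks <- list(tracks)
  if (inherits(tethers, "dna_tether")) {
    tethers <- rep(list(tethers), length(tracks))
  }
  stopifnot(length(tethers) == length(tracks))
  for (tr in tracks) {
    if (any(tr$frames$emitting & tr$params$amplitude_photons < 0)) {
      stop("negative amplitude", call. = FALSE)
    }
  }
  nr <- acq$image_shape[1]; nc <- acq$image_shape[2]
  nf <- acq$n_frames
  if (!is.null(drift_px)) {
    drift_px <- as.matrix(drift_px)
    stopifnot(nrow(drift_px) == nf, ncol(drift_px) == 2L)
  }
  in_stop <- rep(FALSE, nf)
  if (!is.null(acq$flow_stop)) {
    in_stop[(acq$flow_stop[1]:acq$flow_stop[2]) + 1L] <- TRUE
  }

  channels <- sort(unique(vapply(tracks, `[[`, integer(1), "channel")))
  if (!length(channels)) channels <- 0L
  stacks <- lapply(channels, function(ch) array(0, dim = c(nr, nc, nf)))
  names(stacks) <- paste0("c", channels)

  # precompute every emitter's mapped pixel position, then rasterize
  # frame-major so each frame matrix is touched once
  truth <- vector("list", length(tracks))
  clipped <- 0L
  emitters <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]; te <- tethers[[k]]
    fr <- tr$frames
    pos_eff <- fr$position_bp
    if (tr$attachment == "dna") {
      w <- in_stop[fr$frame + 1L] & fr$bound
      pos_eff[w] <- pos_eff[w] * (1 - recoil_factor)
    }
    xy <- bp_to_px(ifelse(is.na(pos_eff), 0, pos_eff), te)
    if (!is.null(drift_px)) {
      xy <- xy + drift_px[fr$frame + 1L, , drop = FALSE]
    }
    out_of <- fr$emitting & (xy[, 1] < 0 | xy[, 1] > nc - 1 |
                             xy[, 2] < 0 | xy[, 2] > nr - 1)
    clipped <- clipped + sum(out_of)
    ei <- which(fr$emitting)
    emitters[[k]] <- data.frame(
      frame = fr$frame[ei], x = xy[ei, 1], y = xy[ei, 2],
      amp = tr$params$amplitude_photons, sigma = tr$params$psf_sigma_px,
      channel = tr$channel)
    truth[[k]] <- data.frame(
      molecule_id = tr$molecule_id, channel = tr$channel,
      frame = fr$frame, time_s = fr$time_s,
      true_position_bp = fr$position_bp,
      emitting = fr$emitting, bound = fr$bound,
      true_x_px = ifelse(fr$bound, xy[, 1], NA_real_),
      true_y_px = ifelse(fr$bound, xy[, 2], NA_real_))
  }
  emit_tab <- do.call(rbind, emitters) %||%
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               amp = numeric(0), sigma = numeric(0), channel = integer(0))
  for (ci in seq_along(stacks)) {
    ch <- channels[ci]
    et <- emit_tab[emit_tab$channel == ch, , drop = FALSE]
    if (!nrow(et)) next
    by_frame <- split(et, et$frame)
    for (key in names(by_frame)) {
      ef <- by_frame[[key]]
      f <- ef$frame[1] + 1L
      img <- matrix(0, nr, nc)
      for (i in seq_len(nrow(ef))) {
        img <- add_psf_patch(img, ef$x[i], ef$y[i], ef$amp[i], ef$sigma[i])
      }
      stacks[[ci]][, , f] <- img
    }
  }
  if (clipped > 0) {
    warning(sprintf("%d emitter-frames fell outside the image and were clipped",
                    clipped), call. = FALSE)
  }
  if (noise) {
    with_seed(seed, {
      for (ci in seq_along(stacks)) {
        lam <- stacks[[ci]] + acq$background
        n_px <- length(lam)
        counts <- stats::rpois(n_px, lam) +
          stats::rnorm(n_px, 0, acq$read_noise_sd)
        stacks[[ci]] <- array(pmax(counts, 0), dim = dim(lam))
      }
    })
  }
  list(stacks = stacks, truth = do.call(rbind, truth), acq = acq,
       channels = channels)
}

#' Write a standard battery of ground-truthed fixtures to disk
#'
#' Generates a small named suite covering the behaviors the analysis pipeline
#' must handle: a stationary fiducial, fast and slow movers, a pausing mover
#' (one scheduled 60 s pause), a blinking mover, a surface-stuck decoy (does
#' not recoil on flow stop), and a two-channel colocalized pair. Each fixture
#' is written as one multi-page 16-bit TIFF per channel plus a shared
#' ground-truth CSV and a config JSON; runs are byte-reproducible for a
#' fixed seed.
#'
#' @param dir Output directory (created if missing).
#' @param acq An [acquisition_config()]; the default is a compact movie
#'   (300 frames at 2 s, 40 x 128 px, flow stop at frames 20-35).
#' @param seed Integer master seed.
#' @return Invisibly, a list with `fixtures` (named list of file paths and
#'   parameters), `truth_csv`, `config_json`.
#' @export
make_fixture_suite <- function(dir,
                               acq = acquisition_config(
                                 n_frames = 300, image_shape = c(40L, 128L),
                                 flow_stop = c(20L, 35L)),
                               seed = 7L) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create ", dir, call. = FALSE)
  }
  tether <- dna_tether(anchor_px = c(8, 20), axis_direction = c(1, 0),
                       extension_px = 100)
  defs <- list(
    stationary_fiducial = motor_params(initial_position_bp = 2000,
                                       attachment = "surface",
                                       amplitude_photons = 3000),
    fast_mover = motor_params(initial_position_bp = 46000,
                              velocity_bp_s = -50),
    slow_mover = motor_params(initial_position_bp = 44000,
                              velocity_bp_s = -10),
    pausing_mover = motor_params(
      initial_position_bp = 45000, velocity_bp_s = -30,
      pause_schedule = data.frame(t_start = 200, duration = 60)),
    blinking_mover = motor_params(initial_position_bp = 43000,
                                  velocity_bp_s = -25,
                                  blink_on_rate = 0.5, blink_off_rate = 0.1),
    surface_decoy = motor_params(initial_position_bp = 20000,
                                 attachment = "surface"),
    colocalized_pair = NULL  # built below, two channels
  )
  fixtures <- list()
  truth_all <- list()
  for (nm in names(defs)) {
    sd_i <- derive_seed(seed, nm)
    if (nm == "colocalized_pair") {
      p0 <- motor_params(initial_position_bp = 40000, velocity_bp_s = -20)
      p1 <- motor_params(initial_position_bp = 40000, velocity_bp_s = -20)
      tr <- list(
        simulate_motor_path(p0, acq, tether, seed = sd_i,
                            molecule_id = paste0(nm, "_A"), channel = 0L),
        simulate_motor_path(p1, acq, tether, seed = sd_i,
                            molecule_id = paste0(nm, "_B"), channel = 1L))
    } else {
      tr <- list(simulate_motor_path(defs[[nm]], acq, tether, seed = sd_i,
                                     molecule_id = nm, channel = 0L))
    }
    rs <- render_stack(tr, tether, acq, seed = derive_seed(sd_i, "noise"))
    paths <- character(0)
    for (ci in seq_along(rs$stacks)) {
      p <- file.path(dir, sprintf("%s_%s.tif", nm, names(rs$stacks)[ci]))
      write_tiff16(rs$stacks[[ci]], p)
      paths <- c(paths, p)
    }
    tru <- rs$truth
    tru$fixture <- nm
    truth_all[[nm]] <- tru
    fixtures[[nm]] <- list(tiff = paths, n_molecules = length(tr))
  }
  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL
  truth_csv <- file.path(dir, "ground_truth.csv")
  utils::write.csv(truth, truth_csv, row.names = FALSE)
  cfg <- list(
    seed = seed,
    acquisition = acq[c("frame_interval", "exposure", "n_frames",
                        "image_shape", "pixel_size", "channels",
                        "background", "read_noise_sd")],
    flow_stop = acq$flow_stop,
    tether = list(anchor_px = tether$anchor_px,
                  axis_direction = tether$axis_direction,
                  extension_px = tether$extension_px,
                  total_bp = tether$total_bp),
    fixtures = lapply(fixtures, function(f) list(
      tiff = basename(f$tiff), n_molecules = f$n_molecules))
  )
  config_json <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, config_json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(fixtures = fixtures, truth_csv = truth_csv,
                 config_json = config_json, tether = tether, acq = acq))
}
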