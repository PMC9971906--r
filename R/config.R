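#' Acquisition configuration for a DNA-curtain movie
#'
#' Describes the camera and timing model of a single-molecule acquisition:
#' shuttered time-lapse imaging at `frame_interval` seconds per frame with
#' `exposure` seconds of illumination, an EMCCD background/read-noise model,
#' and an optional flow-stop window during which buffer flow is halted so
#' that DNA-tethered molecules recoil toward the barrier.
#'
#' The default cadence (0.2 s exposure, 2 s interval) gives 1800 frames per
#' hour of imaging.
#'
#' @param frame_interval Seconds between frame starts (> 0).
#' @param exposure Illuminated seconds per frame (0 < exposure <=
#'   frame_interval).
#' @param n_frames Number of frames (>= 1). Exactly one of `n_frames` and
#'   `duration_s` must be given.
#' @param duration_s Total movie duration in seconds; converted to
#'   `floor(duration_s / frame_interval)` frames.
#' @param image_shape Integer c(rows, cols) of each frame in pixels.
#' @param pixel_size Micrometers per pixel in the sample plane.
#' @param channels Number of spectral channels (1 or 2).
#' @param flow_stop Optional integer c(start_frame, end_frame) (0-based,
#'   inclusive) during which flow is halted; must lie within
#'   `[0, n_frames)`.
#' @param background Mean background level, photons per pixel per frame.
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param rng_seed Default seed used by simulators consuming this config.
#' @return An object of class `acquisition_config`.
#' @examples
#' acq <- acquisition_config(frame_interval = 2, exposure = 0.2,
#'                           duration_s = 3600)
#' acq$n_frames  # 1800
#' @export
acquisition_config <- function(frame_interval = 2, exposure = 0.2,
                               n_frames = NULL, duration_s = NULL,
                               image_shape = c(64L, 128L),
                               pixel_size = 0.27, channels = 1L,
                               flow_stop = NULL, background = 200,
                               read_noise_sd = 10, rng_seed = 1L) {
  assert_scalar_num(frame_interval, "frame_interval", lower = 1e-9)
  assert_scalar_num(exposure, "exposure", lower = 1e-12)
  if (exposure > frame_interval) {
    stop("'exposure' must not exceed 'frame_interval'", call. = FALSE)
  }
  if (is.null(n_frames) && is.null(duration_s)) {
    stop("give one of 'n_frames' or 'duration_s'", call. = FALSE)
  }
  if (!is.null(duration_s)) {
    assert_scalar_num(duration_s, "duration_s", lower = frame_interval)
    n_frames <- as.integer(floor(duration_s / frame_interval))
  }
  assert_scalar_num(n_frames, "n_frames", lower = 1)
  n_frames <- as.integer(n_frames)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8))
  if (!channels %in% c(1L, 2L)) stop("'channels' must be 1 or 2", call. = FALSE)
  if (!is.null(flow_stop)) {
    stopifnot(length(flow_stop) == 2L)
    flow_stop <- as.integer(flow_stop)
    if (flow_stop[1] < 0 || flow_stop[2] >= n_frames ||
        flow_stop[1] > flow_stop[2]) {
      stop("'flow_stop' window must lie within [0, n_frames)", call. = FALSE)
    }
  }
  assert_scalar_num(background, "background", lower = 0)
  assert_scalar_num(read_noise_sd, "read_noise_sd", lower = 0)
  structure(list(
    frame_interval = frame_interval, exposure = exposure,
    n_frames = n_frames, image_shape = as.integer(image_shape),
    pixel_size = pixel_size, channels = as.integer(channels),
    flow_stop = flow_stop, background = background,
    read_noise_sd = read_noise_sd, rng_seed = rng_seed
  ), class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %d frames @ %.3g s (%.3g s exposure), %dx%d px, %d channel(s)\n",
    x$n_frames, x$frame_interval, x$exposure,
    x$image_shape[1], x$image_shape[2], x$channels))
  if (!is.null(x$flow_stop)) {
    cat(sprintf("  flow stop: frames %d-%d\n", x$flow_stop[1], x$flow_stop[2]))
  }
  invisible(x)
}

#' DNA tether geometry
#'
#' One flow-stretched DNA molecule anchored at a diffusion barrier. Positions
#' along the molecule are measured in base pairs from the tethered (anchor)
#' end; the implied calibration is `total_bp / extension_px` base pairs per
#' pixel (about 485 bp/px for a 48,502 bp molecule stretched over 100 px).
#'
#' @param anchor_px Numeric c(x, y), subpixel anchor position (0-based pixel
#'   coordinates; x = column, y = row, pixel centers at integers).
#' @param axis_direction Numeric c(dx, dy) direction of increasing DNA
#'   coordinate in the image plane; normalized internally.
#' @param extension_px Pixels spanned by the full-length stretched DNA (> 0).
#' @param total_bp Total substrate length in base pairs (default lambda
#'   phage, 48,502 bp).
#' @return An object of class `dna_tether`.
#' @export
dna_tether <- function(anchor_px = c(5, 10), axis_direction = c(1, 0),
                       extension_px = 100, total_bp = 48502L) {
  stopifnot(length(anchor_px) == 2L, length(axis_direction) == 2L)
  assert_scalar_num(extension_px, "extension_px", lower = 1e-9)
  assert_scalar_num(total_bp, "total_bp", lower = 1)
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm < 1e-12) stop("'axis_direction' must be non-zero", call. = FALSE)
  structure(list(
    anchor_px = as.numeric(anchor_px),
    axis_direction = as.numeric(axis_direction) / nrm,
    extension_px = extension_px, total_bp = as.integer(total_bp),
    bp_per_px = total_bp / extension_px
  ), class = "dna_tether")
}

#' @export
print.dna_tether <- function(x, ...) {
  cat(sprintf(
    "<dna_tether> %d bp over %.4g px (%.4g bp/px), anchor (%.4g, %.4g)\n",
    x$total_bp, x$extension_px, x$bp_per_px,
    x$anchor_px[1], x$anchor_px[2]))
  invisible(x)
}

#' Motor / emitter behavioral parameters
#'
#' Parameterizes one simulated molecule: directed translocation with optional
#' diffusive jitter, exponentially distributed pauses, dissociation, and
#' two-state quantum-dot blinking. Rates are per second; `velocity_bp_s` is
#' signed along the tether axis (positive = away from the anchor).
#'
#' @param initial_position_bp Starting DNA coordinate in bp from the anchor.
#' @param velocity_bp_s Signed translocation velocity, bp/s.
#' @param velocity_noise_sd Diffusive jitter SD, bp per sqrt(second); applied
#'   as Brownian increments while the motor is moving.
#' @param pause_rate Pause initiation rate while moving, events/s.
#' @param pause_duration_mean Mean pause duration, seconds.
#' @param pause_schedule Optional data.frame with columns `t_start`,
#'   `duration` (seconds) of deterministic injected pauses; overrides the
#'   stochastic pause process.
#' @param dissociation_rate Exponential dissociation rate, 1/s (0 = never).
#' @param stop_after_bp Optional net displacement (bp) after which the motor
#'   dissociates, encoding a ground-truth processivity; `NA` to disable.
#' @param initiates Logical; if `FALSE` the molecule stays end-bound and
#'   static (it never translocates), for initiation-fraction denominators.
#' @param blink_on_rate,blink_off_rate Telegraph-process rates, 1/s, for
#'   dark-to-emitting and emitting-to-dark transitions. Both 0 = always on.
#' @param amplitude_photons Integrated photons per frame when emitting.
#' @param psf_sigma_px Gaussian PSF sigma in pixels.
#' @param attachment `"dna"` for a tethered molecule (recoils on flow stop)
#'   or `"surface"` for a surface-stuck decoy (does not recoil).
#' @return An object of class `motor_params`.
#' @export
motor_params <- function(initial_position_bp = 0, velocity_bp_s = 0,
                         velocity_noise_sd = 0, pause_rate = 0,
                         pause_duration_mean = 60, pause_schedule = NULL,
                         dissociation_rate = 0, stop_after_bp = NA_real_,
                         initiates = TRUE,
                         blink_on_rate = 0, blink_off_rate = 0,
                         amplitude_photons = 2000, psf_sigma_px = 1.1,
                         attachment = c("dna", "surface")) {
  assert_scalar_num(initial_position_bp, "initial_position_bp", lower = 0)
  assert_scalar_num(velocity_bp_s, "velocity_bp_s")
  assert_scalar_num(velocity_noise_sd, "velocity_noise_sd", lower = 0)
  assert_scalar_num(pause_rate, "pause_rate", lower = 0)
  assert_scalar_num(pause_duration_mean, "pause_duration_mean", lower = 0)
  assert_scalar_num(dissociation_rate, "dissociation_rate", lower = 0)
  assert_scalar_num(blink_on_rate, "blink_on_rate", lower = 0)
  assert_scalar_num(blink_off_rate, "blink_off_rate", lower = 0)
  assert_scalar_num(amplitude_photons, "amplitude_photons", lower = 0)
  assert_scalar_num(psf_sigma_px, "psf_sigma_px", lower = 1e-6)
  if (!is.null(pause_schedule)) {
    stopifnot(is.data.frame(pause_schedule),
              all(c("t_start", "duration") %in% names(pause_schedule)))
  }
  structure(list(
    initial_position_bp = initial_position_bp,
    velocity_bp_s = velocity_bp_s,
    velocity_noise_sd = velocity_noise_sd,
    pause_rate = pause_rate, pause_duration_mean = pause_duration_mean,
    pause_schedule = pause_schedule,
    dissociation_rate = dissociation_rate, stop_after_bp = stop_after_bp,
    initiates = isTRUE(initiates),
    blink_on_rate = blink_on_rate, blink_off_rate = blink_off_rate,
    amplitude_photons = amplitude_photons, psf_sigma_px = psf_sigma_px,
    attachment = match.arg(attachment)
  ), class = "motor_params")
}

#' Pixel-to-base-pair calibration map
#'
#' Projects drift-corrected (x, y) localizations onto the tether axis and
#' converts the axial distance from the anchor into base pairs. The anchor
#' projects to 0 bp by construction.
#'
#' @param anchor_px Numeric c(x, y) anchor position, 0-based pixels.
#' @param axis_direction Numeric c(dx, dy); normalized internally.
#' @param bp_per_px Base pairs per pixel (> 0).
#' @param total_bp Substrate length in bp.
#' @return An object of class `calibration_map`.
#' @seealso [dna_tether()]; [as_calibration_map()] converts a tether.
#' @export
calibration_map <- function(anchor_px, axis_direction, bp_per_px,
                            total_bp = 48502L) {
  stopifnot(length(anchor_px) == 2L, length(axis_direction) == 2L)
  assert_scalar_num(bp_per_px, "bp_per_px", lower = 1e-9)
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm < 1e-12) stop("'axis_direction' must be non-zero", call. = FALSE)
  structure(list(
    anchor_px = as.numeric(anchor_px),
    axis_direction = as.numeric(axis_direction) / nrm,
    bp_per_px = bp_per_px, total_bp = as.integer(total_bp)
  ), class = "calibration_map")
}

#' @rdname calibration_map
#' @param tether A [dna_tether()].
#' @export
as_calibration_map <- function(tether) {
  stopifnot(inherits(tether, "dna_tether"))
  calibration_map(tether$anchor_px, tether$axis_direction,
                  tether$bp_per_px, tether$total_bp)
}
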