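#' Detect candidate spots in a single frame
#'
#' Finds local intensity maxima whose background-subtracted peak exceeds
#' `min_snr` times a robust noise estimate (median absolute deviation of the
#' frame; spots are sparse outliers, so the MAD tracks the noise floor), then
#' applies non-maximum suppression within `min_separation_px`.
#'
#' @param frame Numeric 2D matrix of non-negative intensities.
#' @param min_snr Peak threshold in robust noise SDs above the frame median.
#' @param min_separation_px Minimum Euclidean distance between kept peaks.
#' @return data.frame with 0-based integer pixel coordinates `x_px` (column),
#'   `y_px` (row) and the raw `peak` intensity, strongest first.
#' @export
detect_spots <- function(frame, min_snr = 5, min_separation_px = 3) {
  if (!is.matrix(frame) || any(dim(frame) < 3) || anyNA(frame)) {
    stop("'frame' must be a 2D intensity matrix (>= 3x3, no NA)",
         call. = FALSE)
  }
  if (any(frame < 0)) stop("'frame' must be non-negative", call. = FALSE)
  bg <- stats::median(frame)
  noise_sd <- stats::mad(frame)
  thr <- bg + min_snr * max(noise_sd, 1e-12)
  nr <- nrow(frame); nc <- ncol(frame)
  # strict local maximum over the 8-neighborhood (interior pixels only)
  core <- frame[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- frame[2:(nr - 1) + dr, 2:(nc - 1) + dc]
    is_max <- is_max & (core > nb | (core == nb & (dr > 0 | (dr == 0 & dc > 0))))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(x_px = integer(0), y_px = integer(0),
                      peak = numeric(0)))
  }
  # interior index i maps to full-frame 1-based i+1, i.e. 0-based i
  cand <- data.frame(x_px = idx[, 2], y_px = idx[, 1], peak = core[idx])
  cand <- cand[order(-cand$peak, cand$y_px, cand$x_px), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    d2 <- (kept$x_px - cand$x_px[i])^2 + (kept$y_px - cand$y_px[i])^2
    keep[i] <- all(d2 >= min_separation_px^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

psf_model_window <- function(par, xs, ys) {
  gx <- stats::pnorm((xs + 0.5 - par[1]) / par[5]) -
        stats::pnorm((xs - 0.5 - par[1]) / par[5])
  gy <- stats::pnorm((ys + 0.5 - par[2]) / par[5]) -
        stats::pnorm((ys - 0.5 - par[2]) / par[5])
  par[4] + par[3] * (gy %o% gx)
}

#' Fit an integrated 2D Gaussian PSF in a window around a candidate
#'
#' Nonlinear least squares of an integrated symmetric 2D Gaussian (amplitude,
#' subpixel center, shared isotropic sigma) plus a constant background over a
#' `window_px` x `window_px` region. The production engine is a compiled
#' Levenberg-Marquardt solver; `engine = "r"` runs an independent
#' `stats::optim()` L-BFGS-B minimization of the same sum of squares and is
#' used as a cross-check in the test suite.
#'
#' @param frame Numeric 2D intensity matrix.
#' @param candidate_px Numeric c(x, y) candidate position, 0-based pixels.
#' @param window_px Odd window edge length; the window must lie fully inside
#'   the frame.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return One-row data.frame (a SpotDetection): `frame` (NA, filled by
#'   callers), `channel`, `x_px`, `y_px`, `amplitude`, `sigma_px`,
#'   `background`, `fit_rss`, `converged`.
#' @export
fit_psf <- function(frame, candidate_px, window_px = 9,
                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(frame), length(candidate_px) == 2L, window_px >= 5)
  half <- floor(window_px / 2)
  cx <- round(candidate_px[1]); cy <- round(candidate_px[2])
  nr <- nrow(frame); nc <- ncol(frame)
  if (cx - half < 0 || cx + half > nc - 1 ||
      cy - half < 0 || cy + half > nr - 1) {
    stop("fit window extends outside the frame", call. = FALSE)
  }
  rows <- (cy - half):(cy + half)   # 0-based
  cols <- (cx - half):(cx + half)
  win <- frame[rows + 1, cols + 1]
  if (stats::var(as.vector(win)) < 1e-24) {
    stop("singular (flat) fit window", call. = FALSE)
  }
  b0 <- min(win)
  wsub <- win - b0
  tot <- sum(wsub)
  x0 <- sum(t(wsub) * cols) / tot   # intensity centroid start
  y0 <- sum(wsub * rows) / tot
  start <- c(x0 = x0, y0 = y0, A = max(tot, max(wsub)), b = b0, s = 1.2)

  if (engine == "cpp") {
    fit <- .psf_fit_cpp(win, cols[1], rows[1], as.numeric(start))
    par <- c(fit$x0, fit$y0, fit$amplitude, fit$background, fit$sigma)
    rss <- fit$rss; conv <- isTRUE(fit$converged)
  } else {
    sse <- function(p) sum((win - psf_model_window(p, cols, rows))^2)
    op <- stats::optim(start, sse, method = "L-BFGS-B",
                       lower = c(cols[1], rows[1], 0, -Inf, 0.3),
                       upper = c(cols[length(cols)], rows[length(rows)],
                                 Inf, Inf, window_px / 2),
                       control = list(maxit = 500, factr = 1e4))
    par <- op$par; rss <- op$value; conv <- op$convergence == 0
  }
  data.frame(frame = NA_integer_, channel = NA_integer_,
             x_px = par[1], y_px = par[2], amplitude = par[3],
             sigma_px = par[5], background = par[4], fit_rss = rss,
             converged = conv)
}

#' Localize every frame of an image stack
#'
#' Runs [detect_spots()] and [fit_psf()] on each frame. Candidates too close
#' to the border for a full fit window are dropped.
#'
#' @param stack Array `[rows, cols, frames]`.
#' @param channel Integer channel label stored in the output.
#' @param min_snr,min_separation_px Passed to [detect_spots()].
#' @param window_px,engine Passed to [fit_psf()].
#' @return Detections data.frame, one row per fitted spot.
#' @export
localize_stack <- function(stack, channel = 0L, min_snr = 5,
                           min_separation_px = 3, window_px = 9,
                           engine = "cpp") {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  half <- floor(window_px / 2)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  out <- vector("list", dim(stack)[3])
  for (f in seq_len(dim(stack)[3])) {
    fr <- stack[, , f]
    cand <- detect_spots(fr, min_snr = min_snr,
                         min_separation_px = min_separation_px)
    if (!nrow(cand)) next
    ok <- cand$x_px - half >= 0 & cand$x_px + half <= nc - 1 &
          cand$y_px - half >= 0 & cand$y_px + half <= nr - 1
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    fits <- lapply(seq_len(nrow(cand)), function(i) {
      fit_psf(fr, c(cand$x_px[i], cand$y_px[i]), window_px = window_px,
              engine = engine)
    })
    det <- do.call(rbind, fits)
    det$frame <- f - 1L
    det$channel <- as.integer(channel)
    out[[f]] <- det
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(0), channel = integer(0),
                      x_px = numeric(0), y_px = numeric(0),
                      amplitude = numeric(0), sigma_px = numeric(0),
                      background = numeric(0), fit_rss = numeric(0),
                      converged = logical(0))
  }
  rownames(res) <- NULL
  res
}

#' Estimate stage drift from a tracked fiducial
#'
#' A stationary surface particle is localized in every frame; its offset
#' from its frame-0 position is the stage drift. Frames where the fiducial
#' was dark (blinking) are filled by linear interpolation; an optional
#' centered running-mean smooths localization noise. The series is re-zeroed
#' at frame 0 after smoothing so the frame-0 invariant holds exactly.
#'
#' @param fiducial_detections data.frame with `frame`, `x_px`, `y_px` for one
#'   fiducial (any extra columns ignored).
#' @param n_frames Total number of frames the drift series must cover.
#' @param smooth_window Odd running-mean width in frames; 1 disables.
#' @param min_coverage Minimum fraction of frames with a detection.
#' @return data.frame of class `drift_series`: `frame`, `dx_px`, `dy_px`.
#' @export
estimate_drift <- function(fiducial_detections, n_frames,
                           smooth_window = 5, min_coverage = 0.5) {
  d <- fiducial_detections
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(d)))
  d <- d[order(d$frame), , drop = FALSE]
  d <- d[!duplicated(d$frame), , drop = FALSE]
  if (nrow(d) < 2 || nrow(d) < min_coverage * n_frames) {
    stop(sprintf("fiducial detected in %d/%d frames; need >= %.0f%%",
                 nrow(d), n_frames, 100 * min_coverage), call. = FALSE)
  }
  frames <- 0:(n_frames - 1)
  x <- stats::approx(d$frame, d$x_px, xout = frames, rule = 2)$y
  y <- stats::approx(d$frame, d$y_px, xout = frames, rule = 2)$y
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- function(v) {
      s <- stats::filter(v, k, sides = 2)
      s[is.na(s)] <- v[is.na(s)]  # keep raw values at the edges
      as.numeric(s)
    }
    x <- sm(x); y <- sm(y)
  }
  out <- data.frame(frame = frames, dx_px = x - x[1], dy_px = y - y[1])
  class(out) <- c("drift_series", "data.frame")
  attr(out, "source_id") <- attr(fiducial_detections, "source_id")
  out
}

#' Subtract stage drift from detections
#'
#' @param detections Detections data.frame with `frame`, `x_px`, `y_px`.
#' @param drift A [estimate_drift()] result covering every detection frame.
#' @return Detections with drift-corrected coordinates.
#' @export
apply_drift <- function(detections, drift) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(detections)))
  i <- match(detections$frame, drift$frame)
  if (anyNA(i)) {
    stop("drift series does not cover all detection frames", call. = FALSE)
  }
  detections$x_px <- detections$x_px - drift$dx_px[i]
  detections$y_px <- detections$y_px - drift$dy_px[i]
  detections
}
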