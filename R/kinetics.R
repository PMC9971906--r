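# --- motile-span helpers ----------------------------------------------------

# Take-off point: displacement from the start exceeds the spatial resolution
# and never returns below it. Returns c(start_idx, end_idx) of the motile
# span (1-based into the trajectory rows), or NULL for a static trace.
# start_idx is the last sub-resolution frame (the take-off frame), end_idx
# the first frame attaining the maximum excursion.
motile_span <- function(pos, resolution_bp = 500) {
  d <- abs(pos - pos[1])
  if (max(d) < resolution_bp) return(NULL)
  below <- d < resolution_bp
  # suffix scan: first index from which displacement stays >= resolution
  cross <- length(pos)
  for (i in rev(seq_along(pos))) {
    if (below[i]) break
    cross <- i
  }
  start <- max(cross - 1L, 1L)
  end <- which.max(d)
  if (end <= start) return(NULL)
  c(start, end)
}

# Starting position for excursion measurements. A molecule with a static
# lead-in sits at its start position until take-off, and an immediately
# moving one has pos[1] at its start, so the first localization is an
# unbiased anchor in both regimes (a lead-in median would drag the anchor
# into the sub-resolution early motion).
start_position <- function(pos, resolution_bp = 500) {
  pos[1]
}

ols_slope <- function(t, p) {
  n <- length(t)
  tm <- t - mean(t); pm <- p - mean(p)
  stt <- sum(tm^2)
  slope <- sum(tm * pm) / stt
  res <- pm - slope * tm
  se <- if (n > 2) sqrt(sum(res^2) / (n - 2) / stt) else NA_real_
  c(slope = slope, se = se)
}

#' Translocation velocity of one trajectory
#'
#' Ordinary least-squares slope of position versus time over the motile span
#' (from the take-off frame to the frame of maximum excursion), as a single
#' line fit per molecule. Pauses are included in the fit by default; pass
#' `exclude_pauses = TRUE` together with a pause table to fit only the
#' motile segments (a diagnostic mode). The sign convention is movement away
#' from the starting position is positive, so resection velocities are
#' positive regardless of tether orientation.
#'
#' @param traj One molecule's calibrated trajectory (`time_s`,
#'   `position_bp`), frames strictly increasing.
#' @param resolution_bp Spatial resolution used to find the motile span.
#' @param exclude_pauses Logical; drop frames inside `pauses`.
#' @param pauses Optional [detect_pauses()] table used when
#'   `exclude_pauses = TRUE`.
#' @return c(velocity_bp_s, stderr).
#' @export
compute_velocity <- function(traj, resolution_bp = 500,
                             exclude_pauses = FALSE, pauses = NULL) {
  stopifnot(all(c("time_s", "position_bp") %in% names(traj)))
  if (nrow(traj) < 5) stop("need >= 5 points for a velocity fit",
                           call. = FALSE)
  pos <- traj$position_bp; tt <- traj$time_s
  sp <- motile_span(pos, resolution_bp)
  idx <- if (is.null(sp)) seq_along(pos) else sp[1]:sp[2]
  if (exclude_pauses && !is.null(pauses) && nrow(pauses)) {
    keep <- rep(TRUE, length(idx))
    for (i in seq_len(nrow(pauses))) {
      keep <- keep & !(tt[idx] >= pauses$t_start[i] &
                         tt[idx] <= pauses$t_end[i])
    }
    if (sum(keep) >= 5) idx <- idx[keep]
  }
  if (length(idx) < 2) return(c(velocity_bp_s = 0, stderr = NA_real_))
  fit <- ols_slope(tt[idx], pos[idx])
  sgn <- sign(pos[idx[length(idx)]] - pos[idx[1]])
  if (sgn == 0) sgn <- 1
  c(velocity_bp_s = unname(fit["slope"]) * sgn, stderr = unname(fit["se"]))
}

#' Processivity of one trajectory
#'
#' Distance traveled along the DNA, in kb: the maximum absolute excursion of
#' the trajectory from its starting position (median of the pre-motion
#' segment). Net displacement is the default because these motors are
#' unidirectional; `mode = "path"` instead sums |steps| (total path length),
#' which over-counts localization noise and is provided as a diagnostic.
#'
#' @inheritParams compute_velocity
#' @param mode `"net"` (default) or `"path"`.
#' @return Processivity in kb (>= 0).
#' @export
compute_processivity <- function(traj, resolution_bp = 500,
                                 mode = c("net", "path")) {
  mode <- match.arg(mode)
  pos <- traj$position_bp
  if (mode == "path") return(sum(abs(diff(pos))) / 1000)
  p0 <- start_position(pos, resolution_bp)
  max(abs(pos - p0)) / 1000
}

#' Detect pauses in a translocating trajectory
#'
#' A pause is an interval of at least `min_pause_duration_s` during which a
#' translocating molecule shows no net movement beyond the spatial
#' resolution. Frames are classified by a sliding local velocity (OLS slope
#' over a window of `min_pause_duration_s`); a frame is pause-flagged when
#' its local speed falls below 45% of the molecule's own motile-span speed.
#' Flagged runs separated by sub-resolution gaps (shorter than half a
#' window) are merged; a run is emitted as a pause iff it lasts at least
#' `min_pause_duration_s`, its net displacement stays below
#' `resolution_bp`, and that displacement is clearly smaller than continued
#' translocation would have produced. Pre- and post-pause velocities are
#' OLS fits on the flanking motile segments.
#'
#' The threshold is adaptive (relative to each molecule's own velocity)
#' rather than absolute, because at typical resection speeds a 30 s window
#' displaces less than the ~500 bp resolution, so an absolute dwell rule
#' cannot separate slow movers from true stalls.
#'
#' @inheritParams compute_velocity
#' @param min_pause_duration_s Minimum pause duration (default 30 s).
#' @return data.frame of pause events: `t_start`, `t_end`, `duration`,
#'   `position_bp`, `prepause_velocity`, `postpause_velocity`. Attribute
#'   `short_trace` is TRUE when the trajectory is shorter than the minimum
#'   pause duration.
#' @export
detect_pauses <- function(traj, resolution_bp = 500,
                          min_pause_duration_s = 30) {
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), position_bp = numeric(0),
                      prepause_velocity = numeric(0),
                      postpause_velocity = numeric(0))
  stopifnot(all(c("time_s", "position_bp") %in% names(traj)))
  tt <- traj$time_s; pos <- traj$position_bp
  n <- length(tt)
  if (n < 3 || (tt[n] - tt[1]) < min_pause_duration_s) {
    attr(empty, "short_trace") <- TRUE
    return(empty)
  }
  attr(empty, "short_trace") <- FALSE
  sp <- motile_span(pos, resolution_bp)
  if (is.null(sp)) return(empty)
  idx <- sp[1]:sp[2]
  ts <- tt[idx]; ps <- pos[idx]
  m <- length(idx)
  dt <- stats::median(diff(ts))
  w <- max(5L, round(min_pause_duration_s / dt))     # window, frames
  h <- floor(w / 2)
  if (m < w + 2) return(empty)

  vg <- abs(ols_slope(ts, ps)["slope"])              # molecule's own speed
  vcut <- 0.45 * vg
  centers <- (h + 1):(m - h)
  vloc <- vapply(centers, function(c0) {
    ols_slope(ts[(c0 - h):(c0 + h)], ps[(c0 - h):(c0 + h)])["slope"]
  }, numeric(1))
  flag <- abs(vloc) < vcut
  if (!any(flag)) return(empty)

  # runs of flagged centers; noise can briefly lift the local slope above
  # threshold inside a genuine stall, so near-adjacent runs are merged
  # a gap shorter than w/2 windows of apparent motion is sub-resolution
  # (at threshold speed it covers < resolution_bp), so it cannot witness a
  # genuine resumption of translocation between two stalls
  merge_gap <- max(3L, ceiling(w / 2))
  r <- rle(flag)
  if (length(r$lengths) > 2) {
    short_gap <- !r$values & r$lengths < merge_gap
    short_gap[1] <- FALSE; short_gap[length(short_gap)] <- FALSE
    r$values[short_gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    c1 <- centers[starts[k]]; c2 <- centers[ends[k]]
    # a window centered exactly on a pause boundary sits at the threshold,
    # so the flagged run starts one frame inside the pause on each side
    t1 <- max(ts[c1] - dt, ts[1])
    t2 <- min(ts[c2] + dt, ts[m])
    dur <- t2 - t1
    if (dur < min_pause_duration_s) next
    # net displacement across the run (noise-robust 3-frame endpoints):
    # a stall must stay sub-resolution AND move clearly less than the
    # molecule's own continued translocation would have (otherwise a noisy
    # slow mover chains false flags into a "pause" while still advancing)
    p_lo <- stats::median(ps[max(c1 - 2, 1):c1])
    p_hi <- stats::median(ps[c2:min(c2 + 2, m)])
    disp <- abs(p_hi - p_lo)
    if (disp >= resolution_bp) next
    if (disp >= 0.5 * vg * dur) next
    pre_idx <- 1:max(c1 - 1, 1)
    post_idx <- min(c2 + 1, m):m
    prev <- if (length(pre_idx) >= 3)
      unname(ols_slope(ts[pre_idx], ps[pre_idx])["slope"]) else NA_real_
    postv <- if (length(post_idx) >= 3)
      unname(ols_slope(ts[post_idx], ps[post_idx])["slope"]) else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      t_start = t1, t_end = t2, duration = dur,
      position_bp = stats::median(ps[c1:c2]),
      prepause_velocity = prev, postpause_velocity = postv)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$t_start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "short_trace") <- FALSE
  res
}

#' Per-molecule kinetics for a set of trajectories
#'
#' Convenience wrapper: computes velocity, processivity, pauses, bound
#' lifetime and a dissociation flag for every translocating molecule, and
#' bound lifetimes for static ones.
#'
#' @param traj Calibrated trajectories data.frame (`molecule_id`, `frame`,
#'   `time_s`, `position_bp`).
#' @param translocating_ids Molecule ids from [movement_filter()].
#' @param n_frames Total movie frames (for censoring: a molecule whose last
#'   detection lies within `censor_slack_frames` of the movie end is treated
#'   as still bound).
#' @param frame_interval Seconds per frame.
#' @param resolution_bp,min_pause_duration_s Passed to [detect_pauses()].
#' @param censor_slack_frames Frames of slack at the movie end.
#' @return List with `kinetics` (one row per molecule: `molecule_id`,
#'   `velocity_bp_s`, `velocity_stderr`, `processivity_kb`, `n_pauses`,
#'   `bound_lifetime_s`, `censored`, `dissociated_within_horizon`,
#'   `translocating`) and `pauses` (one row per pause event with
#'   `molecule_id`).
#' @export
analyze_trajectories <- function(traj, translocating_ids, n_frames,
                                 frame_interval = 2, resolution_bp = 500,
                                 min_pause_duration_s = 30,
                                 censor_slack_frames = 10) {
  ids <- unique(traj$molecule_id)
  kin <- list(); pev <- list()
  for (id in ids) {
    tr <- traj[traj$molecule_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    lifetime <- (max(tr$frame) - min(tr$frame) + 1L) * frame_interval
    censored <- max(tr$frame) >= n_frames - 1L - censor_slack_frames
    moving <- id %in% translocating_ids
    v <- c(NA_real_, NA_real_); pk <- NA_real_; np <- 0L
    if (moving && nrow(tr) >= 5) {
      pz <- detect_pauses(tr, resolution_bp, min_pause_duration_s)
      v <- compute_velocity(tr, resolution_bp)
      pk <- compute_processivity(tr, resolution_bp)
      np <- nrow(pz)
      if (np) pev[[length(pev) + 1L]] <- cbind(molecule_id = id, pz)
    }
    kin[[length(kin) + 1L]] <- data.frame(
      molecule_id = id, velocity_bp_s = unname(v[1]),
      velocity_stderr = unname(v[2]),
      processivity_kb = pk, n_pauses = np, bound_lifetime_s = lifetime,
      censored = censored,
      dissociated_within_horizon = !censored,
      translocating = moving)
  }
  list(kinetics = do.call(rbind, kin),
       pauses = if (length(pev)) do.call(rbind, pev) else
         data.frame(molecule_id = integer(0), t_start = numeric(0),
                    t_end = numeric(0), duration = numeric(0),
                    position_bp = numeric(0),
                    prepause_velocity = numeric(0),
                    postpause_velocity = numeric(0)))
}

#' Pause fractions over a cohort
#'
#' @param kinetics The `kinetics` table from [analyze_trajectories()] (or
#'   any data.frame with `n_pauses` and `translocating`).
#' @return List with `fractions` (no_pause, ge1_pause, ge2_pause), `counts`
#'   and `n`.
#' @export
pause_summary <- function(kinetics) {
  k <- kinetics[kinetics$translocating, , drop = FALSE]
  if (!nrow(k)) stop("no translocating molecules", call. = FALSE)
  n <- nrow(k)
  counts <- c(no_pause = sum(k$n_pauses == 0),
              ge1_pause = sum(k$n_pauses >= 1),
              ge2_pause = sum(k$n_pauses >= 2))
  list(fractions = counts / n, counts = counts, n = n)
}

#' Fit a single-exponential decay to bound lifetimes
#'
#' Builds the empirical survival curve S(t) (Kaplan-Meier, so right-censored
#' molecules -- still bound at the movie end -- contribute at-risk time) and
#' fits S(t) = exp(-k t). The default `"loglinear"` method is least squares
#' of log S on t through the origin over points with S > 0 (for two
#' uncensored lifetimes this reduces to the closed form
#' k = -sum(t log S) / sum(t^2)); `"nls"` fits exp(-k t) to S(t) directly;
#' `"mle"` is the censoring-aware exponential maximum-likelihood rate
#' (events / total observed time).
#'
#' @param lifetimes Numeric bound lifetimes in seconds.
#' @param censored Logical; TRUE where the molecule was still bound at the
#'   end of observation.
#' @param method `"loglinear"`, `"nls"` or `"mle"`.
#' @return An object of class `survival_fit`: list with `k` (1/s),
#'   `half_life_s`, `method`, `n`, `n_censored`, `curve` (data.frame
#'   time, surv).
#' @export
fit_survival <- function(lifetimes, censored = rep(FALSE, length(lifetimes)),
                         method = c("loglinear", "nls", "mle")) {
  method <- match.arg(method)
  stopifnot(length(lifetimes) == length(censored))
  if (all(censored)) stop("all lifetimes are censored", call. = FALSE)
  if (sum(!censored) < 2 && method != "mle") {
    stop("need >= 2 uncensored lifetimes", call. = FALSE)
  }
  sf <- survival::survfit(survival::Surv(lifetimes, !censored) ~ 1)
  curve <- data.frame(time = sf$time, surv = sf$surv)
  k <- switch(method,
    loglinear = {
      pts <- curve[curve$surv > 0 & curve$time > 0, , drop = FALSE]
      if (!nrow(pts)) stop("degenerate survival curve", call. = FALSE)
      -sum(pts$time * log(pts$surv)) / sum(pts$time^2)
    },
    nls = {
      k0 <- {
        pts <- curve[curve$surv > 0 & curve$time > 0, , drop = FALSE]
        max(-sum(pts$time * log(pts$surv)) / sum(pts$time^2), 1e-8)
      }
      fit <- stats::nls(surv ~ exp(-k * time), data = curve,
                        start = list(k = k0),
                        control = stats::nls.control(warnOnly = TRUE))
      unname(stats::coef(fit)["k"])
    },
    mle = sum(!censored) / sum(lifetimes)
  )
  if (!is.finite(k) || k <= 0) stop("survival fit produced k <= 0",
                                    call. = FALSE)
  structure(list(k = k, half_life_s = log(2) / k, method = method,
                 n = length(lifetimes), n_censored = sum(censored),
                 curve = curve), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf(
    "<survival_fit> k = %.4g /s (half-life %.4g s), %s fit, n = %d (%d censored)\n",
    x$k, x$half_life_s, x$method, x$n, x$n_censored))
  invisible(x)
}

#' Fraction of molecules dissociating within an observation horizon
#'
#' @param lifetimes Numeric bound lifetimes (s), or a kinetics table with a
#'   `bound_lifetime_s` column.
#' @param horizon_s Observation horizon in seconds (default 1800 s = the
#'   30 min experiment).
#' @param n_boot,seed Bootstrap replicates and seed for the SD.
#' @return List with `fraction`, `sd` (bootstrap), `n`.
#' @export
dissociation_fraction <- function(lifetimes, horizon_s = 1800,
                                  n_boot = 1000, seed = 1L) {
  if (is.data.frame(lifetimes)) lifetimes <- lifetimes$bound_lifetime_s
  if (!length(lifetimes)) stop("no lifetimes", call. = FALSE)
  flags <- as.integer(lifetimes < horizon_s)
  bs <- bootstrap_fraction(flags, n_boot = n_boot, seed = seed)
  list(fraction = bs$fraction, sd = bs$sd, n = length(flags))
}
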