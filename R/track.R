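#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbor frame-to-frame assignment: within each frame,
#' candidate (track, detection) pairs are considered in order of increasing
#' distance and accepted while the per-frame-step distance does not exceed
#' `max_step_px` (a track dark for `g` frames may move up to
#' `g * max_step_px`). Tracks may bridge up to `max_gap_frames` dark frames
#' (quantum-dot blinks); unmatched detections seed new trajectories.
#' Molecules on curtains are sparse and well separated, so greedy assignment
#' is adequate; the test suite bounds its error against ground-truth
#' identities.
#'
#' @param detections Drift-corrected single-channel detections data.frame
#'   (`frame`, `x_px`, `y_px`, other columns carried through).
#' @param max_step_px Maximum per-frame-step movement in pixels.
#' @param max_gap_frames Maximum bridged dark gap in frames.
#' @return The detections with a `molecule_id` column and a `bridged_gap`
#'   flag (TRUE on the first detection after a dark gap), ordered by
#'   (molecule_id, frame). Gap records are in `attr(, "gaps")`
#'   (molecule_id, from_frame, to_frame).
#' @export
link_detections <- function(detections, max_step_px = 3,
                            max_gap_frames = 10) {
  need <- c("frame", "x_px", "y_px")
  stopifnot(all(need %in% names(detections)))
  det <- detections[order(detections$frame, detections$x_px,
                          detections$y_px), , drop = FALSE]
  n <- nrow(det)
  det$molecule_id <- rep(NA_integer_, n)
  det$bridged_gap <- rep(FALSE, n)
  if (n == 0) {
    attr(det, "gaps") <- data.frame(molecule_id = integer(0),
                                    from_frame = integer(0),
                                    to_frame = integer(0))
    return(det)
  }
  # active track state
  tr_id <- integer(0); tr_x <- numeric(0); tr_y <- numeric(0)
  tr_frame <- integer(0)
  next_id <- 1L
  gaps <- list()
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    live <- which(f - tr_frame >= 1 & f - tr_frame <= max_gap_frames + 1)
    if (length(live) && length(rows)) {
      g <- f - tr_frame[live]
      dx <- outer(tr_x[live], det$x_px[rows], "-")
      dy <- outer(tr_y[live], det$y_px[rows], "-")
      dist <- sqrt(dx^2 + dy^2)
      lim <- g * max_step_px
      cand <- which(dist <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand], tr_id[live][cand[, 1]],
                     det$x_px[rows][cand[, 2]], det$y_px[rows][cand[, 2]])
        used_t <- logical(length(live)); used_d <- logical(length(rows))
        for (k in ord) {
          ti <- cand[k, 1]; di <- cand[k, 2]
          if (used_t[ti] || used_d[di]) next
          used_t[ti] <- TRUE; used_d[di] <- TRUE
          r <- rows[di]
          det$molecule_id[r] <- tr_id[live[ti]]
          if (g[ti] > 1L) {
            det$bridged_gap[r] <- TRUE
            gaps[[length(gaps) + 1L]] <- data.frame(
              molecule_id = tr_id[live[ti]],
              from_frame = tr_frame[live[ti]], to_frame = f)
          }
          tr_x[live[ti]] <- det$x_px[r]
          tr_y[live[ti]] <- det$y_px[r]
          tr_frame[live[ti]] <- f
        }
      }
    }
    # unmatched detections start new tracks
    for (r in rows[is.na(det$molecule_id[rows])]) {
      det$molecule_id[r] <- next_id
      tr_id <- c(tr_id, next_id); tr_x <- c(tr_x, det$x_px[r])
      tr_y <- c(tr_y, det$y_px[r]); tr_frame <- c(tr_frame, f)
      next_id <- next_id + 1L
    }
  }
  det <- det[order(det$molecule_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  attr(det, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(molecule_id = integer(0), from_frame = integer(0),
               to_frame = integer(0))
  det
}

#' Calibrate trajectories from pixels to base pairs
#'
#' Projects each (x, y) localization onto the tether axis and converts the
#' axial distance from the anchor to base pairs; adds `time_s` from the
#' frame interval. Positions outside `[0, total_bp]` are clipped and
#' flagged.
#'
#' @param traj Linked detections data.frame (`molecule_id`, `frame`, `x_px`,
#'   `y_px`).
#' @param cal A [calibration_map()] (or [dna_tether()], converted).
#' @param frame_interval Seconds per frame.
#' @return `traj` with `time_s`, `position_bp`, `out_of_range` columns.
#' @export
calibrate <- function(traj, cal, frame_interval = 2) {
  if (inherits(cal, "dna_tether")) cal <- as_calibration_map(cal)
  stopifnot(inherits(cal, "calibration_map"),
            all(c("frame", "x_px", "y_px") %in% names(traj)))
  s_px <- (traj$x_px - cal$anchor_px[1]) * cal$axis_direction[1] +
          (traj$y_px - cal$anchor_px[2]) * cal$axis_direction[2]
  pos <- s_px * cal$bp_per_px
  traj$time_s <- traj$frame * frame_interval
  traj$out_of_range <- pos < 0 | pos > cal$total_bp
  traj$position_bp <- clamp(pos, 0, cal$total_bp)
  traj
}

#' Partition trajectories by flow-stop recoil
#'
#' When buffer flow is halted, DNA tethers recoil toward the anchor and so do
#' all DNA-bound proteins, while surface-stuck particles stay put. A
#' molecule is retained iff its mean axial position during the flow-stop
#' window moves toward the anchor by at least `recoil_threshold_bp` relative
#' to the adjacent flowing frames (windows of equal length before and after
#' the stop). Molecules with no localizations inside the window cannot be
#' assessed and are excluded.
#'
#' Because the recoil jump far exceeds any linking step limit, trajectories
#' usually do not span the stop window themselves. If `stop_detections` is
#' given (raw localizations made during the window, not linked), molecules
#' without in-window frames are assessed by matching stop-window detections
#' on the same tether (within `row_tol_px` transversally) and measuring
#' their axial displacement.
#'
#' @param traj Calibrated trajectories data.frame (`molecule_id`, `frame`,
#'   `position_bp`).
#' @param flow_stop Integer c(start_frame, end_frame), 0-based inclusive.
#' @param recoil_threshold_bp Minimum recoil amplitude in bp.
#' @param stop_detections Optional data.frame of detections during the stop
#'   window (`frame`, `x_px`, `y_px`), for molecules whose own track does
#'   not cover it.
#' @param cal [calibration_map()], required with `stop_detections`.
#' @param row_tol_px Transverse matching tolerance in pixels.
#' @return List with `retained`, `excluded` (molecule id vectors) and
#'   `table` (per-molecule recoil summary).
#' @export
flow_stop_filter <- function(traj, flow_stop, recoil_threshold_bp = 2000,
                             stop_detections = NULL, cal = NULL,
                             row_tol_px = 4) {
  if (is.null(flow_stop) || length(flow_stop) != 2L ||
      flow_stop[2] < flow_stop[1]) {
    stop(paste("no valid flow-stop window; if the acquisition had no flow",
               "stop, skip this filter explicitly"), call. = FALSE)
  }
  stopifnot(all(c("molecule_id", "frame", "position_bp") %in% names(traj)))
  len <- flow_stop[2] - flow_stop[1] + 1L
  pre <- c(flow_stop[1] - len, flow_stop[1] - 1L)
  post <- c(flow_stop[2] + 1L, flow_stop[2] + len)
  if (!is.null(stop_detections) && nrow(stop_detections)) {
    if (is.null(cal)) {
      stop("'cal' is required with 'stop_detections'", call. = FALSE)
    }
    stop_detections <- calibrate(stop_detections, cal)
  }
  ids <- unique(traj$molecule_id)
  rows <- lapply(ids, function(id) {
    tr <- traj[traj$molecule_id == id, ]
    instop <- tr$position_bp[tr$frame >= flow_stop[1] &
                               tr$frame <= flow_stop[2]]
    adjacent <- tr$position_bp[(tr$frame >= pre[1] & tr$frame <= pre[2]) |
                                 (tr$frame >= post[1] & tr$frame <= post[2])]
    if (!length(adjacent)) {
      # no flowing frames next to the window: widen to the nearest frames
      near <- tr[order(pmin(abs(tr$frame - flow_stop[1]),
                            abs(tr$frame - flow_stop[2]))), ]
      adjacent <- utils::head(near$position_bp, len)
    }
    if (!length(instop) && !is.null(stop_detections) &&
        nrow(stop_detections)) {
      y0 <- stats::median(tr$y_px %||% NA_real_)
      if (is.finite(y0)) {
        sd_rows <- stop_detections[abs(stop_detections$y_px - y0) <=
                                     row_tol_px, ]
        instop <- sd_rows$position_bp
      }
    }
    if (!length(instop) || !length(adjacent)) {
      return(data.frame(molecule_id = id, recoil_bp = NA_real_,
                        retained = FALSE))
    }
    recoil <- mean(adjacent) - mean(instop)  # positive = toward anchor
    data.frame(molecule_id = id, recoil_bp = recoil,
               retained = recoil >= recoil_threshold_bp)
  })
  tab <- do.call(rbind, rows)
  list(retained = tab$molecule_id[tab$retained],
       excluded = tab$molecule_id[!tab$retained],
       table = tab)
}

#' Partition trajectories into translocating and static
#'
#' A molecule is translocating iff its maximum absolute displacement from
#' its starting position reaches `min_displacement_bp` (inclusive at the
#' boundary). Distances below ~1 kb approach the assay's spatial resolution
#' (~500 bp) and are not analyzed kinetically; static molecules are kept for
#' initiation-fraction denominators.
#'
#' @param traj Calibrated trajectories data.frame.
#' @param min_displacement_bp Inclusive displacement threshold, bp.
#' @return List with `translocating`, `static` (id vectors) and `table`
#'   (per-molecule displacement).
#' @export
movement_filter <- function(traj, min_displacement_bp = 1000) {
  stopifnot(all(c("molecule_id", "position_bp") %in% names(traj)))
  ids <- unique(traj$molecule_id)
  disp <- vapply(ids, function(id) {
    p <- traj$position_bp[traj$molecule_id == id]
    max(abs(p - p[1]))
  }, numeric(1))
  tab <- data.frame(molecule_id = ids, displacement_bp = disp,
                    translocating = disp >= min_displacement_bp)
  list(translocating = ids[tab$translocating],
       static = ids[!tab$translocating],
       table = tab)
}
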