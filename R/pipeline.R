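#' Run the full simulate -> localize -> track -> analyze -> stats pipeline
#'
#' Orchestrates a reproducible run from a single configuration (a nested
#' list, or a path to a JSON file with the same structure). Each stage
#' writes its outputs under `out_dir` and can be re-run from the
#' intermediates of an earlier run; a manifest records the config snapshot,
#' seeds, file hashes and per-stage molecule counts.
#'
#' Config blocks (all optional except `stages`): `simulate`
#' (n_molecules, velocity_mean, velocity_sd, processivity_mean_kb,
#' processivity_sd_kb, initiation_fraction, pause_rate, n_frames, ...),
#' `localize` (min_snr, min_separation_px, window_px), `track`
#' (max_step_px, max_gap_frames, min_displacement_bp, flow_stop,
#' recoil_threshold_bp), `analyze` (resolution_bp, min_pause_duration_s,
#' exclude_pauses), `stats` (condition, horizon_s, n_boot).
#'
#' @param config Nested list or JSON file path.
#' @param out_dir Output directory.
#' @param seed Master seed; stage seeds are derived from it.
#' @return Invisibly, a list with the stage outputs and `manifest` path.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  stages <- config$stages %||%
    c("simulate", "localize", "track", "analyze", "stats")
  known <- c("simulate", "localize", "track", "analyze", "stats")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  deps <- list(localize = "simulate", track = "localize",
               analyze = "track", stats = "analyze")
  have_file <- function(f) file.exists(file.path(out_dir, f))
  prereq_out <- c(simulate = "truth.csv", localize = "detections.csv",
                  track = "trajectories.csv", analyze = "kinetics.csv")
  for (st in stages) {
    d <- deps[[st]]
    if (!is.null(d) && !(d %in% stages) && !have_file(prereq_out[[d]])) {
      stop(sprintf(
        "config error at stages: stage '%s' requires stage '%s' (or its output %s)",
        st, d, prereq_out[[d]]), call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  out <- list()

  acq_from_cfg <- function(sc) {
    acquisition_config(
      frame_interval = sc$frame_interval %||% 2,
      exposure = sc$exposure %||% 0.2,
      n_frames = sc$n_frames %||% 450,
      flow_stop = sc$flow_stop,
      background = sc$background %||% 200,
      read_noise_sd = sc$read_noise_sd %||% 10)
  }

  if ("simulate" %in% stages) {
    sc <- config$simulate %||% list()
    acq <- acq_from_cfg(sc)
    sim <- simulate_cohort(
      n_molecules = sc$n_molecules %||% 10, acq = acq,
      velocity_mean = sc$velocity_mean %||% 18,
      velocity_sd = sc$velocity_sd %||% 11,
      processivity_mean_kb = sc$processivity_mean_kb %||% 18,
      processivity_sd_kb = sc$processivity_sd_kb %||% 6,
      initiation_fraction = sc$initiation_fraction %||% 1,
      pause_rate = sc$pause_rate %||% 0,
      pause_duration_mean = sc$pause_duration_mean %||% 60,
      seed = derive_seed(seed, "simulate"))
    for (s in seq_along(sim$stacks)) {
      write_tiff16(sim$stacks[[s]]$stacks[[1]],
                   file.path(out_dir, sprintf("stack_%02d_c0.tif", s)))
    }
    truth <- do.call(rbind, lapply(sim$stacks, `[[`, "truth"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_stacks = length(sim$stacks),
           n_frames = acq$n_frames, frame_interval = acq$frame_interval,
           fiducial_roi = as.list(sim$fiducial_roi),
           row_spacing_px = sim$row_spacing_px,
           bp_per_px = sim$calibration$bp_per_px,
           anchor_px = sim$calibration$anchor_px,
           axis_direction = sim$calibration$axis_direction,
           flow_stop = acq$flow_stop),
      file.path(out_dir, "sim.json"), auto_unbox = TRUE, digits = NA)
    counts$simulate <- nrow(sim$truth_params)
    out$sim <- sim
  }

  meta <- jsonlite::read_json(file.path(out_dir, "sim.json"),
                              simplifyVector = TRUE)

  if ("localize" %in% stages) {
    lc <- config$localize %||% list()
    dets <- list()
    for (s in seq_len(meta$n_stacks)) {
      stack <- read_tiff16(file.path(out_dir,
                                     sprintf("stack_%02d_c0.tif", s)))
      d <- localize_stack(stack, channel = 0L,
                          min_snr = lc$min_snr %||% 5,
                          min_separation_px = lc$min_separation_px %||% 3,
                          window_px = lc$window_px %||% 9)
      d$stack <- s
      dets[[s]] <- d
    }
    det <- do.call(rbind, dets)
    utils::write.csv(det, file.path(out_dir, "detections.csv"),
                     row.names = FALSE)
    counts$localize <- nrow(det)
    out$detections <- det
  }

  if ("track" %in% stages) {
    tc <- config$track %||% list()
    det <- utils::read.csv(file.path(out_dir, "detections.csv"))
    roi <- unlist(meta$fiducial_roi)
    cal <- calibration_map(meta$anchor_px, meta$axis_direction,
                           meta$bp_per_px)
    fs <- tc$flow_stop %||% meta$flow_stop
    if (!length(fs)) fs <- NULL  # JSON null round-trips as empty list
    fs <- unlist(fs)
    trajs <- list(); stop_dets <- list()
    id_offset <- 0L
    for (s in unique(det$stack)) {
      ds <- det[det$stack == s, ]
      fid <- ds[ds$x_px >= roi["x"] & ds$x_px < roi["x"] + roi["w"] &
                  ds$y_px >= roi["y"] & ds$y_px < roi["y"] + roi["h"], ]
      drift <- estimate_drift(fid, n_frames = meta$n_frames)
      ds <- apply_drift(ds, drift)
      ds <- ds[!(ds$y_px >= roi["y"] - 1 & ds$y_px < roi["y"] + roi["h"]), ]
      if (!is.null(fs)) {
        # stop-window localizations are the recoil control, not track data
        in_stop <- ds$frame >= fs[1] & ds$frame <= fs[2]
        sd_s <- ds[in_stop, ]
        sd_s$stack <- s
        stop_dets[[length(stop_dets) + 1L]] <- sd_s
        ds <- ds[!in_stop, ]
      }
      linked <- link_detections(ds, max_step_px = tc$max_step_px %||% 3,
                                max_gap_frames = tc$max_gap_frames %||% 10)
      if (!nrow(linked)) next
      linked$molecule_id <- linked$molecule_id + id_offset
      linked$stack <- s
      id_offset <- max(linked$molecule_id)
      trajs[[length(trajs) + 1L]] <-
        calibrate(linked, cal, frame_interval = meta$frame_interval)
    }
    traj <- do.call(rbind, trajs)
    nfr <- table(traj$molecule_id)
    traj <- traj[traj$molecule_id %in%
                   names(nfr)[nfr >= (tc$min_track_frames %||% 20)], ]
    if (!is.null(fs)) {
      retained <- character(0)
      for (s in unique(traj$stack)) {
        sds <- do.call(rbind, stop_dets)
        part <- flow_stop_filter(traj[traj$stack == s, ], fs,
                                 tc$recoil_threshold_bp %||% 2000,
                                 stop_detections = sds[sds$stack == s, ],
                                 cal = cal)
        retained <- c(retained, part$retained)
      }
      traj <- traj[traj$molecule_id %in% retained, ]
    }
    mf <- movement_filter(traj, tc$min_displacement_bp %||% 1000)
    utils::write.csv(traj, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(translocating = mf$translocating, static = mf$static),
      file.path(out_dir, "partition.json"), digits = NA)
    counts$track <- length(unique(traj$molecule_id))
    out$traj <- traj
  }

  if ("analyze" %in% stages) {
    ac <- config$analyze %||% list()
    traj <- utils::read.csv(file.path(out_dir, "trajectories.csv"))
    part <- jsonlite::read_json(file.path(out_dir, "partition.json"),
                                simplifyVector = TRUE)
    res <- analyze_trajectories(
      traj, part$translocating, n_frames = meta$n_frames,
      frame_interval = meta$frame_interval,
      resolution_bp = ac$resolution_bp %||% 500,
      min_pause_duration_s = ac$min_pause_duration_s %||% 30)
    utils::write.csv(res$kinetics, file.path(out_dir, "kinetics.csv"),
                     row.names = FALSE)
    utils::write.csv(res$pauses, file.path(out_dir, "pauses.csv"),
                     row.names = FALSE)
    lt <- res$kinetics
    if (sum(!lt$censored) >= 2) {
      sfit <- fit_survival(lt$bound_lifetime_s, lt$censored)
      jsonlite::write_json(
        list(k_per_s = sfit$k, half_life_s = sfit$half_life_s,
             method = sfit$method, n = sfit$n,
             n_censored = sfit$n_censored),
        file.path(out_dir, "survival.json"), auto_unbox = TRUE,
        digits = NA)
    }
    counts$analyze <- nrow(res$kinetics)
    out$kinetics <- res$kinetics
    out$pauses <- res$pauses
  }

  if ("stats" %in% stages) {
    stc <- config$stats %||% list()
    kin <- utils::read.csv(file.path(out_dir, "kinetics.csv"))
    summ <- cohort_summary(kin, condition = stc$condition %||% "synthetic",
                           horizon_s = stc$horizon_s %||% 1800,
                           n_boot = stc$n_boot %||% 1000,
                           seed = derive_seed(seed, "stats"))
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    counts$stats <- summ$n_molecules
    out$summary <- summ
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("curtaintrack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, stages = stages, config = config,
    molecule_counts = counts,
    files = lapply(stats::setNames(files, basename(files)), tools::md5sum))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out$manifest <- manifest_path
  invisible(out)
}

#' Validate pipeline input/output files
#'
#' Structural checks: TIFF readability, expected CSV columns, 0-based
#' non-negative frames, and base-pair coordinates within `[0, total_bp]`.
#' Violations are reported, not raised.
#'
#' @param files Character vector of file paths.
#' @param total_bp Substrate length for coordinate-range checks.
#' @return data.frame report: `file`, `check`, `ok`, `message`.
#' @export
validate_io <- function(files, total_bp = 48502) {
  rows <- list()
  add <- function(f, check, ok, msg = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = basename(f), check = check, ok = ok, message = msg)
  }
  schemas <- list(
    detections = c("frame", "x_px", "y_px", "amplitude", "sigma_px",
                   "background", "fit_rss", "converged"),
    trajectories = c("molecule_id", "frame", "time_s", "position_bp",
                     "x_px", "y_px"),
    truth = c("molecule_id", "frame", "time_s", "true_position_bp",
              "emitting", "bound"),
    ground_truth = c("molecule_id", "frame", "time_s", "true_position_bp",
                     "emitting", "bound"),
    kinetics = c("molecule_id", "velocity_bp_s", "processivity_kb",
                 "n_pauses", "bound_lifetime_s", "translocating"))
  for (f in files) {
    if (!file.exists(f)) { add(f, "exists", FALSE, "missing file"); next }
    add(f, "exists", TRUE)
    ext <- tolower(tools::file_ext(f))
    if (ext %in% c("tif", "tiff")) {
      ok <- tryCatch({ read_tiff16(f); TRUE },
                     error = function(e) conditionMessage(e))
      add(f, "tiff_readable", isTRUE(ok),
          if (isTRUE(ok)) "" else ok)
    } else if (ext == "csv") {
      d <- tryCatch(utils::read.csv(f, nrows = 100000),
                    error = function(e) NULL)
      if (is.null(d)) { add(f, "csv_readable", FALSE, "parse error"); next }
      add(f, "csv_readable", TRUE)
      kind <- names(schemas)[vapply(names(schemas), function(k)
        grepl(k, basename(f), fixed = TRUE), logical(1))]
      if (length(kind)) {
        need <- schemas[[kind[1]]]
        miss <- setdiff(need, names(d))
        add(f, "schema", !length(miss),
            if (length(miss)) paste("missing columns:",
                                    paste(miss, collapse = ", ")) else "")
      }
      if ("frame" %in% names(d)) {
        bad <- sum(d$frame < 0 | d$frame != floor(d$frame))
        add(f, "frame_range", bad == 0,
            if (bad) sprintf("%d invalid frame values (< 0 or non-integer)",
                             bad) else "")
      }
      pcol <- intersect(c("position_bp", "true_position_bp"), names(d))
      if (length(pcol)) {
        v <- d[[pcol[1]]]
        bad <- sum(v < 0 | v > total_bp, na.rm = TRUE)
        add(f, "bp_range", bad == 0,
            if (bad) sprintf("%d positions outside [0, %d]", bad,
                             total_bp) else "")
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
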