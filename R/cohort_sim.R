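#' Simulate an imaged cohort of resecting molecules
#'
#' Generates a multi-stack synthetic experiment: molecules are placed on
#' parallel tethers (one per image row band, plus one stationary surface
#' fiducial per stack), with per-molecule velocities and processivities
#' drawn from normal distributions truncated at small positive floors.
#' Motors start near the free DNA end and translocate toward the anchor;
#' each dissociates after covering its drawn run length. Optional stochastic
#' pausing, quantum-dot blinking and linear stage drift are applied at
#' render time.
#'
#' Defaults encode the reference resection cohort: velocity 18 +/- 11 bp/s,
#' processivity 18 +/- 6 kb.
#'
#' @param n_molecules Number of DNA-bound molecules.
#' @param acq An [acquisition_config()]; image_shape is overridden per stack.
#' @param velocity_mean,velocity_sd Cohort velocity distribution, bp/s.
#' @param processivity_mean_kb,processivity_sd_kb Cohort processivity
#'   distribution, kb.
#' @param initiation_fraction Probability a molecule translocates at all.
#' @param pause_rate,pause_duration_mean Stochastic pause process (see
#'   [motor_params()]).
#' @param blink_on_rate,blink_off_rate Blinking rates, 1/s.
#' @param velocity_noise_sd Diffusive jitter, bp/sqrt(s).
#' @param drift_px_per_frame Linear stage drift c(dx, dy) per frame.
#' @param n_per_stack Molecules per rendered stack.
#' @param row_spacing_px Vertical spacing between tethers.
#' @param n_decoys Surface-stuck decoy particles per stack (they do not
#'   recoil during a flow stop and should be removed by
#'   [flow_stop_filter()]).
#' @param seed Master seed.
#' @return List of class `cohort_sim`: `stacks` (list of [render_stack()]
#'   results), `truth_params` (per-molecule drawn parameters),
#'   `calibration`, `fiducial_roi`, `acq`, `drift_px_per_frame`.
#' @export
simulate_cohort <- function(n_molecules, acq,
                            velocity_mean = 18, velocity_sd = 11,
                            processivity_mean_kb = 18,
                            processivity_sd_kb = 6,
                            initiation_fraction = 1,
                            pause_rate = 0, pause_duration_mean = 60,
                            blink_on_rate = 0.45, blink_off_rate = 0.05,
                            velocity_noise_sd = 20,
                            drift_px_per_frame = c(0.002, -0.001),
                            n_per_stack = 20, row_spacing_px = 12,
                            n_decoys = 0, seed = 1L) {
  stopifnot(inherits(acq, "acquisition_config"))
  draws <- with_seed(derive_seed(seed, "draws"), {
    v <- pmax(stats::rnorm(n_molecules, velocity_mean, velocity_sd), 2)
    p <- pmax(stats::rnorm(n_molecules, processivity_mean_kb,
                           processivity_sd_kb), 2)
    ini <- stats::runif(n_molecules) < initiation_fraction
    start <- stats::runif(n_molecules, 45500, 48000)
    data.frame(molecule_id = seq_len(n_molecules), velocity_bp_s = v,
               processivity_kb = p, initiates = ini, start_bp = start)
  })
  n_stacks <- ceiling(n_molecules / n_per_stack)
  nc <- 112L
  anchor_x <- 5
  drift <- NULL
  if (any(drift_px_per_frame != 0)) {
    drift <- cbind((0:(acq$n_frames - 1)) * drift_px_per_frame[1],
                   (0:(acq$n_frames - 1)) * drift_px_per_frame[2])
  }
  stacks <- vector("list", n_stacks)
  for (s in seq_len(n_stacks)) {
    idx <- ((s - 1) * n_per_stack + 1):min(s * n_per_stack, n_molecules)
    nr <- as.integer(row_spacing_px * (length(idx) + n_decoys + 1) +
                       row_spacing_px)
    acq_s <- acq
    acq_s$image_shape <- c(nr, nc)
    tracks <- list(); tethers <- list()
    # fiducial on the first row band
    fid_te <- dna_tether(anchor_px = c(anchor_x, row_spacing_px / 2),
                         axis_direction = c(1, 0), extension_px = 100)
    fid <- simulate_motor_path(
      motor_params(initial_position_bp = 25000, attachment = "surface",
                   amplitude_photons = 4000),
      acq_s, fid_te, seed = derive_seed(seed, paste0("fid", s)),
      molecule_id = paste0("fiducial_", s), channel = 0L)
    tracks[[1]] <- fid; tethers[[1]] <- fid_te
    for (j in seq_along(idx)) {
      i <- idx[j]
      te <- dna_tether(anchor_px = c(anchor_x, row_spacing_px / 2 +
                                       j * row_spacing_px),
                       axis_direction = c(1, 0), extension_px = 100)
      mp <- motor_params(
        initial_position_bp = draws$start_bp[i],
        velocity_bp_s = -draws$velocity_bp_s[i],
        velocity_noise_sd = velocity_noise_sd,
        pause_rate = pause_rate, pause_duration_mean = pause_duration_mean,
        stop_after_bp = draws$processivity_kb[i] * 1000,
        initiates = draws$initiates[i],
        blink_on_rate = blink_on_rate, blink_off_rate = blink_off_rate)
      tracks[[j + 1]] <- simulate_motor_path(
        mp, acq_s, te, seed = derive_seed(seed, paste0("mol", i)),
        molecule_id = draws$molecule_id[i], channel = 0L)
      tethers[[j + 1]] <- te
    }
    for (d in seq_len(n_decoys)) {
      te <- dna_tether(anchor_px = c(anchor_x, row_spacing_px / 2 +
                                       (length(idx) + d) * row_spacing_px),
                       axis_direction = c(1, 0), extension_px = 100)
      dk <- simulate_motor_path(
        motor_params(initial_position_bp = 46000, attachment = "surface"),
        acq_s, te, seed = derive_seed(seed, paste0("decoy", s, d)),
        molecule_id = paste0("decoy_", s, "_", d), channel = 0L)
      tracks[[length(tracks) + 1]] <- dk
      tethers[[length(tethers) + 1]] <- te
    }
    stacks[[s]] <- render_stack(tracks, tethers, acq_s,
                                seed = derive_seed(seed, paste0("noise", s)),
                                drift_px = drift)
  }
  cal <- calibration_map(anchor_px = c(anchor_x, 0),
                         axis_direction = c(1, 0),
                         bp_per_px = 48502 / 100)
  structure(list(
    stacks = stacks, truth_params = draws, calibration = cal,
    fiducial_roi = c(x = 0, y = 0, w = nc, h = row_spacing_px),
    acq = acq, drift_px_per_frame = drift_px_per_frame,
    row_spacing_px = row_spacing_px, seed = seed
  ), class = "cohort_sim")
}

#' Ground-truth kinetics of a simulated cohort
#'
#' Summarizes what actually happened in the rendered movie: each molecule's
#' drawn velocity and its realized processivity (maximum true excursion from
#' its start, which can be shorter than the drawn run length if the movie
#' ends first).
#'
#' @param sim A [simulate_cohort()] result.
#' @return data.frame: `molecule_id`, `true_velocity_bp_s`,
#'   `true_processivity_kb`, `initiates`.
#' @export
cohort_truth <- function(sim) {
  stopifnot(inherits(sim, "cohort_sim"))
  truth <- do.call(rbind, lapply(sim$stacks, `[[`, "truth"))
  ids <- sim$truth_params$molecule_id
  real_p <- vapply(ids, function(id) {
    p <- truth$true_position_bp[truth$molecule_id == id & truth$bound]
    if (!length(p)) return(NA_real_)
    max(abs(p - p[1])) / 1000
  }, numeric(1))
  data.frame(molecule_id = ids,
             true_velocity_bp_s = sim$truth_params$velocity_bp_s,
             true_processivity_kb = real_p,
             initiates = sim$truth_params$initiates)
}

#' Run the analysis pipeline on a simulated cohort in memory
#'
#' localize -> drift-correct -> link -> calibrate -> movement filter ->
#' kinetics, with recovered trajectories matched back to ground-truth
#' molecules by tether row.
#'
#' @param sim A [simulate_cohort()] result.
#' @param min_snr,window_px Localization settings.
#' @param max_step_px,max_gap_frames Linking settings.
#' @param resolution_bp,min_pause_duration_s Kinetics settings.
#' @param min_displacement_bp Movement-filter threshold.
#' @param min_track_frames Discard spurious tracks shorter than this.
#' @return List with `kinetics` (with `true_molecule_id` where matched),
#'   `pauses`, `traj`, `drift`.
#' @export
recover_cohort <- function(sim, min_snr = 5, window_px = 9,
                           max_step_px = 3, max_gap_frames = 10,
                           resolution_bp = 500, min_pause_duration_s = 30,
                           min_displacement_bp = 1000,
                           min_track_frames = 20) {
  stopifnot(inherits(sim, "cohort_sim"))
  all_kin <- list(); all_pauses <- list(); all_traj <- list()
  id_offset <- 0L
  for (s in seq_along(sim$stacks)) {
    rs <- sim$stacks[[s]]
    stack <- rs$stacks[[1]]
    det <- localize_stack(stack, min_snr = min_snr, window_px = window_px)
    if (!nrow(det)) next
    roi <- sim$fiducial_roi
    fid <- det[det$x_px >= roi["x"] & det$x_px < roi["x"] + roi["w"] &
                 det$y_px >= roi["y"] & det$y_px < roi["y"] + roi["h"], ]
    drift <- estimate_drift(fid, n_frames = sim$acq$n_frames)
    det <- apply_drift(det, drift)
    # drop the fiducial before linking molecules
    det <- det[!(det$y_px >= roi["y"] - 1 &
                   det$y_px < roi["y"] + roi["h"]), ]
    linked <- link_detections(det, max_step_px = max_step_px,
                              max_gap_frames = max_gap_frames)
    if (!nrow(linked)) next
    keep <- table(linked$molecule_id)
    keep <- as.integer(names(keep)[keep >= min_track_frames])
    linked <- linked[linked$molecule_id %in% keep, ]
    if (!nrow(linked)) next
    linked$molecule_id <- linked$molecule_id + id_offset
    traj <- calibrate(linked, sim$calibration,
                      frame_interval = sim$acq$frame_interval)
    # match to ground truth by tether row band
    band <- round((stats::ave(traj$y_px, traj$molecule_id) -
                     sim$row_spacing_px / 2) / sim$row_spacing_px)
    stack_ids <- unique(do.call(rbind, list(rs$truth))$molecule_id)
    stack_ids <- setdiff(stack_ids, paste0("fiducial_", s))
    traj$true_molecule_id <- NA
    idx_map <- stats::setNames(stack_ids, seq_along(stack_ids))
    bi <- as.character(as.integer(band))
    traj$true_molecule_id <- unname(idx_map[bi])
    mf <- movement_filter(traj, min_displacement_bp = min_displacement_bp)
    res <- analyze_trajectories(traj, mf$translocating,
                                n_frames = sim$acq$n_frames,
                                frame_interval = sim$acq$frame_interval,
                                resolution_bp = resolution_bp,
                                min_pause_duration_s = min_pause_duration_s)
    kin <- res$kinetics
    tm <- tapply(traj$true_molecule_id, traj$molecule_id, function(v) v[1])
    kin$true_molecule_id <- unname(tm[as.character(kin$molecule_id)])
    all_kin[[s]] <- kin
    all_pauses[[s]] <- res$pauses
    all_traj[[s]] <- traj
    id_offset <- id_offset + max(linked$molecule_id)
  }
  list(kinetics = do.call(rbind, all_kin),
       pauses = do.call(rbind, all_pauses),
       traj = do.call(rbind, all_traj))
}
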