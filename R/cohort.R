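#' Bootstrap standard deviation of a proportion
#'
#' Resamples molecules with replacement `n_boot` times and returns the SD of
#' the resampled fractions; this is the error bar used for initiation,
#' pause, colocalization and dissociation fractions.
#'
#' @param flags Logical/0-1 indicator per molecule.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed (recorded in the output for provenance).
#' @return List with `fraction`, `sd`, `n`, `n_boot`, `seed`.
#' @export
bootstrap_fraction <- function(flags, n_boot = 1000, seed = 1L) {
  flags <- as.numeric(flags)
  if (!length(flags)) stop("empty indicator vector", call. = FALSE)
  if (any(is.na(flags)) || any(!flags %in% c(0, 1))) {
    stop("'flags' must be 0/1 indicators", call. = FALSE)
  }
  n <- length(flags)
  frac <- mean(flags)
  sd_boot <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      mean(flags[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    stats::sd(reps)
  })
  list(fraction = frac, sd = sd_boot, n = n, n_boot = n_boot, seed = seed)
}

#' Initiation fraction of a cohort
#'
#' Fraction of end-bound molecules that begin long-range (> 1 kb)
#' translocation, with a bootstrap SD. Accepts either the partition from
#' [movement_filter()] or explicit counts.
#'
#' @param partition A [movement_filter()] result, or `NULL` when counts are
#'   given.
#' @param n_translocating,n_total Printed molecule counts, as an alternative
#'   to a partition.
#' @param n_boot,seed Bootstrap parameters.
#' @return List with `fraction`, `sd`, `n_translocating`, `n_total`.
#' @examples
#' initiation_fraction(n_translocating = 86, n_total = 111)$fraction # 0.77...
#' @export
initiation_fraction <- function(partition = NULL, n_translocating = NULL,
                                n_total = NULL, n_boot = 1000, seed = 1L) {
  if (!is.null(partition)) {
    n_translocating <- length(partition$translocating)
    n_total <- n_translocating + length(partition$static)
  }
  if (is.null(n_translocating) || is.null(n_total) || n_total < 1) {
    stop("empty denominator: no end-bound molecules", call. = FALSE)
  }
  if (n_translocating > n_total) {
    stop("numerator exceeds denominator", call. = FALSE)
  }
  flags <- c(rep(1, n_translocating), rep(0, n_total - n_translocating))
  bs <- bootstrap_fraction(flags, n_boot = n_boot, seed = seed)
  list(fraction = bs$fraction, sd = bs$sd,
       n_translocating = n_translocating, n_total = n_total)
}

#' Fraction from printed numerator/denominator counts
#'
#' The worked-example path: reproduces a printed percentage from its
#' molecule counts through the same indicator-vector machinery used for
#' measured cohorts.
#'
#' @param numerator,denominator Molecule counts.
#' @param percent Return the fraction times 100.
#' @param n_boot,seed Bootstrap parameters.
#' @return List with `fraction` (or percent), `sd` (same scale), counts.
#' @examples
#' fraction_from_counts(97, 112, percent = TRUE)$fraction  # 86.6...
#' @export
fraction_from_counts <- function(numerator, denominator, percent = FALSE,
                                 n_boot = 1000, seed = 1L) {
  if (denominator < 1) stop("empty denominator", call. = FALSE)
  if (numerator > denominator) stop("numerator exceeds denominator",
                                    call. = FALSE)
  flags <- c(rep(1, numerator), rep(0, denominator - numerator))
  bs <- bootstrap_fraction(flags, n_boot = n_boot, seed = seed)
  sc <- if (percent) 100 else 1
  list(fraction = bs$fraction * sc, sd = bs$sd * sc,
       numerator = numerator, denominator = denominator)
}

#' Two-channel colocalization
#'
#' An A-channel molecule is colocalized iff some B-channel molecule stays
#' within `threshold_bp` along the tether for at least `min_overlap_frames`
#' consecutive simultaneous frames. Colocalization is directional (fraction
#' of A near B differs from B near A); call with the channels swapped for
#' the reverse direction.
#'
#' @param traj_a,traj_b Calibrated trajectory data.frames for the two
#'   channels (`molecule_id`, `frame`, `position_bp`), drift-corrected and
#'   channel-registered.
#' @param threshold_bp Axial distance threshold (default 1000 bp, twice the
#'   ~500 bp resolution).
#' @param min_overlap_frames Minimum consecutive overlapping frames.
#' @param n_boot,seed Bootstrap parameters for the SD.
#' @return An object of class `colocalization_result`: `n_a`,
#'   `n_colocalized`, `fraction`, `sd`, `threshold_bp`,
#'   `min_overlap_frames`, `per_molecule` flags.
#' @export
colocalize <- function(traj_a, traj_b, threshold_bp = 1000,
                       min_overlap_frames = 5, n_boot = 1000, seed = 1L) {
  need <- c("molecule_id", "frame", "position_bp")
  stopifnot(all(need %in% names(traj_a)), all(need %in% names(traj_b)))
  ids_a <- unique(traj_a$molecule_id)
  ids_b <- unique(traj_b$molecule_id)
  if (!length(ids_a)) stop("channel A has no molecules", call. = FALSE)
  coloc <- vapply(ids_a, function(ia) {
    a <- traj_a[traj_a$molecule_id == ia, ]
    for (ib in ids_b) {
      b <- traj_b[traj_b$molecule_id == ib, ]
      m <- merge(a[, c("frame", "position_bp")],
                 b[, c("frame", "position_bp")], by = "frame")
      if (nrow(m) < min_overlap_frames) next
      near <- abs(m$position_bp.x - m$position_bp.y) <= threshold_bp
      # longest run of consecutive near frames (consecutive frame numbers)
      m <- m[order(m$frame), ]
      run <- 0L; best <- 0L; prev_frame <- NA_integer_
      for (i in seq_len(nrow(m))) {
        if (near[i] && !is.na(prev_frame) && m$frame[i] == prev_frame + 1L &&
            run > 0L) {
          run <- run + 1L
        } else if (near[i]) {
          run <- 1L
        } else {
          run <- 0L
        }
        best <- max(best, run)
        prev_frame <- m$frame[i]
      }
      if (best >= min_overlap_frames) return(TRUE)
    }
    FALSE
  }, logical(1))
  bs <- bootstrap_fraction(as.integer(coloc), n_boot = n_boot, seed = seed)
  structure(list(n_a = length(ids_a), n_colocalized = sum(coloc),
                 fraction = bs$fraction, sd = bs$sd,
                 threshold_bp = threshold_bp,
                 min_overlap_frames = min_overlap_frames,
                 per_molecule = stats::setNames(coloc, ids_a)),
            class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf(
    "<colocalization> %d/%d (%.0f%%, bootstrap SD %.1f%%) within %g bp for >= %d frames\n",
    x$n_colocalized, x$n_a, 100 * x$fraction, 100 * x$sd,
    x$threshold_bp, x$min_overlap_frames))
  invisible(x)
}

#' Two-sample comparison with significance stars
#'
#' Two-sided two-sample t test (Welch by default; `var_equal = TRUE` for the
#' pooled-variance Student test) with the star bins used in figure legends:
#' ns p > 0.05, * < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001. Groups
#' with zero variance are handled by an exact-equality shortcut.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @param var_equal Logical; pooled-variance Student test if TRUE.
#' @return List with `t`, `p`, `stars`, `df`, `mean_a`, `mean_b`, `method`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    t_stat <- if (same) 0 else Inf * sign(mean(values_a) - mean(values_b))
    p <- if (same) 1 else 0
    return(list(t = t_stat, p = p, stars = p_stars(p), df = NA_real_,
                mean_a = mean(values_a), mean_b = mean(values_b),
                method = "degenerate (zero variance)"))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value, stars = p_stars(ht$p.value),
       df = unname(ht$parameter), mean_a = mean(values_a),
       mean_b = mean(values_b), method = ht$method)
}

p_stars <- function(p) {
  if (p > 0.05) "ns"
  else if (p >= 0.01) "*"
  else if (p >= 0.001) "**"
  else if (p >= 0.0001) "***"
  else "****"
}

#' Fold change between two group means
#'
#' @param mean_a,mean_b Group means; `mean_b` must be non-zero.
#' @return The ratio `mean_a / mean_b` (class `fold_change`; printed to one
#'   decimal, the reporting convention for fold changes).
#' @examples
#' fold_change(18, 9)   # 2.0
#' fold_change(18, 13)  # 1.4
#' @export
fold_change <- function(mean_a, mean_b) {
  assert_scalar_num(mean_a, "mean_a")
  assert_scalar_num(mean_b, "mean_b")
  if (mean_b == 0) stop("zero denominator", call. = FALSE)
  structure(mean_a / mean_b, class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("%.1f-fold\n", unclass(x)))
  invisible(x)
}

#' Condition-level summary of a kinetics table
#'
#' @param kinetics The kinetics table from [analyze_trajectories()].
#' @param condition Condition label.
#' @param horizon_s Dissociation horizon in seconds.
#' @param n_boot,seed Bootstrap parameters.
#' @return One-row data.frame of class `cohort_summary`: n, velocity and
#'   processivity mean/SD/median/IQR, initiation fraction +/- bootstrap SD,
#'   pause fractions, dissociation fraction.
#' @export
cohort_summary <- function(kinetics, condition = "condition",
                           horizon_s = 1800, n_boot = 1000, seed = 1L) {
  k <- kinetics
  tr <- k[k$translocating, , drop = FALSE]
  init <- bootstrap_fraction(as.integer(k$translocating), n_boot, seed)
  ps <- if (nrow(tr)) pause_summary(k) else
    list(fractions = c(no_pause = NA, ge1_pause = NA, ge2_pause = NA))
  dis <- dissociation_fraction(k$bound_lifetime_s, horizon_s, n_boot,
                               derive_seed(seed, "diss"))
  qv <- stats::quantile(tr$velocity_bp_s, c(0.25, 0.5, 0.75), na.rm = TRUE)
  qp <- stats::quantile(tr$processivity_kb, c(0.25, 0.5, 0.75), na.rm = TRUE)
  out <- data.frame(
    condition = condition, n_molecules = nrow(k),
    n_translocating = nrow(tr),
    velocity_mean = mean(tr$velocity_bp_s, na.rm = TRUE),
    velocity_sd = stats::sd(tr$velocity_bp_s, na.rm = TRUE),
    velocity_median = unname(qv[2]), velocity_iqr = unname(qv[3] - qv[1]),
    processivity_mean = mean(tr$processivity_kb, na.rm = TRUE),
    processivity_sd = stats::sd(tr$processivity_kb, na.rm = TRUE),
    processivity_median = unname(qp[2]),
    processivity_iqr = unname(qp[3] - qp[1]),
    initiation_fraction = init$fraction, initiation_sd = init$sd,
    frac_no_pause = unname(ps$fractions["no_pause"]),
    frac_ge1_pause = unname(ps$fractions["ge1_pause"]),
    frac_ge2_pause = unname(ps$fractions["ge2_pause"]),
    dissociation_fraction = dis$fraction, dissociation_sd = dis$sd)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Sliding-window GC profile of a DNA sequence
#'
#' @param sequence A `Biostrings::DNAString`, a character string, or a path
#'   to a FASTA file (first record used).
#' @param window_bp Window width in bp.
#' @param step_bp Step between window starts (default = `window_bp`, i.e.
#'   non-overlapping tiling).
#' @return data.frame: `start_bp` (0-based), `end_bp` (exclusive), `gc`
#'   fraction. Non-ACGT characters are counted as non-GC with a warning.
#' @export
gc_profile <- function(sequence, window_bp = 500, step_bp = window_bp) {
  if (is.character(sequence) && length(sequence) == 1 &&
      file.exists(sequence)) {
    sequence <- Biostrings::readDNAStringSet(sequence)[[1]]
  } else if (is.character(sequence)) {
    sequence <- Biostrings::DNAString(paste(sequence, collapse = ""))
  }
  len <- length(sequence)
  if (len < window_bp) stop("sequence shorter than window", call. = FALSE)
  freq <- Biostrings::alphabetFrequency(sequence)
  other <- sum(freq) - sum(freq[c("A", "C", "G", "T")])
  if (other > 0) {
    warning(sprintf("%d non-ACGT characters counted as non-GC", other),
            call. = FALSE)
  }
  starts <- seq(1L, len - window_bp + 1L, by = step_bp)
  v <- Biostrings::Views(sequence, start = starts,
                         width = window_bp)
  gc <- Biostrings::letterFrequency(v, "GC") / window_bp
  data.frame(start_bp = starts - 1L, end_bp = starts - 1L + window_bp,
             gc = as.numeric(gc))
}

# GC fraction at arbitrary bp coordinates, from a tiled profile
gc_at <- function(profile, positions_bp) {
  w <- profile$end_bp[1] - profile$start_bp[1]
  step <- if (nrow(profile) > 1) profile$start_bp[2] - profile$start_bp[1]
          else w
  idx <- pmin(pmax(floor(positions_bp / step) + 1L, 1L), nrow(profile))
  profile$gc[idx]
}

#' Association between pause positions and local GC content
#'
#' Compares the GC content at observed pause positions against matched
#' random non-pause positions drawn uniformly from the substrate (excluding
#' windows containing a pause), via [compare_groups()].
#'
#' @param pause_positions_bp Pause positions in bp on the substrate
#'   coordinate system.
#' @param profile A [gc_profile()] data.frame.
#' @param n_random Number of matched random positions (default 10 per
#'   pause).
#' @param seed Integer seed for the random draw.
#' @return The [compare_groups()] list, plus `gc_pause_mean`,
#'   `gc_random_mean`.
#' @export
pause_gc_association <- function(pause_positions_bp, profile,
                                 n_random = 10 * length(pause_positions_bp),
                                 seed = 1L) {
  if (length(pause_positions_bp) < 2) {
    stop("need >= 2 pause positions", call. = FALSE)
  }
  gc_pause <- gc_at(profile, pause_positions_bp)
  span <- max(profile$end_bp)
  pause_windows <- unique(floor(pause_positions_bp /
                                  (profile$end_bp[1] - profile$start_bp[1])))
  rand <- with_seed(seed, {
    r <- stats::runif(4 * n_random, 0, span)
    w <- floor(r / (profile$end_bp[1] - profile$start_bp[1]))
    r <- r[!(w %in% pause_windows)]
    r[seq_len(min(n_random, length(r)))]
  })
  gc_rand <- gc_at(profile, rand)
  res <- compare_groups(gc_pause, gc_rand)
  res$gc_pause_mean <- mean(gc_pause)
  res$gc_random_mean <- mean(gc_rand)
  res
}
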