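# EMG conditioning, gait-cycle segmentation onto 200 phase bins, amplitude
# and unit-variance normalization, plus the Froude-number walking-speed
# protocol utilities.

#' Raw multi-channel EMG recording
#'
#' @param emg Numeric matrix, channels x samples (signed, arbitrary units).
#' @param fs Sampling frequency in Hz.
#' @param muscle_labels Character vector, one unique label per channel.
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(emg, fs, muscle_labels = NULL) {
  emg <- as.matrix(emg)
  if (is.null(muscle_labels)) muscle_labels <- default_muscles(nrow(emg))
  if (fs <= 0) stop_invalid("fs must be positive")
  if (length(muscle_labels) != nrow(emg)) {
    stop_invalid("muscle_labels length (", length(muscle_labels),
                 ") must equal channel count (", nrow(emg), ")")
  }
  if (anyDuplicated(muscle_labels)) stop_invalid("muscle labels must be unique")
  structure(list(emg = emg, fs = fs, muscle_labels = muscle_labels),
            class = "raw_recording")
}

#' Sagittal limb-axis marker track
#'
#' Two-dimensional trajectories of the greater trochanter (GT) and lateral
#' malleolus (LM) markers; columns are (anterior x, vertical y) in metres.
#'
#' @param gt_xy,lm_xy Numeric matrices, samples x 2.
#' @param fs Sampling frequency in Hz.
#' @return A `limb_axis_track` object.
#' @export
limb_axis_track <- function(gt_xy, lm_xy, fs) {
  gt_xy <- as.matrix(gt_xy); lm_xy <- as.matrix(lm_xy)
  if (nrow(gt_xy) != nrow(lm_xy)) stop_invalid("marker tracks differ in length")
  if (ncol(gt_xy) != 2 || ncol(lm_xy) != 2) stop_invalid("tracks must have 2 columns (x, y)")
  if (fs <= 0) stop_invalid("fs must be positive")
  structure(list(gt_xy = gt_xy, lm_xy = lm_xy, fs = fs),
            class = "limb_axis_track")
}

#' Condition raw EMG into linear envelopes
#'
#' High-pass filters at `high_pass` Hz (zero-phase 4th-order Butterworth),
#' demeans, full-wave rectifies, then low-pass filters at `low_pass` Hz
#' (same filter class) to obtain nonnegative linear envelopes.
#'
#' @param rec A [raw_recording()] (or plain channels x samples matrix with
#'   `fs` given).
#' @param fs Sampling rate, required when `rec` is a bare matrix.
#' @param high_pass,low_pass Corner frequencies in Hz.
#' @param order Butterworth order of each single pass (applied
#'   forward-backward, so the effective attenuation is doubled).
#' @return Nonnegative envelope matrix, channels x samples.
#' @export
condition_emg <- function(rec, fs = NULL, high_pass = 100, low_pass = 10,
                          order = 4) {
  if (inherits(rec, "raw_recording")) {
    emg <- rec$emg
    fs <- rec$fs
  } else {
    emg <- as.matrix(rec)
    if (is.null(fs)) stop_invalid("fs is required for a bare matrix input")
  }
  if (fs <= 2.2 * high_pass) {
    stop_invalid("fs = ", fs, " Hz too low for a ", high_pass,
                 " Hz high-pass corner (need > ", 2.2 * high_pass, " Hz)")
  }
  if (any(!is.finite(emg))) stop_invalid("EMG contains non-finite samples")
  hp <- butter_coefficients(order, high_pass, fs, "high")
  lp <- butter_coefficients(order, low_pass, fs, "low")
  out <- emg
  for (ch in seq_len(nrow(emg))) {
    x <- filtfilt_zero_phase(hp$b, hp$a, emg[ch, ])
    x <- x - mean(x)
    x <- abs(x)
    x <- filtfilt_zero_phase(lp$b, lp$a, x)
    out[ch, ] <- pmax(x, 0)
  }
  out
}

#' Sagittal elevation angle of the limb axis
#'
#' Angle (degrees) between the LM-to-GT vector and the vertical, positive
#' when the malleolus lies anterior to the trochanter (limb extended
#' forward, as at late swing / foot contact).
#'
#' @param track A [limb_axis_track()].
#' @return Numeric vector of angles in degrees.
#' @export
limb_elevation_angle <- function(track) {
  stopifnot(inherits(track, "limb_axis_track"))
  dx <- track$lm_xy[, 1] - track$gt_xy[, 1]
  dy <- track$gt_xy[, 2] - track$lm_xy[, 2]
  atan2(dx, dy) * 180 / pi
}

#' Detect foot contacts as maxima of the limb elevation angle
#'
#' Foot contact is taken as the time of maximum elevation of the limb axis.
#' Local maxima separated by at least `min_period_s` are returned.
#'
#' @param x A [limb_axis_track()] or a numeric elevation-angle vector.
#' @param fs Sampling rate in Hz (required for a numeric vector).
#' @param min_period_s Minimum separation between contacts in seconds.
#' @return A `gait_events` object with 1-based `contact_samples`.
#' @export
detect_foot_contacts <- function(x, fs = NULL, min_period_s = 0.4) {
  if (inherits(x, "limb_axis_track")) {
    angle <- limb_elevation_angle(x)
    fs <- x$fs
  } else {
    angle <- as.numeric(x)
    if (is.null(fs)) stop_invalid("fs is required for a numeric angle input")
  }
  n <- length(angle)
  if (n < 3) stop_insufficient("angle signal too short")
  is_peak <- c(FALSE, angle[2:(n - 1)] > angle[1:(n - 2)] &
                 angle[2:(n - 1)] >= angle[3:n], FALSE)
  peaks <- which(is_peak)
  # enforce minimum separation, keeping the taller of two close peaks
  min_gap <- max(1L, round(min_period_s * fs))
  if (length(peaks) > 1) {
    keep <- peaks[1]
    for (p in peaks[-1]) {
      last <- keep[length(keep)]
      if (p - last >= min_gap) {
        keep <- c(keep, p)
      } else if (angle[p] > angle[last]) {
        keep[length(keep)] <- p
      }
    }
    peaks <- keep
  }
  if (length(peaks) < 2) {
    stop_insufficient("fewer than 2 limb-axis elevation maxima detected; ",
                      "cannot define a gait cycle")
  }
  structure(list(contact_samples = as.integer(peaks), fs = fs),
            class = "gait_events")
}

#' Segment an envelope into gait cycles and normalize to phase bins
#'
#' Each cycle spans the half-open interval from one foot contact to the
#' next; samples are linearly interpolated onto `n_bins` phase bins (bin j
#' maps to phase (j-1)/n_bins of the cycle). The first cycle is discarded
#' as a transient; of the remainder, the `n_cycles` middle-most cycles are
#' retained and averaged.
#'
#' @param envelope Channels x samples nonnegative matrix.
#' @param events A `gait_events` object (or integer vector of contacts).
#' @param n_bins Number of phase bins (default 200).
#' @param n_cycles Number of cycles to average (default 10).
#' @return List with `average` (channels x n_bins), `cycles` (channels x
#'   n_bins x n_cycles array) and `cycle_indices` (which inter-contact
#'   intervals were used, 1-based).
#' @export
segment_and_normalize <- function(envelope, events, n_bins = 200,
                                  n_cycles = 10) {
  envelope <- as.matrix(envelope)
  contacts <- if (inherits(events, "gait_events")) events$contact_samples
              else as.integer(events)
  if (length(contacts) < 2) stop_insufficient("need at least 2 contacts")
  if (is.unsorted(contacts, strictly = TRUE)) {
    stop_invalid("contact samples must be strictly increasing")
  }
  n_avail <- length(contacts) - 1L   # complete cycles
  usable <- setdiff(seq_len(n_avail), 1L)   # drop first cycle (transient)
  if (length(usable) < n_cycles) {
    stop_insufficient("only ", length(usable), " analysable cycles after ",
                      "discarding the first; need ", n_cycles)
  }
  # middle-most n_cycles of the usable ones
  extra <- length(usable) - n_cycles
  lo <- floor(extra / 2)
  idx <- usable[(lo + 1):(lo + n_cycles)]
  nch <- nrow(envelope)
  cyc <- array(NA_real_, dim = c(nch, n_bins, n_cycles))
  t_all <- seq_len(ncol(envelope))
  for (ii in seq_along(idx)) {
    k <- idx[ii]
    from <- contacts[k]; to <- contacts[k + 1L]
    pos <- from + (seq_len(n_bins) - 1) / n_bins * (to - from)
    for (ch in seq_len(nch)) {
      cyc[ch, , ii] <- approx(t_all, envelope[ch, ], xout = pos)$y
    }
  }
  avg <- apply(cyc, c(1, 2), mean)
  rownames(avg) <- rownames(envelope)
  list(average = avg, cycles = cyc, cycle_indices = idx)
}

#' Gait-cycle EMG matrix for one participant and condition
#'
#' @param values Nonnegative muscles x n_bins matrix.
#' @param muscle_labels Muscle names (rows).
#' @param participant,condition Labels carried through the pipeline.
#' @param scale_info Optional bookkeeping from amplitude normalization.
#' @return A `cycle_matrix` object.
#' @export
cycle_matrix <- function(values, muscle_labels = NULL, participant = NA,
                         condition = NA, scale_info = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop_invalid("cycle matrix must be nonnegative")
  if (is.null(muscle_labels)) {
    muscle_labels <- rownames(values)
    if (is.null(muscle_labels)) muscle_labels <- default_muscles(nrow(values))
  }
  rownames(values) <- muscle_labels
  structure(list(values = values, muscle_labels = muscle_labels,
                 participant = participant, condition = condition,
                 scale_info = scale_info),
            class = "cycle_matrix")
}

#' @export
print.cycle_matrix <- function(x, ...) {
  cat("<cycle_matrix> ", nrow(x$values), " muscles x ", ncol(x$values),
      " bins; participant=", as.character(x$participant),
      " condition=", as.character(x$condition), "\n", sep = "")
  invisible(x)
}

#' Amplitude-normalize cycle matrices across a participant's conditions
#'
#' Per muscle and condition, subtracts that trace's own cycle minimum; the
#' resulting traces are divided by the muscle's maximum across all the
#' participant's conditions, so each muscle peaks at 1 in exactly one
#' condition. Idempotent.
#'
#' @param matrices List of `cycle_matrix` objects (or plain matrices) for
#'   one participant, all sharing muscle order.
#' @return List of normalized `cycle_matrix` objects with `scale_info`.
#' @export
normalize_amplitude <- function(matrices) {
  if (length(matrices) < 1) stop_invalid("need at least one condition")
  vals <- lapply(matrices, as_values_matrix)
  nm <- nrow(vals[[1]])
  labs <- if (inherits(matrices[[1]], "cycle_matrix"))
    matrices[[1]]$muscle_labels else default_muscles(nm)
  for (v in vals) {
    if (nrow(v) != nm) stop_invalid("matrices differ in muscle count")
  }
  shifted <- lapply(vals, function(v) v - apply(v, 1, min))
  maxima <- apply(do.call(cbind, lapply(shifted, function(v) apply(v, 1, max))),
                  1, max)
  dead <- which(maxima <= 0)
  if (length(dead) > 0) {
    stop_degenerate("muscle(s) constant in every condition: ",
                    paste(labs[dead], collapse = ", "))
  }
  lapply(seq_along(matrices), function(i) {
    src <- matrices[[i]]
    out <- shifted[[i]] / maxima
    cycle_matrix(out,
                 muscle_labels = labs,
                 participant = if (inherits(src, "cycle_matrix")) src$participant else NA,
                 condition = if (inherits(src, "cycle_matrix")) src$condition else NA,
                 scale_info = list(max_divisor = maxima))
  })
}

#' Scale each muscle row to unit variance
#'
#' Divides each row by its population standard deviation (divisor n) so all
#' muscles weigh equally in module extraction; the returned scales restore
#' the original amplitude afterwards (applied to the spatial weightings).
#'
#' @param m A `cycle_matrix` or plain matrix.
#' @return List with `values` (scaled matrix) and `scales` (per-muscle sd).
#' @export
scale_unit_variance <- function(m) {
  v <- as_values_matrix(m)
  n <- ncol(v)
  sds <- sqrt(rowSums((v - rowMeans(v))^2) / n)
  if (any(sds <= 0)) {
    labs <- rownames(v)
    if (is.null(labs)) labs <- default_muscles(nrow(v))
    stop_degenerate("zero-variance muscle row(s): ",
                    paste(labs[sds <= 0], collapse = ", "))
  }
  list(values = v / sds, scales = sds)
}

#' Undo unit-variance scaling
#'
#' @param values Scaled matrix (or spatial weightings with muscles as rows).
#' @param scales Per-muscle standard deviations from [scale_unit_variance()].
#' @return Rescaled matrix.
#' @export
unscale_unit_variance <- function(values, scales) {
  as.matrix(values) * scales
}

#' Walking speed at a prescribed Froude number
#'
#' Dynamically similar pendular walking across gravity levels is obtained
#' at equal Froude number Fr = v^2 / (g L); the matched speed is
#' v = sqrt(Fr g L).
#'
#' @param leg_length Leg length L in metres.
#' @param g_eff Effective gravitational acceleration in m/s^2.
#' @param froude Target Froude number (default 0.25).
#' @return List with `v_mps` and `v_kmh`.
#' @export
froude_speed <- function(leg_length, g_eff, froude = 0.25) {
  if (leg_length <= 0 || g_eff <= 0 || froude <= 0) {
    stop_invalid("leg_length, g_eff and froude must all be positive")
  }
  v <- sqrt(froude * g_eff * leg_length)
  list(v_mps = v, v_kmh = v * 3.6)
}

#' Froude number of a walking condition
#'
#' @param v Walking speed in m/s.
#' @param g_eff Effective gravity in m/s^2.
#' @param leg_length Leg length in metres.
#' @return Dimensionless Froude number v^2 / (g L).
#' @export
fr_number <- function(v, g_eff, leg_length) {
  if (v <= 0 || g_eff <= 0 || leg_length <= 0) {
    stop_invalid("all arguments must be positive")
  }
  v^2 / (g_eff * leg_length)
}

#' Scale a Froude-matched speed to another gravity level
#'
#' At fixed Froude number, v scales with the square root of gravity, so
#' `v(r g) = sqrt(r) v(g)` independently of leg length.
#'
#' @param v_ref Reference speed (any unit).
#' @param gravity_ratio Ratio of target to reference gravity (> 0).
#' @return Speed in the same unit as `v_ref`.
#' @export
froude_scaled_speed <- function(v_ref, gravity_ratio) {
  if (v_ref <= 0 || gravity_ratio <= 0) {
    stop_invalid("v_ref and gravity_ratio must be positive")
  }
  v_ref * sqrt(gravity_ratio)
}

#' Net-load proxy of inverted-pendulum walking
#'
#' The effective load on the stance limb early in support scales as
#' m (g - v^2 / L); it turns negative once v^2 / (g L) > 1, the regime
#' where pendular dynamics break down (returned as-is).
#'
#' @param mass Body mass in kg.
#' @param g_eff Effective gravity in m/s^2.
#' @param v Walking speed in m/s.
#' @param leg_length Leg length in metres.
#' @return Net-load proxy in newtons.
#' @export
net_load_proxy <- function(mass, g_eff, v, leg_length) {
  if (mass <= 0 || g_eff <= 0 || v < 0 || leg_length <= 0) {
    stop_invalid("mass, g_eff and leg_length must be positive; v nonnegative")
  }
  mass * (g_eff - v^2 / leg_length)
}
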