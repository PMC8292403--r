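# Synthetic modular EMG with known ground truth. The generator states a
# world with the structure the analysis assumes -- a small set of
# nonnegative spatial modules driven by phase-locked temporal bursts whose
# gains vary systematically with the (gravity) condition -- so every
# downstream stage can be tested as a parameter-recovery problem.

PROFILE_KINDS <- c("constant", "linear_decreasing", "threshold_decreasing",
                   "u_shaped")

gain_profile <- function(kind, n_conditions) {
  pos <- seq(0, 1, length.out = n_conditions)
  switch(kind,
    constant = rep(1, n_conditions),
    # monotone decrease from full recruitment to a weak residual
    linear_decreasing = seq(1, 0.3, length.out = n_conditions),
    # plateau at the highest gravity levels, then near-extinction
    threshold_decreasing = {
      n_plat <- max(1L, floor(n_conditions * 0.4))
      c(rep(1, n_plat),
        seq(1, 0.05, length.out = n_conditions - n_plat + 1)[-1])
    },
    # high at both gravity extremes, minimum at the middle level
    u_shaped = 0.4 + 0.6 * (2 * pos - 1)^2,
    stop_invalid("unknown profile kind '", kind, "'; must be one of ",
                 paste(PROFILE_KINDS, collapse = ", "))
  )
}

#' Create a ground-truth modular EMG generative model
#'
#' Spatial modules have disjoint-dominant muscle groups (unit-norm
#' columns); temporal modules are truncated-Gaussian bursts (sd 5% of the
#' cycle) centred at distinct phases, defaulting to 5, 40, 60 and 95% of
#' the cycle for four modules (initial contact, propulsion, early swing,
#' late swing). Per-module gains follow a named profile over the ordered
#' condition labels, and each participant carries a multiplicative
#' lognormal jitter of the spatial weights.
#'
#' @param n_modules Number of ground-truth modules (>= 1).
#' @param condition_labels Ordered condition labels (>= 2), highest gravity
#'   first.
#' @param profile_kinds One of `"constant"`, `"linear_decreasing"`,
#'   `"threshold_decreasing"`, `"u_shaped"` per module.
#' @param seed Integer seed; the model is fully deterministic given it.
#' @param n_muscles,n_bins,n_participants World dimensions.
#' @param noise_sd Default additive Gaussian noise sd for cycle matrices.
#' @param burst_sd Temporal burst width as a fraction of the cycle.
#' @param burst_centers Optional burst centres as cycle fractions.
#' @param subject_sigma Lognormal sigma of per-participant weight jitter.
#' @return A `ground_truth` object.
#' @export
make_ground_truth <- function(n_modules = 4,
                              condition_labels = c("1g", "0.6g", "0.38g",
                                                   "0.16g", "0.07g"),
                              profile_kinds = c("constant",
                                                "linear_decreasing",
                                                "threshold_decreasing",
                                                "u_shaped"),
                              seed = 1,
                              n_muscles = 12,
                              n_bins = 200,
                              n_participants = 9,
                              noise_sd = 0.02,
                              burst_sd = 0.05,
                              burst_centers = NULL,
                              subject_sigma = 0.1) {
  if (n_modules < 1) stop_invalid("n_modules must be >= 1")
  if (n_modules > n_muscles) {
    stop_invalid("n_modules (", n_modules, ") cannot exceed n_muscles (",
                 n_muscles, ")")
  }
  if (length(condition_labels) < 2) stop_invalid("need at least 2 condition labels")
  if (anyDuplicated(condition_labels)) stop_invalid("condition labels must be unique")
  if (length(profile_kinds) != n_modules) {
    stop_invalid("profile_kinds must name one kind per module")
  }
  bad <- setdiff(profile_kinds, PROFILE_KINDS)
  if (length(bad) > 0) {
    stop_invalid("unknown profile kind '", bad[1], "'; must be one of ",
                 paste(PROFILE_KINDS, collapse = ", "))
  }
  if (is.null(burst_centers)) {
    burst_centers <- if (n_modules == 4) c(0.05, 0.40, 0.60, 0.95)
                     else (2 * seq_len(n_modules) - 1) / (2 * n_modules)
  }
  if (length(burst_centers) != n_modules) {
    stop_invalid("burst_centers must have one entry per module")
  }

  with_seed(seed, {
    # spatial modules: contiguous dominant muscle blocks + weak background
    blocks <- split(seq_len(n_muscles),
                    sort(rep_len(seq_len(n_modules), n_muscles)))
    W <- matrix(runif(n_muscles * n_modules, 0, 0.08),
                n_muscles, n_modules)
    for (m in seq_len(n_modules)) {
      W[blocks[[m]], m] <- runif(length(blocks[[m]]), 0.6, 1)
    }
    W <- unitize_cols(W)

    phase <- (seq_len(n_bins) - 1) / n_bins
    C <- t(vapply(seq_len(n_modules), function(m) {
      exp(-(phase - burst_centers[m])^2 / (2 * burst_sd^2))
    }, numeric(n_bins)))
    C <- unitize_rows(C)

    gains <- vapply(profile_kinds, gain_profile,
                    numeric(length(condition_labels)),
                    n_conditions = length(condition_labels))
    gains <- t(gains)   # modules x conditions
    # Scale so the full-recruitment mixture peaks at 1: cycle matrices then
    # live on the scale of amplitude-normalized EMG (per-muscle peak ~ 1),
    # which is the scale the stated noise sd refers to.
    gains <- gains / max(W %*% C)
    dimnames(gains) <- list(NULL, condition_labels)

    scales <- array(exp(rnorm(n_muscles * n_modules * n_participants,
                              0, subject_sigma)),
                    dim = c(n_muscles, n_modules, n_participants))

    structure(list(n_muscles = n_muscles, n_bins = n_bins,
                   n_modules = n_modules,
                   n_participants = n_participants,
                   muscle_labels = default_muscles(n_muscles),
                   condition_labels = condition_labels,
                   profile_kinds = profile_kinds,
                   burst_centers = burst_centers,
                   W_true = W, C_true = C,
                   gain_profiles = gains,
                   participant_scales = scales,
                   noise_sd = noise_sd,
                   subject_sigma = subject_sigma,
                   seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", x$n_modules, " modules, ", x$n_muscles,
      " muscles x ", x$n_bins, " bins, ", x$n_participants,
      " participants, conditions: ",
      paste(x$condition_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Participant-specific spatial weightings: elementwise jitter, renormalized.
participant_weights <- function(gt, participant) {
  if (participant < 1 || participant > gt$n_participants) {
    stop_invalid("participant index out of range 1..", gt$n_participants)
  }
  unitize_cols(gt$W_true * gt$participant_scales[, , participant])
}

condition_index <- function(gt, condition) {
  idx <- match(condition, gt$condition_labels)
  if (is.na(idx)) {
    stop_invalid("unknown condition label '", condition, "'; expected one of ",
                 paste(gt$condition_labels, collapse = ", "))
  }
  idx
}

#' Generate one participant/condition cycle matrix
#'
#' Returns `max(0, W_p diag(gains) C + noise)` where `W_p` is the
#' participant's jittered spatial weighting, gains are the module gain
#' profile at `condition`, and the noise is i.i.d. Gaussian with sd
#' `noise_sd`, clipped at zero. Deterministic given all arguments.
#'
#' @param gt A [make_ground_truth()] object.
#' @param participant Participant index.
#' @param condition Condition label in `gt$condition_labels`.
#' @param seed Integer seed for the noise draw.
#' @param noise_sd Noise sd; defaults to `gt$noise_sd`.
#' @return A `cycle_matrix`; attribute `clip_fraction` reports the fraction
#'   of entries clipped at zero.
#' @export
generate_cycle_matrix <- function(gt, participant, condition, seed = 1,
                                  noise_sd = gt$noise_sd) {
  stopifnot(inherits(gt, "ground_truth"))
  ci <- condition_index(gt, condition)
  W_p <- participant_weights(gt, participant)
  expected <- W_p %*% diag(gt$gain_profiles[, ci], nrow = gt$n_modules) %*%
    gt$C_true
  if (noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, participant * 131L + ci * 17L),
                       matrix(rnorm(length(expected), 0, noise_sd),
                              nrow(expected), ncol(expected)))
    raw <- expected + noise
  } else {
    raw <- expected
  }
  values <- pmax(raw, 0)
  out <- cycle_matrix(values, muscle_labels = gt$muscle_labels,
                      participant = participant, condition = condition)
  attr(out, "clip_fraction") <- mean(raw < 0)
  out
}

#' Generate a raw synthetic EMG + kinematics trial
#'
#' Per channel, the broadband EMG is the participant's noiseless module
#' mixture (resampled to real time and tiled over cycles) multiplied by a
#' band-limited (100-400 Hz) zero-mean noise carrier scaled to unit mean
#' absolute value, so standard envelope conditioning recovers the mixture.
#' The limb elevation angle is a pure cosine whose maxima fall exactly on
#' the stored true contact samples.
#'
#' @param gt A [make_ground_truth()] object.
#' @param participant Participant index.
#' @param condition Condition label.
#' @param fs Sampling rate in Hz (>= 500 so the conditioning band exists).
#' @param cycle_duration Gait-cycle duration in seconds.
#' @param n_cycles Number of foot contacts simulated (>= 12, so 10
#'   analysable cycles remain once the edge cycles are discarded).
#' @param seed Integer seed for the carrier noise.
#' @return A `synthetic_raw_trial` with fields `emg`, `limb_angle`, `fs`,
#'   `cycle_duration`, `n_cycles`, `contact_samples_true`,
#'   `envelope_true`, `muscle_labels`.
#' @export
generate_raw_trial <- function(gt, participant, condition, fs = 1000,
                               cycle_duration = 1.0, n_cycles = 12,
                               seed = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  if (fs < 500) stop_invalid("fs must be >= 500 Hz; got ", fs)
  if (n_cycles < 12) stop_invalid("n_cycles must be >= 12; got ", n_cycles)
  ci <- condition_index(gt, condition)
  period <- round(fs * cycle_duration)
  n_samples <- n_cycles * period
  first_contact <- as.integer(floor(period / 2) + 1)
  contacts <- first_contact + (seq_len(n_cycles) - 1L) * as.integer(period)

  limb_angle <- 20 * cos(2 * pi * (seq_len(n_samples) - first_contact) /
                           period)

  W_p <- participant_weights(gt, participant)
  mix <- W_p %*% diag(gt$gain_profiles[, ci], nrow = gt$n_modules) %*%
    gt$C_true   # muscles x n_bins, one noiseless cycle

  phase <- ((seq_len(n_samples) - first_contact) %% period) / period
  bin_phase <- c((seq_len(gt$n_bins) - 1) / gt$n_bins, 1)
  env <- t(vapply(seq_len(gt$n_muscles), function(ch) {
    approx(bin_phase, c(mix[ch, ], mix[ch, 1]), xout = phase)$y
  }, numeric(n_samples)))

  emg <- with_seed(derive_seed(seed, participant * 977L + ci * 31L), {
    hp <- butter_coefficients(4, 100, fs, "high")
    lp <- butter_coefficients(4, min(400, 0.45 * fs), fs, "low")
    t(vapply(seq_len(gt$n_muscles), function(ch) {
      carrier <- rnorm(n_samples)
      carrier <- filtfilt_zero_phase(hp$b, hp$a, carrier)
      carrier <- filtfilt_zero_phase(lp$b, lp$a, carrier)
      carrier <- carrier / mean(abs(carrier))
      env[ch, ] * carrier
    }, numeric(n_samples)))
  })

  structure(list(emg = emg, limb_angle = limb_angle, fs = fs,
                 cycle_duration = cycle_duration, n_cycles = n_cycles,
                 contact_samples_true = contacts,
                 envelope_true = env,
                 muscle_labels = gt$muscle_labels,
                 participant = participant, condition = condition),
            class = "synthetic_raw_trial")
}

#' @export
print.synthetic_raw_trial <- function(x, ...) {
  cat("<synthetic_raw_trial> ", nrow(x$emg), " channels x ", ncol(x$emg),
      " samples @ ", x$fs, " Hz; ", x$n_cycles, " contacts\n", sep = "")
  invisible(x)
}
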