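test_that("Butterworth design is correct at its analytic anchors", {
  # |H| = 1/sqrt(2) at the corner, by construction of the prototype
  co <- butter_coefficients(4, 100, 1000, "high")
  hgain <- function(co, f, fs) {
    z <- exp(-1i * 2 * pi * f / fs)
    abs(sum(co$b * z^(seq_along(co$b) - 1)) /
          sum(co$a * z^(seq_along(co$a) - 1)))
  }
  expect_equal(hgain(co, 100, 1000), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(hgain(co, 500, 1000), 1, tolerance = 1e-9)
  lo <- butter_coefficients(4, 10, 1000, "low")
  expect_equal(hgain(lo, 1e-9, 1000), 1, tolerance = 1e-6)
  expect_error(butter_coefficients(4, 600, 1000, "low"),
               class = "gravisyn_invalid_argument")
})

test_that("zero-phase filtering introduces no lag on a slow sinusoid", {
  fs <- 1000
  t <- (0:4999) / fs
  x <- sin(2 * pi * 2 * t)
  lo <- butter_coefficients(4, 10, fs, "low")
  y <- filtfilt_zero_phase(lo$b, lo$a, x)
  mid <- 1000:4000
  expect_equal(y[mid], x[mid], tolerance = 1e-3)   # passband, no phase shift
})

test_that("condition_emg matches the rectified-sine oracle and edge cases", {
  fs <- 1000
  n <- 5000
  # all-zero input -> all-zero envelope
  expect_true(all(condition_emg(matrix(0, 2, n), fs = fs) == 0))
  # pure DC is removed by the high-pass/demean stages
  env_dc <- condition_emg(matrix(5, 1, n), fs = fs)
  expect_lt(max(abs(env_dc[1, 500:4500])), 1e-6)
  # 150 Hz unit sinusoid: mean envelope = (2A/pi) x filter gain, within 5%
  x <- sin(2 * pi * 150 * (0:(n - 1)) / fs)
  env <- condition_emg(matrix(x, 1), fs = fs)
  expect_equal(mean(env[1, 2000:3000]), 2 / pi, tolerance = 0.05)
  # envelopes are nonnegative
  expect_true(all(env >= 0))
  expect_error(condition_emg(matrix(rnorm(100), 1), fs = 200),
               class = "gravisyn_invalid_argument")
  expect_error(condition_emg(matrix(c(rnorm(999), NA), 1), fs = 1000),
               class = "gravisyn_invalid_argument")
})

test_that("foot-contact detection finds sine maxima and rejects flat input", {
  fs <- 100
  ang <- sin(2 * pi * (0:299) / fs)   # maxima at samples 26, 126, 226 (1-based)
  ev <- detect_foot_contacts(ang, fs = fs)
  expect_identical(ev$contact_samples, c(26L, 126L, 226L))
  expect_error(detect_foot_contacts(rep(1, 300), fs = fs),
               class = "gravisyn_insufficient_data")
})

test_that("elevation angle convention puts contact at forward limb extension", {
  fs <- 100
  t <- (0:299) / fs
  # pendulum: malleolus swings anterior (+x) of the trochanter periodically
  gt_xy <- cbind(0, 1 + 0 * t)
  lm_xy <- cbind(0.5 * sin(2 * pi * t), 1 - 0.8)
  track <- limb_axis_track(gt_xy, lm_xy, fs)
  ang <- limb_elevation_angle(track)
  expect_equal(which.max(ang[1:100]), 26)   # max elevation when LM most anterior
  ev <- detect_foot_contacts(track)
  expect_identical(ev$contact_samples, c(26L, 126L, 226L))
})

test_that("segmentation interpolates exactly and enforces cycle counts", {
  # constant envelope: every bin equals the constant
  env <- matrix(2.5, 1, 1300)
  events <- seq(1, 1300, by = 100)   # 12 complete cycles
  seg <- segment_and_normalize(env, events, n_bins = 200, n_cycles = 10)
  expect_true(all(abs(seg$average - 2.5) < 1e-12))
  expect_identical(dim(seg$average), c(1L, 200L))

  # envelope linear in time -> bins linear in bin index (closed form)
  env2 <- matrix(seq_len(1300), 1, 1300)
  seg2 <- segment_and_normalize(env2, events, n_bins = 200, n_cycles = 1)
  cyc <- seg2$cycles[1, , 1]
  start <- events[seg2$cycle_indices]
  oracle <- start + (seq_len(200) - 1) / 200 * 100
  expect_equal(cyc, oracle, tolerance = 1e-12)
  expect_true(all(abs(diff(diff(cyc))) < 1e-9))

  # 9 available cycles cannot provide 10
  expect_error(segment_and_normalize(env[, 1:1000, drop = FALSE],
                                     seq(1, 1000, by = 100), n_cycles = 10),
               class = "gravisyn_insufficient_data")
})

test_that("amplitude normalization follows the min/shared-max rule and is idempotent", {
  m1 <- cycle_matrix(rbind(c(2, 4, 6), c(1, 1, 2)), c("A", "B"))
  out1 <- normalize_amplitude(list(m1))
  expect_equal(out1[[1]]$values["A", ], c(0, 0.5, 1), ignore_attr = TRUE)

  # two conditions: muscle ranges 1 and 2 -> condition-1 peak maps to 0.5
  a <- cycle_matrix(matrix(c(0, 1, 0.5), 1), "A")
  b <- cycle_matrix(matrix(c(0, 2, 1), 1), "A")
  out2 <- normalize_amplitude(list(a, b))
  expect_equal(max(out2[[1]]$values), 0.5)
  expect_equal(max(out2[[2]]$values), 1)

  # idempotence
  once <- normalize_amplitude(list(m1))
  twice <- normalize_amplitude(once)
  expect_equal(twice[[1]]$values, once[[1]]$values, tolerance = 1e-12)

  expect_error(normalize_amplitude(list(cycle_matrix(matrix(3, 2, 4),
                                                     c("A", "B")))),
               class = "gravisyn_degenerate_input")
})

test_that("unit-variance scaling is exact and invertible", {
  m <- matrix(c(0, 1, 0, 1, 0, 1, 2, 0, 2, 0, 2, 0), 2, 6, byrow = TRUE)
  sc <- scale_unit_variance(m)
  pop_var <- function(x) mean((x - mean(x))^2)
  expect_equal(apply(sc$values, 1, pop_var), c(1, 1), tolerance = 1e-12)
  back <- unscale_unit_variance(sc$values, sc$scales)
  expect_equal(back, m, tolerance = 1e-12)
  expect_error(scale_unit_variance(rbind(m[1, ], 0)),
               class = "gravisyn_degenerate_input")
})

test_that("Froude utilities obey the scaling law and invert exactly", {
  # exact sqrt scaling across gravity ratios, any leg length
  for (r in c(0.07, 0.16, 0.38, 0.6, 1)) {
    v1 <- froude_speed(0.9, 9.81)$v_mps
    vr <- froude_speed(0.9, 9.81 * r)$v_mps
    expect_equal(vr / v1, sqrt(r), tolerance = 1e-12)
  }
  expect_equal(froude_scaled_speed(5.05, 1), 5.05)
  v <- froude_speed(0.85, 9.81, 0.25)$v_mps
  expect_equal(fr_number(v, 9.81, 0.85), 0.25, tolerance = 1e-12)
  expect_error(froude_speed(-1, 9.81), class = "gravisyn_invalid_argument")
})

test_that("net-load proxy matches closed forms", {
  # at Fr = 0.25 exactly, load = 0.75 m g
  g <- 9.81; L <- 0.85; m <- 70
  v <- sqrt(0.25 * g * L)
  expect_equal(net_load_proxy(m, g, v, L), 0.75 * m * g, tolerance = 1e-12)
  expect_equal(net_load_proxy(m, g, sqrt(g * L), L), 0, tolerance = 1e-9)
  # hand evaluation of m (g - v^2/L)
  expect_equal(net_load_proxy(64.4, 9.81, 1.403, 0.80),
               64.4 * (9.81 - 1.403^2 / 0.80))
  # above sqrt(gL) the proxy goes negative and is returned as-is
  expect_lt(net_load_proxy(m, g, 1.1 * sqrt(g * L), L), 0)
})

test_that("preprocessing a synthetic trial recovers truth end to end", {
  gt <- make_gt(31)
  tr <- generate_raw_trial(gt, 2, "0.6g", fs = 1000, cycle_duration = 1,
                           n_cycles = 12, seed = 4)
  ev <- detect_foot_contacts(tr$limb_angle, fs = tr$fs)
  expect_length(ev$contact_samples, length(tr$contact_samples_true))
  expect_lte(max(abs(ev$contact_samples - tr$contact_samples_true)), 5)

  env <- condition_emg(tr$emg, fs = tr$fs)
  seg <- segment_and_normalize(env, ev)
  got <- normalize_amplitude(list(cycle_matrix(seg$average)))[[1]]
  oracle <- normalize_amplitude(
    list(generate_cycle_matrix(gt, 2, "0.6g", noise_sd = 0)))[[1]]
  expect_gte(vaf(oracle, got), 90)
})
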