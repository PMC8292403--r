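test_that("ground truth satisfies its structural invariants", {
  gt <- make_gt(1)
  expect_equal(sqrt(colSums(gt$W_true^2)), rep(1, 4), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(gt$C_true^2)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(gt$W_true >= 0) && all(gt$C_true >= 0))
  expect_true(all(gt$gain_profiles >= 0))
  expect_identical(colnames(gt$gain_profiles), GRAVITY5)

  # u-shaped: high at both gravity extremes, minimum at the middle level
  u <- gt$gain_profiles[4, ]
  expect_gt(u["1g"], u["0.38g"])
  expect_gt(u["0.07g"], u["0.38g"])
  # linear decrease is strictly monotone over the ordered labels
  expect_true(all(diff(gt$gain_profiles[2, ]) < 0))
  # threshold: flat plateau then decrease
  th <- gt$gain_profiles[3, ]
  expect_equal(th[["1g"]], th[["0.6g"]])
  expect_true(all(diff(th[-1]) < 0))
})

test_that("ground truth construction validates its arguments", {
  expect_error(make_ground_truth(n_modules = 13, profile_kinds = rep("constant", 13)),
               class = "gravisyn_invalid_argument")
  expect_error(make_ground_truth(profile_kinds = c("constant", "bogus",
                                                   "constant", "constant")),
               class = "gravisyn_invalid_argument")
  gt1 <- make_ground_truth(n_modules = 1, condition_labels = c("a", "b"),
                           profile_kinds = "constant", seed = 0)
  expect_equal(unname(gt1$gain_profiles[1, "a"]),
               unname(gt1$gain_profiles[1, "b"]))
})

test_that("cycle matrices follow the generative model and are reproducible", {
  gt <- make_gt(2, subject_sigma = 0)
  # noiseless, no jitter: exactly W diag(g) C
  m0 <- generate_cycle_matrix(gt, 1, "0.38g", noise_sd = 0)
  expected <- gt$W_true %*% diag(gt$gain_profiles[, "0.38g"]) %*% gt$C_true
  expect_equal(m0$values, expected, ignore_attr = TRUE)

  # zero gains give the zero matrix
  gt0 <- make_gt(2)
  gt0$gain_profiles[] <- 0
  expect_true(all(generate_cycle_matrix(gt0, 1, "1g", noise_sd = 0)$values == 0))

  # determinism and nonnegativity with noise
  gt2 <- make_gt(3)
  a <- generate_cycle_matrix(gt2, 4, "0.16g", seed = 9)
  b <- generate_cycle_matrix(gt2, 4, "0.16g", seed = 9)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0))
  c2 <- generate_cycle_matrix(gt2, 4, "0.16g", seed = 10)
  expect_false(identical(a$values, c2$values))

  expect_error(generate_cycle_matrix(gt2, 1, "2g"),
               class = "gravisyn_invalid_argument")
})

test_that("generated matrices are refit at the true rank with high VAF", {
  gt <- make_gt(4)
  m <- generate_cycle_matrix(gt, 2, "1g", seed = 1)   # noise_sd 0.02
  ms <- nmf_extract(m, 4, n_restarts = 5, seed = 1)
  expect_gte(ms$vaf, 95)
})

test_that("raw trials have exact contact geometry and envelope structure", {
  gt <- make_gt(5)
  tr <- generate_raw_trial(gt, 1, "1g", fs = 1000, cycle_duration = 1,
                           n_cycles = 12, seed = 2)
  expect_equal(ncol(tr$emg), length(tr$limb_angle))
  expect_length(tr$contact_samples_true, 12)
  expect_equal(unique(diff(tr$contact_samples_true)), 1000)

  # limb angle has exactly n_cycles local maxima, at the true contacts
  ang <- tr$limb_angle
  n <- length(ang)
  peaks <- which(c(FALSE, ang[2:(n - 1)] > ang[1:(n - 2)] &
                     ang[2:(n - 1)] >= ang[3:n], FALSE))
  expect_identical(as.integer(peaks), tr$contact_samples_true)

  # zero-gain ground truth produces identically zero EMG
  gt0 <- make_gt(5)
  gt0$gain_profiles[] <- 0
  tr0 <- generate_raw_trial(gt0, 1, "1g", seed = 2)
  expect_true(all(tr0$emg == 0))

  expect_error(generate_raw_trial(gt, 1, "1g", fs = 400),
               class = "gravisyn_invalid_argument")
  expect_error(generate_raw_trial(gt, 1, "1g", n_cycles = 8),
               class = "gravisyn_invalid_argument")

  # reproducibility of the full trial
  tr2 <- generate_raw_trial(gt, 1, "1g", fs = 1000, cycle_duration = 1,
                            n_cycles = 12, seed = 2)
  expect_identical(tr$emg, tr2$emg)
})

test_that("downstream NMF recovers the true spatial modules across participants", {
  # the generator's raison d'etre: parameter recovery at low noise
  gt <- make_gt(6)
  for (p in 1:5) {
    m <- generate_cycle_matrix(gt, p, "1g", seed = p)
    sc <- scale_unit_variance(m)
    ms <- nmf_extract(sc$values, 4, n_restarts = 5, seed = p)
    w <- unscale_unit_variance(ms$W, sc$scales)
    mr <- match_modules(w, gt$W_true, metric = "cosine")
    expect_true(all(mr$pairs$similarity >= 0.90),
                label = paste("participant", p, "cosines",
                              paste(round(mr$pairs$similarity, 3),
                                    collapse = " ")))
  }
})
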