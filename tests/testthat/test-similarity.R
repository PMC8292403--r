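test_that("similarity metrics match hand-computed anchors", {
  expect_equal(cosine_similarity(c(1, 0, 0), c(1, 0, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)),
               class = "gravisyn_invalid_argument")

  a <- c(1, 2, 3)
  expect_equal(pearson_correlation(a, a), 1)
  expect_equal(pearson_correlation(a, -a), -1)
  # hand computation: r = 3 / (sqrt(2) * sqrt(14/3))
  expect_equal(pearson_correlation(a, c(1, 2, 4)),
               3 / (sqrt(2) * sqrt(14 / 3)), tolerance = 1e-12)
  expect_error(pearson_correlation(a, c(2, 2, 2)),
               class = "gravisyn_invalid_argument")
})

test_that("cosine similarity of nonnegative vectors stays in [0, 1]", {
  set.seed(9)
  for (i in 1:50) {
    s <- cosine_similarity(runif(12), runif(12))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("module matching recovers permutations and beats greedy", {
  set.seed(10)
  a <- matrix(runif(12 * 4), 12, 4)
  perm <- c(3, 1, 4, 2)
  mr <- match_modules(a, a[, perm], metric = "cosine")
  expect_equal(mr$pairs$similarity, rep(1, 4), tolerance = 1e-12)
  expect_identical(order(perm), mr$pairs$b[order(mr$pairs$a)])
  expect_equal(mr$overall_median, 1)

  # singleton sets give a single pair
  expect_identical(nrow(match_modules(a[, 1], a[, 2])$pairs), 1L)

  # constructed case where greedy matching is suboptimal
  s <- rbind(c(0.9, 0.8, 0.0),
             c(0.85, 0.7, 0.0),
             c(0.0, 0.6, 0.3))
  # greedy (pick global max first): 0.9 + 0.7 + 0.3 = 1.9
  # optimal: 0.85 + 0.8 + 0.3 = 1.95
  pairs <- gravisyn:::assignment_max(s)
  expect_equal(sum(s[pairs]), 1.95)
  expect_equal(sum(s[pairs]), oracle_assignment_value(s))
})

test_that("matching equals exhaustive search on random instances", {
  set.seed(11)
  for (rep in 1:20) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    s <- matrix(runif(nr * nc), nr, nc)
    pairs <- gravisyn:::assignment_max(s)
    expect_identical(nrow(pairs), as.integer(min(nr, nc)))
    expect_false(anyDuplicated(pairs[, 2]) > 0)
    expect_equal(sum(s[pairs]), oracle_assignment_value(s), tolerance = 1e-12)
  }
})

test_that("unequal set sizes report unmatched leftovers", {
  set.seed(12)
  a <- matrix(runif(12 * 4), 12, 4)
  mr <- match_modules(a, a[, 1:3], metric = "cosine")
  expect_identical(nrow(mr$pairs), 3L)
  expect_length(mr$unmatched_a, 1)
  expect_length(mr$unmatched_b, 0)
  expect_error(match_modules(a[, 0], a), class = "gravisyn_invalid_argument")
})

test_that("bootstrap chance level matches trivial pools and is seeded", {
  ident <- matrix(rep(runit(12), 5), 12, 5)
  ch <- bootstrap_chance_level(ident, n_boot = 500, seed = 1)
  expect_equal(ch$lower_bound, 1, tolerance = 1e-12)

  basis <- diag(12)
  ch0 <- bootstrap_chance_level(basis, n_boot = 500, seed = 1)
  expect_equal(ch0$lower_bound, 0, tolerance = 1e-12)

  set.seed(13)
  pool <- matrix(runif(12 * 20), 12, 20)
  a <- bootstrap_chance_level(pool, n_boot = 2000, seed = 5)
  b <- bootstrap_chance_level(pool, n_boot = 2000, seed = 5)
  expect_identical(a$lower_bound, b$lower_bound)
  expect_error(bootstrap_chance_level(pool[, 1, drop = FALSE]),
               class = "gravisyn_invalid_argument")
})

test_that("NNLS reconstruction is exact in-span and KKT-clean out of span", {
  # identity basis: coefficients equal the target
  target <- c(0.3, 0, 1.2, 0.5)
  fit <- nnls_reconstruct(target, diag(4))
  expect_equal(drop(fit$F), target, tolerance = 1e-10)
  expect_equal(fit$vaf[1], 100, tolerance = 1e-9)

  # orthogonal target: zero coefficients, zero VAF
  basis <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  fit0 <- nnls_reconstruct(c(0, 0, 1, 0), basis)
  expect_equal(drop(fit0$F), c(0, 0))
  expect_equal(fit0$vaf[1], 0)

  # in-span combination recovered exactly
  set.seed(99)
  b1 <- runit(6); b2 <- abs(b1 + rnorm(6)); b2 <- b2 / sqrt(sum(b2^2))
  tgt <- 0.3 * b1 + 0.7 * b2
  fit2 <- nnls_reconstruct(tgt, cbind(b1, b2))
  expect_equal(drop(fit2$F), c(0.3, 0.7), tolerance = 1e-8)

  expect_error(nnls_reconstruct(c(1, 2), diag(3)),
               class = "gravisyn_invalid_argument")
})

test_that("NNLS satisfies the KKT conditions on random problems", {
  set.seed(14)
  for (rep in 1:20) {
    a <- matrix(rnorm(10 * 4), 10, 4)
    b <- rnorm(10)
    f <- gravisyn:::nnls_solve(a, b)
    grad <- drop(crossprod(a, b - a %*% f))
    expect_true(all(f >= 0))
    expect_true(all(grad[f == 0] <= 1e-8))
    expect_true(all(abs(grad[f > 0]) <= 1e-8))
  }
})
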