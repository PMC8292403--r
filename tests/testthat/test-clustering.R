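test_that("spherical k-means recovers well-separated direction groups", {
  set.seed(1)
  d1 <- runit(12); d2 <- abs(d1 + rnorm(12, 0, 2)); d2 <- d2 / sqrt(sum(d2^2))
  # force near-orthogonality by zeroing overlap
  d2[d1 > 0.3] <- 0; d2 <- d2 / sqrt(sum(d2^2))
  pool <- noisy_direction_pool(rbind(d1, d2), n_per = 10, noise = 0.01)
  res <- spherical_kmeans(pool$vectors, 2, n_init = 10, seed = 2)
  expect_true(same_partition(res$assignments, pool$membership))
  expect_equal(sqrt(rowSums(res$centroids^2)), rep(1, 2), tolerance = 1e-9)

  res2 <- spherical_kmeans(pool$vectors, 2, n_init = 10, seed = 2)
  expect_identical(res$assignments, res2$assignments)   # same seed
})

test_that("degenerate k = n_items clustering is flagged with silhouette 0", {
  set.seed(2)
  x <- t(replicate(5, runit(8)))
  res <- spherical_kmeans(x, 5, seed = 1)
  expect_identical(res$assignments, 1:5)
  expect_identical(res$mean_silhouette, 0)
  expect_true(res$degenerate)
  expect_error(spherical_kmeans(x, 6), class = "gravisyn_invalid_argument")
})

test_that("within-participant de-duplication keeps the nearest module", {
  # participant A contributes 3 modules to cluster 1 at known distances
  set.seed(33)
  base <- runit(6)
  v1 <- base
  v2 <- pmax(base + 0.1, 0); v2 <- v2 / sqrt(sum(v2^2))
  v3 <- pmax(base + 0.4, 0); v3 <- v3 / sqrt(sum(v3^2))
  other <- c(0, 0, 0, 0, 0, 1)
  pool <- module_pool(rbind(v1, v2, v3, other),
                      participant = c("A", "A", "A", "B"))
  res <- spherical_kmeans(pool, 2, n_init = 10, seed = 3)
  res2 <- dedupe_within_participant(res, pool)
  grp <- which(res$assignments == res$assignments[1])
  expect_setequal(grp, 1:3)
  # exactly one of A's co-clustered modules retained: the closest (enumerate)
  cent <- res$centroids[res$assignments[1], ]
  dists <- apply(pool$vectors[1:3, ], 1, function(v) sqrt(sum((v - cent)^2)))
  expect_identical(unname(which(!res2$excluded[1:3])),
                   unname(which.min(dists)))
  expect_false(res2$excluded[4])

  # all-unique participants: unchanged
  pool_u <- module_pool(rbind(v1, other), participant = c("A", "B"))
  res_u <- spherical_kmeans(pool_u, 2, n_init = 5, seed = 1)
  expect_identical(dedupe_within_participant(res_u, pool_u)$excluded,
                   c(FALSE, FALSE))
})

test_that("representatives are normalized means of retained members", {
  v1 <- c(1, 0, 0, 0); v2 <- c(0.8, 0.6, 0, 0); v3 <- c(0, 0, 0, 1)
  pool <- module_pool(rbind(v1, v2, v3), participant = c("A", "B", "C"))
  res <- spherical_kmeans(pool, 2, n_init = 10, seed = 1)
  reps <- representative_modules(res, pool)
  two <- which(table(res$assignments) == 2)
  mid <- colMeans(rbind(v1, v2))
  expect_equal(sort(reps[two, ]), sort(mid / sqrt(sum(mid^2))),
               tolerance = 1e-9)
  single <- which(table(res$assignments) == 1)
  expect_equal(sort(reps[single, ]), sort(v3), tolerance = 1e-9)
})

test_that("constrained clustering honours cannot-link groups exactly", {
  # 5 gravity levels x 4 shared directions
  set.seed(4)
  gt <- make_gt(41)
  dirs <- t(gt$W_true)
  vectors <- NULL; gravity <- NULL; truth <- NULL
  for (g in GRAVITY5) {
    p <- noisy_direction_pool(dirs, n_per = 1, noise = 0.02)
    vectors <- rbind(vectors, p$vectors)
    gravity <- c(gravity, rep(g, 4))
    truth <- c(truth, p$membership)
  }
  pool <- module_pool(vectors, gravity = gravity)
  res <- constrained_kmeans(pool, 4, n_init = 20, seed = 5)
  expect_true(res$feasible)
  expect_identical(res$constraint_violations, 0L)
  # each cluster holds exactly one module per gravity level
  expect_true(all(table(res$assignments, gravity) == 1))
  expect_true(same_partition(res$assignments, truth))

  # pigeonhole infeasibility is an outcome, not an error
  inf <- constrained_kmeans(pool, 3, n_init = 5, seed = 1)
  expect_false(inf$feasible)
  expect_identical(inf$mean_silhouette, 0)

  # without constraints the problem reduces to spherical k-means
  pool1 <- module_pool(vectors, gravity = seq_len(nrow(vectors)))
  r1 <- constrained_kmeans(pool1, 4, n_init = 20, seed = 6)
  r2 <- spherical_kmeans(pool1, 4, n_init = 20, seed = 6)
  expect_true(same_partition(r1$assignments, r2$assignments))
})

test_that("silhouette-based k selection finds the group count", {
  set.seed(5)
  dirs <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0, 0, 0),
                c(0, 0, 0, 0, 1, 0, 0, 0), c(0, 0, 0, 0, 0, 0, 1, 0))
  p4 <- noisy_direction_pool(dirs, n_per = 6, noise = 0.02)
  sel4 <- select_k_by_silhouette(p4$vectors, k_range = 2:8, n_init = 10,
                                 seed = 7)
  expect_identical(sel4$k_best, 4L)
  expect_gt(max(sel4$table$mean_silhouette), 0.7)
  expect_true(all(abs(sel4$table$mean_silhouette) <= 1))

  p2 <- noisy_direction_pool(dirs[1:2, ], n_per = 8, noise = 0.02)
  sel2 <- select_k_by_silhouette(p2$vectors, k_range = 2:6, n_init = 10,
                                 seed = 8)
  expect_identical(sel2$k_best, 2L)
})
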