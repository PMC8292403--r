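# Similarity metrics, optimal one-to-one module matching, bootstrap
# chance levels, and NNLS reconstruction of clustered modules from CP
# factor components.

#' Cosine similarity of two vectors
#' @param a,b Numeric vectors of equal length, neither all zero.
#' @return `dot(a, b) / (||a|| ||b||)`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_invalid("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Centred Pearson correlation of two vectors
#' @param a,b Numeric vectors of equal length with positive variance.
#' @return Pearson r.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("length mismatch")
  if (sd(a) == 0 || sd(b) == 0) {
    stop_invalid("correlation undefined for a constant vector")
  }
  cor(a, b)
}

similarity_fun <- function(metric = c("cosine", "correlation")) {
  metric <- match.arg(metric)
  if (metric == "cosine") cosine_similarity else pearson_correlation
}

# Exact maximum-weight one-to-one assignment by bitmask dynamic
# programming over the smaller side (fine for module counts; capped to
# keep memory bounded).
assignment_max <- function(s) {
  transposed <- FALSE
  if (nrow(s) > ncol(s)) { s <- t(s); transposed <- TRUE }
  nr <- nrow(s); nc <- ncol(s)
  if (nc > 20) stop_invalid("assignment limited to 20 items per side")
  n_mask <- bitwShiftL(1L, nc)
  dp <- rep(-Inf, n_mask); dp[1] <- 0
  popcnt <- vapply(0:(n_mask - 1), function(m) {
    sum(bitwAnd(m, bitwShiftL(1L, 0:(nc - 1))) != 0)
  }, numeric(1))
  for (m in order(popcnt)) {
    mask <- m - 1L
    row <- popcnt[m] + 1
    if (row > nr || !is.finite(dp[m])) next
    for (j in seq_len(nc)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0) next
      nm <- bitwOr(mask, bit) + 1L
      val <- dp[m] + s[row, j]
      if (val > dp[nm]) dp[nm] <- val
    }
  }
  assign <- assignment_backtrack(s, dp, popcnt)
  if (transposed) {
    pairs <- cbind(assign, seq_len(nr))
  } else {
    pairs <- cbind(seq_len(nr), assign)
  }
  pairs[order(pairs[, 1]), , drop = FALSE]
}

# Deterministic re-derivation of one optimal path from the filled dp table.
assignment_backtrack <- function(s, dp, popcnt) {
  nr <- nrow(s); nc <- ncol(s)
  full <- which(popcnt == nr & is.finite(dp))
  mask <- full[which.max(dp[full])] - 1L
  assign <- integer(nr)
  for (row in seq(nr, 1)) {
    for (j in seq_len(nc)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0) next
      pm <- mask - bit
      if (is.finite(dp[pm + 1L]) &&
          isTRUE(all.equal(dp[pm + 1L] + s[row, j], dp[mask + 1L]))) {
        assign[row] <- j
        mask <- pm
        break
      }
    }
  }
  assign
}

#' Match two module sets one-to-one by maximal total similarity
#'
#' Solves the optimal (global, not greedy) assignment between the columns
#' of `set_a` and `set_b` under the chosen metric; when the sets differ in
#' size the leftovers are reported unmatched and excluded from the median.
#'
#' @param set_a,set_b Matrices with one module per column (vectors are
#'   treated as single modules).
#' @param metric `"cosine"` or `"correlation"`.
#' @return A `match_result`: `pairs` (data.frame `a`, `b`, `similarity`),
#'   `overall_median`, `unmatched_a`, `unmatched_b`, `metric`.
#' @export
match_modules <- function(set_a, set_b, metric = c("cosine", "correlation")) {
  metric <- match.arg(metric)
  a <- as.matrix(set_a); b <- as.matrix(set_b)
  if (ncol(a) == 0 || ncol(b) == 0) stop_invalid("empty module set")
  fun <- similarity_fun(metric)
  s <- outer(seq_len(ncol(a)), seq_len(ncol(b)),
             Vectorize(function(i, j) fun(a[, i], b[, j])))
  s <- matrix(s, ncol(a), ncol(b))
  pairs <- assignment_max(s)
  sims <- s[pairs]
  structure(list(pairs = data.frame(a = pairs[, 1], b = pairs[, 2],
                                    similarity = sims),
                 overall_median = median(sims),
                 unmatched_a = setdiff(seq_len(ncol(a)), pairs[, 1]),
                 unmatched_b = setdiff(seq_len(ncol(b)), pairs[, 2]),
                 metric = metric),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " pairs (", x$metric,
      "), median similarity = ",
      formatC(x$overall_median, digits = 3, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Bootstrap chance level of a similarity metric
#'
#' Per round, two vectors are drawn independently with replacement from
#' the pool (re-drawing when the same item is picked twice) and the metric
#' recomputed; the chance level is the lower bound of the central 95%
#' interval, i.e. the `alpha/2` percentile of the bootstrap distribution.
#'
#' @param pool Matrix with one vector per column (>= 2 columns).
#' @param metric `"cosine"` or `"correlation"`.
#' @param n_boot Bootstrap rounds (default 10000).
#' @param alpha Interval level complement (default 0.05).
#' @param seed Integer seed.
#' @return A `chance_level`: `lower_bound`, `n_boot`, `alpha`, `metric`,
#'   `samples` (the bootstrap metric values).
#' @export
bootstrap_chance_level <- function(pool, metric = c("cosine", "correlation"),
                                   n_boot = 10000, alpha = 0.05, seed = 1) {
  metric <- match.arg(metric)
  pool <- as.matrix(pool)
  n <- ncol(pool)
  if (n < 2) stop_invalid("need at least 2 vectors in the pool")
  fun <- similarity_fun(metric)
  sims <- with_seed(seed, {
    i <- sample.int(n, n_boot, replace = TRUE)
    j <- sample.int(n, n_boot, replace = TRUE)
    while (any(same <- i == j)) {
      j[same] <- sample.int(n, sum(same), replace = TRUE)
    }
    vapply(seq_len(n_boot), function(r) fun(pool[, i[r]], pool[, j[r]]),
           numeric(1))
  })
  structure(list(lower_bound = unname(quantile(sims, alpha / 2)),
                 n_boot = n_boot, alpha = alpha, metric = metric,
                 samples = sims),
            class = "chance_level")
}

#' @export
print.chance_level <- function(x, ...) {
  cat("<chance_level> ", x$metric, " lower bound of ",
      100 * (1 - x$alpha), "% CI = ",
      formatC(x$lower_bound, digits = 4, format = "f"),
      " (", x$n_boot, " resamples)\n", sep = "")
  invisible(x)
}

# Lawson-Hanson active-set nonnegative least squares for a single target.
nnls_solve <- function(a, b, tol = NULL) {
  m <- ncol(a)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(a)) * max(dim(a))
  passive <- rep(FALSE, m)
  x <- rep(0, m)
  w <- drop(crossprod(a, b - a %*% x))
  iter <- 0
  while (any(!passive) && any(w[!passive] > tol) && iter < 30 * m) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- rep(0, m)
      ap <- a[, passive, drop = FALSE]
      s[passive] <- drop(solve(crossprod(ap), crossprod(ap, b)))
      if (all(s[passive] > 0)) break
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    x <- s
    w <- drop(crossprod(a, b - a %*% x))
  }
  x
}

#' Reconstruct clustered modules from CP factor components by NNLS
#'
#' Models each target module as a nonnegative linear combination of the
#' basis columns (e.g. SPc modules from the spatial CP components),
#' solving `min ||target - basis f||^2, f >= 0` per target, and reports
#' the per-target VAF of the reconstruction.
#'
#' @param targets Matrix with one target module per column (vectors ok).
#' @param basis Matrix with one basis component per column.
#' @return A `cross_model_fit`: `F` (targets x basis coefficients), `vaf`
#'   per target, `fitted`.
#' @export
nnls_reconstruct <- function(targets, basis) {
  targets <- as.matrix(targets); basis <- as.matrix(basis)
  if (nrow(targets) != nrow(basis)) stop_invalid("dimension mismatch")
  if (ncol(basis) < 1) stop_invalid("basis must have at least one column")
  f <- t(vapply(seq_len(ncol(targets)), function(i) {
    nnls_solve(basis, targets[, i])
  }, numeric(ncol(basis))))
  f <- matrix(f, ncol(targets), ncol(basis))
  fitted <- basis %*% t(f)
  vafs <- vapply(seq_len(ncol(targets)), function(i) {
    tot <- sum(targets[, i]^2)
    if (tot == 0) return(NA_real_)
    100 * (1 - sum((targets[, i] - fitted[, i])^2) / tot)
  }, numeric(1))
  structure(list(F = f, vaf = vafs, fitted = fitted),
            class = "cross_model_fit")
}
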