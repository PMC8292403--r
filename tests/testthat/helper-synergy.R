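# Shared fixtures and independent oracles. Oracles are deliberately
# written in the most naive way possible (enumeration / plain loops) and
# never call the code paths they check.

GRAVITY5 <- c("1g", "0.6g", "0.38g", "0.16g", "0.07g")
KINDS4 <- c("constant", "linear_decreasing", "threshold_decreasing",
            "u_shaped")

make_gt <- function(seed, ...) {
  make_ground_truth(n_modules = 4, condition_labels = GRAVITY5,
                    profile_kinds = KINDS4, seed = seed, ...)
}

# Exhaustive maximum-similarity one-to-one assignment (permutation
# enumeration over the smaller side).
oracle_assignment_value <- function(s) {
  if (nrow(s) > ncol(s)) s <- t(s)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(ncol(s)))) {
    tot <- sum(s[cbind(seq_len(nrow(s)), p[seq_len(nrow(s))])])
    if (tot > best) best <- tot
  }
  best
}

# Plain-loop bootstrap chance level: independent sampling scheme and
# explicit metric arithmetic.
oracle_chance_level <- function(pool, n_boot, alpha, seed) {
  set.seed(seed)
  n <- ncol(pool)
  sims <- numeric(n_boot)
  for (r in seq_len(n_boot)) {
    repeat {
      i <- sample.int(n, 1); j <- sample.int(n, 1)
      if (i != j) break
    }
    a <- pool[, i]; b <- pool[, j]
    sims[r] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  unname(quantile(sims, alpha / 2))
}

# Random nonnegative unit vector
runit <- function(d) {
  v <- runif(d)
  v / sqrt(sum(v^2))
}

# Pool of n noisy copies of each row of `directions` (items x dim),
# nonnegative, unit-norm.
noisy_direction_pool <- function(directions, n_per, noise = 0.02) {
  out <- NULL
  memb <- integer(0)
  for (i in seq_len(nrow(directions))) {
    for (r in seq_len(n_per)) {
      v <- pmax(directions[i, ] + rnorm(ncol(directions), 0, noise), 0)
      out <- rbind(out, v / sqrt(sum(v^2)))
      memb <- c(memb, i)
    }
  }
  list(vectors = out, membership = memb)
}

# Agreement of two partitions up to label permutation.
same_partition <- function(a, b) {
  key <- function(z) {
    sort(unname(vapply(split(seq_along(z), z), function(ix) {
      paste(sort(ix), collapse = ",")
    }, character(1))))
  }
  identical(key(a), key(b))
}
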