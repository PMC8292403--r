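# Cosine k-means clustering of modules across participants, within-
# participant de-duplication, cluster representatives (SPc / TEc), and the
# cannot-link constrained variant used across gravity levels. Silhouettes
# (cosine distance) select the number of clusters over 2..10.

#' Pool of unit-norm module vectors with item labels
#'
#' Rows are modules; they are Euclidean-normalized on construction.
#'
#' @param vectors Nonnegative items x dim matrix.
#' @param participant,gravity,module Per-item labels (recycled scalars ok).
#' @param kind `"spatial"` or `"temporal"`.
#' @return A `module_pool` object with `vectors` and data.frame `items`.
#' @export
module_pool <- function(vectors, participant = NA, gravity = NA,
                        module = seq_len(nrow(vectors)),
                        kind = "spatial") {
  vectors <- as.matrix(vectors)
  if (any(vectors < 0)) stop_invalid("module vectors must be nonnegative")
  if (any(rowSums(vectors) == 0)) stop_invalid("zero module vector in pool")
  vectors <- unitize_rows(vectors)
  n <- nrow(vectors)
  items <- data.frame(participant = rep_len(participant, n),
                      gravity = rep_len(gravity, n),
                      module = rep_len(module, n),
                      kind = rep_len(kind, n))
  structure(list(vectors = vectors, items = items), class = "module_pool")
}

#' Concatenate module pools
#' @param ... `module_pool` objects.
#' @return A single `module_pool`.
#' @export
bind_pools <- function(...) {
  pools <- list(...)
  if (length(pools) == 1 && is.list(pools[[1]]) &&
      !inherits(pools[[1]], "module_pool")) {
    pools <- pools[[1]]
  }
  stopifnot(all(vapply(pools, inherits, logical(1), "module_pool")))
  out <- list(vectors = do.call(rbind, lapply(pools, `[[`, "vectors")),
              items = do.call(rbind, lapply(pools, `[[`, "items")))
  structure(out, class = "module_pool")
}

pool_matrix <- function(pool) {
  if (inherits(pool, "module_pool")) pool$vectors
  else unitize_rows(as.matrix(pool))
}

cosine_distance_matrix <- function(x) {
  d <- 1 - tcrossprod(x)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# Mean silhouette under cosine distance; single-member clusters get s = 0.
mean_silhouette_cosine <- function(x, assign) {
  n <- nrow(x)
  k <- length(unique(assign))
  if (k < 2 || k >= n) return(NA_real_)
  d <- cosine_distance_matrix(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assign == assign[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a_i <- mean(d[i, setdiff(own, i)])
    b_i <- min(vapply(setdiff(unique(assign), assign[i]), function(cl) {
      mean(d[i, assign == cl])
    }, numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- (1 - drop(x %*% x[centers[1], ]))^2
  for (j in seq_len(k)[-1]) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, (1 - drop(x %*% x[centers[j], ]))^2)
  }
  x[centers, , drop = FALSE]
}

kmeans_core <- function(x, cent, max_iter) {
  n <- nrow(x)
  assign_prev <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    sim <- x %*% t(cent)
    assign <- max.col(sim, ties.method = "first")
    for (cl in seq_len(nrow(cent))) {        # revive empty clusters
      if (!any(assign == cl)) {
        worst <- which.min(sim[cbind(seq_len(n), assign)])
        assign[worst] <- cl
        sim[worst, ] <- -Inf; sim[worst, cl] <- Inf
      }
    }
    if (all(assign == assign_prev)) break
    assign_prev <- assign
    cent <- unitize_rows(t(vapply(seq_len(nrow(cent)), function(cl) {
      colMeans(x[assign == cl, , drop = FALSE])
    }, numeric(ncol(x)))))
  }
  obj <- sum(1 - (x %*% t(cent))[cbind(seq_len(n), assign)])
  list(assignments = assign, centroids = cent, objective = obj)
}

#' Spherical (cosine) k-means
#'
#' Minimizes total cosine distance (1 - cosine similarity) of unit-norm
#' items to unit-norm centroids, best of `n_init` k-means++-style starts.
#'
#' @param pool A [module_pool()] or items x dim matrix.
#' @param k Number of clusters (`k <= n_items`).
#' @param n_init Random restarts (default 50).
#' @param seed Integer seed.
#' @param max_iter Iteration cap per restart.
#' @return A `cluster_result`: `assignments`, `centroids`,
#'   `mean_silhouette` (0 with `degenerate = TRUE` when undefined),
#'   `objective`, `k`, `feasible`, `constraint_violations`.
#' @export
spherical_kmeans <- function(pool, k, n_init = 50, seed = 1,
                             max_iter = 100) {
  x <- pool_matrix(pool)
  n <- nrow(x)
  if (k > n) stop_invalid("k = ", k, " exceeds n_items = ", n)
  if (k == n) {
    return(structure(list(assignments = seq_len(n), centroids = x,
                          mean_silhouette = 0, degenerate = TRUE,
                          objective = 0, k = k, feasible = TRUE,
                          constraint_violations = 0L,
                          excluded = rep(FALSE, n)),
                     class = "cluster_result"))
  }
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_init)) {
      fit <- kmeans_core(x, kmeanspp_init(x, k), max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  sil <- mean_silhouette_cosine(x, best$assignments)
  structure(list(assignments = best$assignments, centroids = best$centroids,
                 mean_silhouette = if (is.na(sil)) 0 else sil,
                 degenerate = is.na(sil),
                 objective = best$objective, k = k, feasible = TRUE,
                 constraint_violations = 0L,
                 excluded = rep(FALSE, nrow(x))),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k=", x$k,
      if (!x$feasible) " (infeasible)" else "",
      ", mean silhouette=", formatC(x$mean_silhouette, digits = 3,
                                    format = "f"),
      ", excluded=", sum(x$excluded), "\n", sep = "")
  invisible(x)
}

#' Keep one module per participant per cluster
#'
#' When several modules from the same participant land in one cluster,
#' only the one closest (Euclidean) to the cluster centroid is retained;
#' the rest are marked excluded. `rule = "literal_gt2"` applies the looser
#' reading that tolerates two co-clustered modules and prunes only beyond
#' that.
#'
#' @param result A `cluster_result`.
#' @param pool The clustered [module_pool()] (participant labels used).
#' @param rule `"single"` (default) or `"literal_gt2"`.
#' @return Updated `cluster_result` with `excluded` set.
#' @export
dedupe_within_participant <- function(result, pool,
                                      rule = c("single", "literal_gt2")) {
  rule <- match.arg(rule)
  stopifnot(inherits(result, "cluster_result"),
            inherits(pool, "module_pool"))
  x <- pool$vectors
  excluded <- result$excluded
  groups <- split(seq_len(nrow(x)),
                  list(pool$items$participant, result$assignments),
                  drop = TRUE)
  keep_n <- if (rule == "single") 1L else 2L
  for (g in groups) {
    if (length(g) <= keep_n) next
    cent <- result$centroids[result$assignments[g[1]], ]
    dist <- sqrt(colSums((t(x[g, , drop = FALSE]) - cent)^2))
    ord <- order(dist, g)    # ties: smaller index wins
    excluded[g[ord[-seq_len(keep_n)]]] <- TRUE
  }
  result$excluded <- excluded
  result
}

#' Cluster-representative modules (SPc / TEc)
#'
#' Per cluster, the unit-normalized mean of the retained (non-excluded)
#' members.
#'
#' @param result A `cluster_result`.
#' @param pool The clustered [module_pool()].
#' @return k x dim matrix of unit-norm representatives.
#' @export
representative_modules <- function(result, pool) {
  x <- pool_matrix(pool)
  k <- result$k
  out <- matrix(NA_real_, k, ncol(x))
  for (cl in seq_len(k)) {
    members <- which(result$assignments == cl & !result$excluded)
    if (length(members) == 0) {
      stop_degenerate("cluster ", cl, " has no retained members")
    }
    out[cl, ] <- colMeans(x[members, , drop = FALSE])
  }
  unitize_rows(out)
}

#' Cannot-link constrained cosine k-means (COP-k-means)
#'
#' Items sharing a `groups` label (e.g. the same gravity level) may not be
#' assigned to the same cluster. Per restart, items are visited in random
#' order and assigned to the nearest centroid whose cluster holds no
#' same-group member; a dead end fails the restart. Infeasibility (by
#' pigeonhole or after all restarts) is an outcome, not an error: the
#' result has `feasible = FALSE` and silhouette 0.
#'
#' @param pool A [module_pool()] or matrix.
#' @param k Number of clusters.
#' @param groups Per-item cannot-link group labels; defaults to the pool's
#'   gravity labels.
#' @param n_init Random restarts (default 50).
#' @param seed Integer seed.
#' @param max_iter Assignment/update sweeps per restart.
#' @return A `cluster_result` (with `feasible` flag).
#' @export
constrained_kmeans <- function(pool, k, groups = NULL, n_init = 50,
                               seed = 1, max_iter = 50) {
  x <- pool_matrix(pool)
  n <- nrow(x)
  if (is.null(groups)) {
    if (!inherits(pool, "module_pool")) {
      stop_invalid("groups must be supplied for a bare matrix pool")
    }
    groups <- pool$items$gravity
  }
  groups <- as.character(rep_len(groups, n))
  if (k > n) stop_invalid("k = ", k, " exceeds n_items = ", n)
  infeasible <- function() {
    structure(list(assignments = rep(NA_integer_, n), centroids = NULL,
                   mean_silhouette = 0, degenerate = TRUE,
                   objective = Inf, k = k, feasible = FALSE,
                   constraint_violations = NA_integer_,
                   excluded = rep(FALSE, n)),
              class = "cluster_result")
  }
  if (k < max(table(groups))) return(infeasible())

  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_init)) {
      cent <- kmeanspp_init(x, k)
      assign <- rep(NA_integer_, n)
      ok <- TRUE
      for (sweep_i in seq_len(max_iter)) {
        new_assign <- rep(NA_integer_, n)
        taken <- vector("list", k)   # group labels already in each cluster
        ok <- TRUE
        for (i in sample.int(n)) {
          sims <- drop(x[i, ] %*% t(cent))
          allowed <- which(vapply(seq_len(k), function(cl) {
            !(groups[i] %in% taken[[cl]])
          }, logical(1)))
          if (length(allowed) == 0) { ok <- FALSE; break }
          cl <- allowed[which.max(sims[allowed])]
          new_assign[i] <- cl
          taken[[cl]] <- c(taken[[cl]], groups[i])
        }
        if (!ok) break
        if (!anyNA(assign) && all(new_assign == assign)) break
        assign <- new_assign
        cent <- unitize_rows(t(vapply(seq_len(k), function(cl) {
          members <- which(assign == cl)
          if (length(members) == 0) x[sample.int(n, 1), ]
          else colMeans(x[members, , drop = FALSE])
        }, numeric(ncol(x)))))
      }
      if (!ok) next
      obj <- sum(1 - (x %*% t(cent))[cbind(seq_len(n), assign)])
      if (is.null(best) || obj < best$objective) {
        best <- list(assignments = assign, centroids = cent, objective = obj)
      }
    }
  })
  if (is.null(best)) return(infeasible())
  violations <- sum(vapply(seq_len(k), function(cl) {
    sum(duplicated(groups[best$assignments == cl]))
  }, numeric(1)))
  sil <- mean_silhouette_cosine(x, best$assignments)
  structure(list(assignments = best$assignments, centroids = best$centroids,
                 mean_silhouette = if (is.na(sil)) 0 else sil,
                 degenerate = is.na(sil),
                 objective = best$objective, k = k, feasible = TRUE,
                 constraint_violations = as.integer(violations),
                 excluded = rep(FALSE, n)),
            class = "cluster_result")
}

#' Select the number of clusters by mean silhouette
#'
#' Runs the (optionally constrained) clustering for each k in `k_range`
#' and returns the k with the largest mean cosine silhouette; infeasible
#' or degenerate k score 0; ties break towards smaller k.
#'
#' @param pool A [module_pool()] or matrix.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param constrained Use [constrained_kmeans()]?
#' @param groups Cannot-link groups when `constrained`.
#' @param n_init,seed,max_iter Passed through.
#' @return List with `k_best`, `table` (data.frame k / mean_silhouette /
#'   feasible) and `results` (per-k `cluster_result`s).
#' @export
select_k_by_silhouette <- function(pool, k_range = 2:10,
                                   constrained = FALSE, groups = NULL,
                                   n_init = 50, seed = 1, max_iter = 100) {
  x <- pool_matrix(pool)
  if (nrow(x) <= max(k_range)) {
    k_range <- k_range[k_range < nrow(x)]
    if (length(k_range) == 0) stop_invalid("pool too small for any candidate k")
  }
  results <- lapply(k_range, function(k) {
    if (constrained) {
      constrained_kmeans(pool, k, groups = groups, n_init = n_init,
                         seed = derive_seed(seed, k), max_iter = max_iter)
    } else {
      spherical_kmeans(pool, k, n_init = n_init,
                       seed = derive_seed(seed, k), max_iter = max_iter)
    }
  })
  sil <- vapply(results, function(r) {
    if (!r$feasible || isTRUE(r$degenerate)) 0 else r$mean_silhouette
  }, numeric(1))
  tab <- data.frame(k = k_range, mean_silhouette = sil,
                    feasible = vapply(results, `[[`, logical(1), "feasible"))
  k_best <- k_range[which.max(sil)]   # which.max: first max -> smaller k
  list(k_best = k_best, table = tab, results = setNames(results, k_range))
}
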