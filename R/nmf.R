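# Nonnegative matrix factorization of cycle matrices: M ~ W C with
# W (muscles x N) the spatial modules and C (N x bins) the temporal
# modules. Model-order selection uses 5-fold cross-validation over time
# bins and the smallest N whose mean held-out VAF exceeds 90%.

#' Variance accounted for by a reconstruction
#'
#' Primary definition: `100 * (1 - sum((M - Mhat)^2) / sum(M^2))`, the
#' uncentred coefficient of determination. The squared uncentred Pearson
#' correlation between the vectorized matrices is available as an
#' alternative; the two agree at the anchor cases but are not identical in
#' general.
#'
#' @param m Data matrix (not all zero).
#' @param m_hat Reconstruction of the same shape.
#' @param method `"residual"` (default) or `"uncentered_r2"`.
#' @return VAF in percent; may be negative (flagged with a warning).
#' @export
vaf <- function(m, m_hat, method = c("residual", "uncentered_r2")) {
  method <- match.arg(method)
  m <- as_values_matrix(m); m_hat <- as_values_matrix(m_hat)
  if (!all(dim(m) == dim(m_hat))) stop_invalid("shape mismatch in vaf()")
  tot <- sum(m^2)
  if (tot == 0) stop_degenerate("vaf undefined for an all-zero data matrix")
  out <- if (method == "residual") {
    100 * (1 - sum((m - m_hat)^2) / tot)
  } else {
    100 * sum(m * m_hat)^2 / (tot * sum(m_hat^2))
  }
  if (out < 0) warning("negative VAF (", format(out), "%): reconstruction ",
                       "worse than the zero model")
  out
}

#' Extract spatial and temporal modules by NMF
#'
#' Lee-Seung multiplicative updates on the squared Frobenius loss,
#' restarted `n_restarts` times from uniform random factors in \[0, 1\];
#' the restart with the highest VAF wins. Spatial columns are normalized
#' to unit Euclidean norm with the scale absorbed into the temporal
#' coefficients.
#'
#' @param m Nonnegative muscles x bins matrix (typically unit-variance
#'   scaled), or a `cycle_matrix`.
#' @param n_modules Number of modules N, `1 <= N <= n_muscles`.
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer seed.
#' @param max_iter,tol Convergence controls per restart.
#' @return A `module_set` with `W`, `C`, `n_modules`, `vaf`,
#'   `restart_vafs`, `meta`.
#' @export
nmf_extract <- function(m, n_modules, n_restarts = 20, seed = 1,
                        max_iter = 1000, tol = 1e-6) {
  meta <- if (inherits(m, "cycle_matrix")) {
    list(participant = m$participant, condition = m$condition)
  } else NULL
  v <- as_values_matrix(m)
  if (any(v < 0)) stop_invalid("NMF input must be nonnegative")
  if (sum(v) == 0) stop_degenerate("NMF input is all zero")
  if (n_modules < 1 || n_modules > nrow(v)) {
    stop_invalid("n_modules must be in 1..", nrow(v), "; got ", n_modules)
  }
  fits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      w0 <- matrix(runif(nrow(v) * n_modules), nrow(v), n_modules)
      c0 <- matrix(runif(n_modules * ncol(v)), n_modules, ncol(v))
      nmf_mu_cpp(v, w0, c0, max_iter, tol, FALSE)
    })
  })
  vafs <- vapply(fits, function(f) vaf(v, f$W %*% f$C), numeric(1))
  best <- fits[[which.max(vafs)]]
  norms <- sqrt(colSums(best$W^2))
  norms[norms == 0] <- 1
  W <- sweep(best$W, 2, norms, "/")
  C <- best$C * norms
  rownames(W) <- rownames(v)
  structure(list(W = W, C = C, n_modules = n_modules,
                 vaf = max(vafs), restart_vafs = vafs,
                 loss = best$loss, meta = meta),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("<module_set> N=", x$n_modules, ", VAF=",
      formatC(x$vaf, digits = 2, format = "f"), "%\n", sep = "")
  invisible(x)
}

#' Cross-validated VAF curve over candidate module numbers
#'
#' Per repeat, the time bins are randomly partitioned into `n_folds`
#' disjoint column sets. For each fold, modules are extracted from the
#' training columns; on the held-out columns only the temporal
#' coefficients are refit (multiplicative updates with W frozen) and the
#' held-out VAF recorded. Each repeat contributes the mean over folds; the
#' curve reports mean and sd over repeats.
#'
#' @param m Nonnegative matrix or `cycle_matrix`.
#' @param n_range Candidate module numbers (default 1:12).
#' @param n_folds Number of folds (must divide the column count).
#' @param n_reps Number of random re-partitions (default 20).
#' @param n_restarts Restarts per training fit (default 1; the selection
#'   curve is robust to this and the full 20 restarts are reserved for the
#'   final extraction).
#' @param seed Integer seed.
#' @param max_iter,tol Convergence controls.
#' @return A `vaf_curve`: data.frame columns `n`, `mean_vaf`, `sd_vaf`,
#'   with settings in attributes.
#' @export
cross_validated_vaf_curve <- function(m, n_range = 1:12, n_folds = 5,
                                      n_reps = 20, n_restarts = 1, seed = 1,
                                      max_iter = 500, tol = 1e-5) {
  v <- as_values_matrix(m)
  nc <- ncol(v)
  if (nc %% n_folds != 0) {
    stop_invalid("column count ", nc, " is not divisible by n_folds = ",
                 n_folds)
  }
  if (any(n_range < 1 | n_range > nrow(v))) {
    stop_invalid("n_range must lie within 1..", nrow(v))
  }
  fold_size <- nc / n_folds
  rep_vaf <- matrix(NA_real_, n_reps, length(n_range))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      perm <- sample.int(nc)
      folds <- split(perm, rep(seq_len(n_folds), each = fold_size))
      for (ni in seq_along(n_range)) {
        n <- n_range[ni]
        fold_vafs <- vapply(folds, function(test_cols) {
          train <- v[, -test_cols, drop = FALSE]
          test <- v[, test_cols, drop = FALSE]
          best <- NULL
          for (s in seq_len(n_restarts)) {
            w0 <- matrix(runif(nrow(v) * n), nrow(v), n)
            c0 <- matrix(runif(n * ncol(train)), n, ncol(train))
            fit <- nmf_mu_cpp(train, w0, c0, max_iter, tol, FALSE)
            if (is.null(best) || fit$loss < best$loss) best <- fit
          }
          c0t <- matrix(runif(n * ncol(test)), n, ncol(test))
          ct <- nmf_update_c_cpp(test, best$W, c0t, max_iter, tol)$C
          vaf(test, best$W %*% ct)
        }, numeric(1))
        rep_vaf[r, ni] <- mean(fold_vafs)
      }
    }
  })
  out <- data.frame(n = n_range,
                    mean_vaf = colMeans(rep_vaf),
                    sd_vaf = apply(rep_vaf, 2, sd))
  attr(out, "n_folds") <- n_folds
  attr(out, "n_reps") <- n_reps
  attr(out, "rep_vaf") <- rep_vaf
  class(out) <- c("vaf_curve", "data.frame")
  out
}

#' Select the number of modules from a VAF curve
#'
#' The smallest candidate N whose mean cross-validated VAF exceeds the
#' threshold (default 90%). When no candidate reaches it, a "not reached"
#' sentinel is returned carrying the best available N.
#'
#' @param curve A `vaf_curve`, or a plain numeric vector of mean VAFs
#'   (interpreted as N = 1, 2, ...).
#' @param threshold VAF threshold in percent (default 90, strict `>`).
#' @return List with `n_selected` (NA when not reached), `reached`,
#'   `threshold`, `vaf_at_selected`, `n_max`, `vaf_at_max`.
#' @export
select_module_number <- function(curve, threshold = 90) {
  if (is.numeric(curve) && is.null(dim(curve))) {
    curve <- data.frame(n = seq_along(curve), mean_vaf = as.numeric(curve))
  }
  if (nrow(curve) == 0) stop_invalid("empty VAF curve")
  hit <- which(curve$mean_vaf > threshold)
  if (length(hit) == 0) {
    imax <- which.max(curve$mean_vaf)
    return(list(n_selected = NA_integer_, reached = FALSE,
                threshold = threshold,
                vaf_at_selected = NA_real_,
                n_max = curve$n[imax], vaf_at_max = curve$mean_vaf[imax]))
  }
  i <- hit[which.min(curve$n[hit])]
  list(n_selected = as.integer(curve$n[i]), reached = TRUE,
       threshold = threshold, vaf_at_selected = curve$mean_vaf[i],
       n_max = curve$n[which.max(curve$mean_vaf)],
       vaf_at_max = max(curve$mean_vaf))
}

#' Group-level module number
#'
#' Mode across participants' selected module numbers; ties break towards
#' the smaller N.
#'
#' @param ns Integer vector of per-participant selections (NAs dropped).
#' @return Modal module number.
#' @export
modal_module_number <- function(ns) {
  ns <- ns[!is.na(ns)]
  if (length(ns) == 0) stop_invalid("no selections to summarize")
  tab <- table(ns)
  as.integer(names(tab)[tab == max(tab)][1])
}
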