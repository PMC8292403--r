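# Nonnegative CANDECOMP/PARAFAC decomposition of the EMG tensor
# (muscles x phase bins x condition slices). Each component is a rank-1
# triple lambda_n * w_n (spatial) o c_n (temporal) o t_n (task gains),
# with unit-norm factor columns and the scale carried by lambda.

#' Stack cycle matrices into a 3-way EMG tensor
#'
#' @param matrices List of `cycle_matrix` objects (or plain matrices)
#'   sharing muscle order and bin count; stacked as slices in order.
#' @param slice_labels Optional data.frame (one row per slice) with at
#'   least `participant` and `gravity` columns; inferred from
#'   `cycle_matrix` metadata when absent (condition -> gravity).
#' @return An `emg_tensor`: `values` (I x J x K array), `slice_labels`,
#'   `muscle_labels`.
#' @export
build_tensor <- function(matrices, slice_labels = NULL) {
  if (length(matrices) == 0) stop_invalid("empty slice list")
  vals <- lapply(matrices, as_values_matrix)
  d <- dim(vals[[1]])
  labs <- if (inherits(matrices[[1]], "cycle_matrix"))
    matrices[[1]]$muscle_labels else rownames(vals[[1]])
  if (is.null(labs)) labs <- default_muscles(d[1])
  for (i in seq_along(vals)) {
    if (!all(dim(vals[[i]]) == d)) {
      stop_invalid("slice ", i, " has shape ", paste(dim(vals[[i]]),
                   collapse = "x"), ", expected ", paste(d, collapse = "x"))
    }
    li <- if (inherits(matrices[[i]], "cycle_matrix"))
      matrices[[i]]$muscle_labels else rownames(vals[[i]])
    if (!is.null(li) && !identical(li, labs)) {
      stop_invalid("slice ", i, " has inconsistent muscle order")
    }
  }
  if (is.null(slice_labels)) {
    slice_labels <- data.frame(
      participant = vapply(matrices, function(m) {
        if (inherits(m, "cycle_matrix")) as.character(m$participant)
        else NA_character_
      }, character(1)),
      gravity = vapply(matrices, function(m) {
        if (inherits(m, "cycle_matrix")) as.character(m$condition)
        else NA_character_
      }, character(1)))
  }
  if (nrow(slice_labels) != length(matrices)) {
    stop_invalid("slice_labels must have one row per slice")
  }
  key <- do.call(paste, c(slice_labels, sep = "\r"))
  if (!all(is.na(slice_labels[[1]])) && anyDuplicated(key)) {
    stop_invalid("duplicate slice labels")
  }
  arr <- array(unlist(vals), dim = c(d[1], d[2], length(vals)))
  structure(list(values = arr, slice_labels = slice_labels,
                 muscle_labels = labs),
            class = "emg_tensor")
}

#' @export
print.emg_tensor <- function(x, ...) {
  cat("<emg_tensor> ", paste(dim(x$values), collapse = " x "), "\n", sep = "")
  invisible(x)
}

tensor_values <- function(x) {
  if (inherits(x, "emg_tensor")) x$values else as.array(x)
}

#' Nonnegative CP decomposition by multiplicative updates
#'
#' Fits `P ~ sum_n lambda_n w_n o c_n o t_n` with all factors nonnegative,
#' minimizing the sum of squared errors. After convergence each factor
#' column is normalized to unit Euclidean norm and the product of norms
#' becomes `lambda_n`; components are sorted by decreasing lambda. Best of
#' `n_restarts` uniform random initializations by VAF.
#'
#' @param tensor An `emg_tensor` or nonnegative 3-way array.
#' @param n_components Number of components N.
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer seed.
#' @param max_iter,tol Convergence controls (defaults 2000, 1e-6).
#' @return A `cp_model`: `lambdas`, `W_st` (I x N), `C_st` (J x N), `T`
#'   (K x N), `vaf`, `restart_vafs`, `slice_labels`.
#' @export
ncp_decompose <- function(tensor, n_components, n_restarts = 20, seed = 1,
                          max_iter = 2000, tol = 1e-6) {
  x <- tensor_values(tensor)
  if (length(dim(x)) != 3) stop_invalid("tensor must be a 3-way array")
  if (any(x < 0)) stop_invalid("tensor must be nonnegative")
  if (sum(x) == 0) stop_degenerate("tensor is all zero")
  dims <- dim(x)
  if (n_components < 1 || n_components > min(dims)) {
    stop_invalid("n_components must be in 1..", min(dims))
  }
  fits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      a0 <- matrix(runif(dims[1] * n_components), dims[1], n_components)
      b0 <- matrix(runif(dims[2] * n_components), dims[2], n_components)
      c0 <- matrix(runif(dims[3] * n_components), dims[3], n_components)
      ncp_mu_cpp(x, a0, b0, c0, max_iter, tol)
    })
  })
  tot <- sum(x^2)
  vafs <- vapply(fits, function(f) 100 * (1 - f$loss / tot), numeric(1))
  best <- fits[[which.max(vafs)]]
  wn <- sqrt(colSums(best$A^2)); wn[wn == 0] <- 1
  cn <- sqrt(colSums(best$B^2)); cn[cn == 0] <- 1
  tn <- sqrt(colSums(best$C^2)); tn[tn == 0] <- 1
  lambdas <- wn * cn * tn
  ord <- order(lambdas, decreasing = TRUE)
  W <- sweep(best$A, 2, wn, "/")[, ord, drop = FALSE]
  C <- sweep(best$B, 2, cn, "/")[, ord, drop = FALSE]
  Tm <- sweep(best$C, 2, tn, "/")[, ord, drop = FALSE]
  rownames(W) <- if (inherits(tensor, "emg_tensor")) tensor$muscle_labels
  structure(list(lambdas = lambdas[ord], W_st = W, C_st = C, T = Tm,
                 vaf = max(vafs), restart_vafs = vafs,
                 n_components = n_components,
                 slice_labels = if (inherits(tensor, "emg_tensor"))
                   tensor$slice_labels),
            class = "cp_model")
}

#' @export
print.cp_model <- function(x, ...) {
  cat("<cp_model> N=", x$n_components, ", VAF=",
      formatC(x$vaf, digits = 2, format = "f"), "%, lambda=",
      paste(formatC(x$lambdas, digits = 3, format = "g"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Reconstruct the tensor from a CP model
#'
#' @param model A `cp_model`.
#' @return 3-way array `sum_n lambda_n w_n o c_n o t_n`.
#' @export
cp_reconstruct <- function(model) {
  dims <- c(nrow(model$W_st), nrow(model$C_st), nrow(model$T))
  out <- array(0, dims)
  for (n in seq_len(model$n_components)) {
    out <- out + model$lambdas[n] *
      outer(outer(model$W_st[, n], model$C_st[, n]), model$T[, n])
  }
  out
}

#' VAF of a CP model on its tensor
#'
#' Same uncentred definition as the matrix case, over all tensor entries.
#'
#' @param tensor An `emg_tensor` or 3-way array.
#' @param model A `cp_model`.
#' @return VAF in percent.
#' @export
tensor_vaf <- function(tensor, model) {
  x <- tensor_values(tensor)
  xh <- cp_reconstruct(model)
  if (!all(dim(x) == dim(xh))) stop_invalid("model/tensor shape mismatch")
  tot <- sum(x^2)
  if (tot == 0) stop_degenerate("all-zero tensor")
  100 * (1 - sum((x - xh)^2) / tot)
}

#' Condition-level summary of task-dependent gains
#'
#' Mean of each component's task gains over the slices sharing a label
#' (e.g. the participants at one gravity level).
#'
#' @param model A `cp_model` fitted on a labelled `emg_tensor`.
#' @param by Column of the slice labels to group by (default `"gravity"`).
#' @param levels Optional explicit ordering of the grouping labels.
#' @return Matrix conditions x components of mean gains.
#' @export
gain_by_condition <- function(model, by = "gravity", levels = NULL) {
  labs <- model$slice_labels
  if (is.null(labs) || !(by %in% names(labs))) {
    stop_invalid("model carries no slice label column '", by, "'")
  }
  g <- as.character(labs[[by]])
  if (is.null(levels)) levels <- unique(g)
  out <- t(vapply(levels, function(l) colMeans(model$T[g == l, , drop = FALSE]),
                  numeric(model$n_components)))
  rownames(out) <- levels
  out
}
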