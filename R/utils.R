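# Internal helpers shared across modules. Nothing here is exported except
# with_seed(), which user code needs to reproduce seeded examples without
# clobbering the session RNG.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the previous state of
#' `.Random.seed`, so seeded package functions never disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic derivation of stage/sub seeds from a master seed, kept
# within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483629)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("gravisyn_invalid_argument",
                                             "gravisyn_error")))
}

stop_insufficient <- function(...) {
  stop(errorCondition(paste0(...), class = c("gravisyn_insufficient_data",
                                             "gravisyn_error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("gravisyn_degenerate_input",
                                             "gravisyn_error")))
}

# Euclidean-normalize columns (or rows); zero vectors are left untouched.
unitize_cols <- function(x) {
  nrm <- sqrt(colSums(x^2))
  nrm[nrm == 0] <- 1
  sweep(x, 2, nrm, "/")
}

unitize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  sweep(x, 1, nrm, "/")
}

# Coerce cycle_matrix-like inputs to a plain numeric matrix.
as_values_matrix <- function(x) {
  if (inherits(x, "cycle_matrix")) return(x$values)
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  stop_invalid("cannot interpret input of class '", class(x)[1],
               "' as a muscles-by-bins matrix")
}

default_muscles <- function(n) {
  std <- c("MG", "LG", "SOL", "TA", "VL", "RF",
           "BFL", "BFS", "AL", "TFL", "GMed", "GMax")
  if (n == length(std)) std else sprintf("M%02d", seq_len(n))
}
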