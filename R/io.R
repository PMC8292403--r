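# Plain-text readers and writers: cycle matrices and trials as CSV,
# ground truth / reports as JSON. Sampling rate may come from a
# "# fs=1000" header comment.

#' Write a cycle matrix to CSV (muscles as rows, bins as columns)
#' @param m A `cycle_matrix` or matrix.
#' @param path Output file.
#' @export
write_cycle_matrix <- function(m, path) {
  v <- as_values_matrix(m)
  colnames(v) <- sprintf("bin%03d", seq_len(ncol(v)))
  df <- data.frame(muscle = rownames(v) %||% default_muscles(nrow(v)), v,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cycle matrix from CSV
#' @param path CSV with a `muscle` column and one column per bin.
#' @param participant,condition Labels to attach.
#' @return A `cycle_matrix`.
#' @export
read_cycle_matrix <- function(path, participant = NA, condition = NA) {
  df <- read.csv(path, check.names = FALSE)
  labs <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  cycle_matrix(v, muscle_labels = labs, participant = participant,
               condition = condition)
}

#' Write a raw trial (EMG + limb angle) to CSV with a time column
#' @param trial A `synthetic_raw_trial`.
#' @param path Output file.
#' @export
write_raw_trial <- function(trial, path) {
  stopifnot(inherits(trial, "synthetic_raw_trial"))
  df <- data.frame(time = (seq_len(ncol(trial$emg)) - 1) / trial$fs,
                   t(trial$emg), limb_angle = trial$limb_angle)
  names(df)[2:(1 + nrow(trial$emg))] <- trial$muscle_labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", trial$fs), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read multi-channel signals from CSV
#'
#' Accepts an optional leading `# fs=...` comment line and an optional
#' `time` column; remaining columns are channels.
#'
#' @param path CSV file.
#' @param fs Sampling rate; overrides any header comment.
#' @return List with `data` (channels x samples matrix, rownames =
#'   channel labels) and `fs`.
#' @export
read_signals_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1)
  header_fs <- NULL
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("fs=([0-9.]+)", first))[[1]]
    if (length(m) == 2) header_fs <- as.numeric(m[2])
  }
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (tolower(names(df)[1]) == "time") df <- df[, -1, drop = FALSE]
  out <- t(as.matrix(df))
  fs <- fs %||% header_fs
  if (is.null(fs)) stop_invalid("sampling rate not given and no '# fs=' header")
  list(data = out, fs = fs)
}

#' Serialize a ground truth model to JSON
#' @param gt A `ground_truth`.
#' @param path Output file.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  obj <- unclass(gt)
  obj$participant_scales <- lapply(seq_len(gt$n_participants), function(p) {
    gt$participant_scales[, , p]
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Write a module set (W, C) as CSV files under a directory
#' @param ms A `module_set`.
#' @param dir Output directory (created).
#' @export
write_module_set <- function(ms, dir) {
  stopifnot(inherits(ms, "module_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(ms$W, file.path(dir, "W.csv"), row.names = TRUE)
  write.csv(ms$C, file.path(dir, "C.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_modules = ms$n_modules, vaf = ms$vaf,
                            meta = ms$meta),
                       file.path(dir, "modules.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
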