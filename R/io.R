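#' Write the epochs of one session to a tabular trace file
#'
#' The on-disk trace format is plain CSV with columns `epoch` (1-based
#' sweep index), `block` (which of the session's averages the sweep
#' belongs to), `time_ms` (epoch-relative, 0 = flash onset) and
#' `microvolts`. One file holds all sweeps of one session.
#'
#' @param session A `vep_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  t <- epoch_times(session$acq)
  n_sweeps <- nrow(session$epochs)
  df <- data.frame(
    epoch = rep(seq_len(n_sweeps), each = length(t)),
    block = rep(session$block, each = length(t)),
    time_ms = rep(t, times = n_sweeps),
    microvolts = as.vector(t(session$epochs)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read epoched traces from a tabular trace file
#'
#' Reads the CSV trace format written by [write_session()], validating
#' uniform sampling and equal epoch lengths.
#'
#' @param path File path.
#' @param format Only `"tabular"` is supported; `"edf"` is recognized but
#'   not implemented.
#' @return A list with `epochs` (matrix, sweeps x samples), `block`,
#'   `sampling_rate` (Hz) and `t0` (ms of the first sample).
#' @export
read_epochs <- function(path, format = c("tabular", "edf")) {
  format <- match.arg(format)
  if (format == "edf") {
    stop("EDF reading is not implemented; use the tabular trace format")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path), error = function(e) {
    stop("empty or unreadable trace file: ", path)
  })
  if (nrow(df) == 0) stop("empty trace file: ", path)
  req <- c("epoch", "block", "time_ms", "microvolts")
  if (!all(req %in% names(df))) {
    stop("trace file needs columns: ", paste(req, collapse = ", "))
  }
  t1 <- df$time_ms[df$epoch == df$epoch[1]]
  dt <- diff(t1)
  if (length(dt) == 0 || max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("non-uniform sampling in trace file")
  }
  counts <- table(df$epoch)
  if (length(unique(counts)) != 1) stop("epochs have mixed lengths")
  n <- unname(counts[1])
  ep_ids <- unique(df$epoch)
  epochs <- matrix(df$microvolts, nrow = length(ep_ids), ncol = n, byrow = TRUE)
  block <- df$block[match(ep_ids, df$epoch)]
  list(epochs = epochs, block = block,
       sampling_rate = 1000 / dt[1], t0 = t1[1])
}

#' Write a cohort manifest
#'
#' One row per session: `eye_id`, `mouse_id`, `group`, `day`, `path` of
#' the session's trace file, and the ground-truth component latencies
#' when the cohort is simulated.
#'
#' @param manifest Data frame (e.g. `sim$manifest` with a `path` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' @param path Manifest CSV path.
#' @param known_groups Optional character vector; group labels outside it
#'   are rejected.
#' @return The validated manifest data frame. Eyes with no baseline
#'   (day 0) row are recorded in attribute `"missing_baseline"` (their
#'   percent-change endpoints will be undefined).
#' @export
read_manifest <- function(path, known_groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("eye_id", "group", "day")
  if (!all(req %in% names(df))) {
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  }
  if (any(df$day < 0)) stop("negative day in manifest")
  if (anyDuplicated(df[c("eye_id", "day")])) {
    stop("duplicate (eye_id, day) rows in manifest")
  }
  if (!is.null(known_groups) && !all(df$group %in% known_groups)) {
    bad <- setdiff(unique(df$group), known_groups)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  with_base <- unique(df$eye_id[df$day == 0])
  missing <- setdiff(unique(df$eye_id), with_base)
  if (length(missing) > 0) {
    warning("eyes without baseline session: ", paste(missing, collapse = ", "))
  }
  attr(df, "missing_baseline") <- missing
  df
}
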