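#' Read an EMG pair from CSV
#'
#' Expects a header row with columns `time`, `emg1`, `emg2` (comma
#' separated, `.` decimal). The time column must be strictly increasing and
#' uniformly spaced (relative tolerance 1e-6 on the sampling interval);
#' amplitudes must be non-negative and complete — raw EMG containing
#' negative excursions must be rectified upstream.
#'
#' @param path Path to a CSV file.
#' @return An [emg_pair()], with the time vector attached as attribute
#'   `"time"`.
#' @export
read_emg_pair <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  required <- c("time", "emg1", "emg2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         "; expected header 'time, emg1, emg2'", call. = FALSE)
  }
  for (col in required) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      stop("missing or non-finite value in column '", col, "' at row ",
           bad[1], call. = FALSE)
    }
  }
  for (col in c("emg1", "emg2")) {
    bad <- which(df[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative amplitude ", format(df[[col]][bad[1]]), " in column '",
           col, "' at row ", bad[1],
           "; rectify the signal before computing co-contraction",
           call. = FALSE)
    }
  }
  dt <- diff(df$time)
  if (any(dt <= 0)) {
    stop("time must be strictly increasing (violated at row ",
         which(dt <= 0)[1] + 1, ")", call. = FALSE)
  }
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
    stop("non-uniform time base: sampling interval varies by more than ",
         "1e-6 relative tolerance", call. = FALSE)
  }
  pair <- emg_pair(df$emg1, df$emg2)
  attr(pair, "time") <- df$time
  pair
}

#' Write an EMG pair to CSV
#'
#' Writes `time, emg1, emg2` with enough precision (15 significant digits)
#' for a faithful round-trip through [read_emg_pair()].
#'
#' @param pair An [emg_pair()].
#' @param path Output path.
#' @param time Optional time vector; defaults to the pair's `"time"`
#'   attribute or, failing that, a unit-duration base `(0:(n-1))/(n-1)`.
#' @return `path`, invisibly.
#' @export
write_emg_pair <- function(pair, path, time = NULL) {
  pair <- as_emg_pair(pair)
  if (is.null(time)) time <- attr(pair, "time")
  if (is.null(time)) time <- seq(0, 1, length.out = pair$n)
  df <- data.frame(time = format(time, digits = 15, trim = TRUE),
                   emg1 = format(as.numeric(pair$emg1), digits = 15,
                                 trim = TRUE),
                   emg2 = format(as.numeric(pair$emg2), digits = 15,
                                 trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write study tables with a run manifest
#'
#' Serializes a named list of tidy tables as CSV files (one per table,
#' `<name>.csv`) plus a `manifest.json` recording the run configuration, its
#' hash, the package version, and per-table row and undefined-value counts,
#' so every output is traceable to the configuration that produced it.
#' Row order is preserved as given, making reruns byte-identical.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param config Named list describing the run (seeds, sizes, thresholds).
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, dir, config = list()) {
  stopifnot(is.list(tables), length(tables) > 0,
            !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (name in names(tables)) {
    utils::write.csv(as.data.frame(tables[[name]]),
                     file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    config = config,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("ccindex")),
    tables = lapply(tables, function(tab) {
      list(n_rows = nrow(tab),
           n_undefined = if ("defined" %in% names(tab))
             sum(!tab$defined) else 0L)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
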