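#' Read a multivariate signal from delimited text
#'
#' Accepts comma- or whitespace-delimited numeric text, one row per time
#' sample, one column per channel. A single non-numeric first line is treated
#' as a header and skipped. Ragged rows and non-numeric cells are reported
#' with their line number.
#'
#' @param path Path to the text file.
#' @param sampling_rate Samples per second attached to the result (default 1).
#' @return A [signal_matrix()].
#' @export
read_signal <- function(path, sampling_rate = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty file: %s", path))
  split_row <- function(line) {
    strsplit(trimws(line), "[,[:space:]]+")[[1L]]
  }
  first <- suppressWarnings(as.numeric(split_row(lines[1L])))
  offset <- 0L
  if (anyNA(first)) {
    offset <- 1L  # header line
    lines <- lines[-1L]
    if (length(lines) == 0L) stop(sprintf("no data rows in %s", path))
  }
  cells <- lapply(lines, split_row)
  ncol <- length(cells[[1L]])
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) != ncol)
      stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                   i + offset, path, length(cells[[i]]), ncol))
    row <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(row))
      stop(sprintf("non-numeric value at line %d of %s", i + offset, path))
    cells[[i]] <- row
  }
  signal_matrix(do.call(rbind, cells), sampling_rate = sampling_rate)
}

#' Write a signal or total-persistence table to delimited text
#'
#' `write_signal()` writes a comma-separated matrix, one row per sample, no
#' header, with full float precision (`%.17g`), so a read-back via
#' [read_signal()] is bit-identical. `write_tp()` writes a [tv_total_persistence()]
#' table as CSV with a header (`window_index, end_time, tp0, ...`), also at
#' full precision; `read_tp()` reads it back.
#'
#' @param signal A [signal_matrix()] or numeric matrix.
#' @param curves A `tp_curves` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_signal <- function(signal, path) {
  m <- unclass(as_signal_matrix(signal))
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_signal
#' @export
write_tp <- function(curves, path) {
  if (!is.data.frame(curves) || nrow(curves) == 0L)
    stop("empty or invalid total-persistence table")
  df <- as.data.frame(curves)
  header <- paste(names(df), collapse = ",")
  body <- apply(df, 1L, function(r) {
    paste(c(sprintf("%d", as.integer(r[[1L]])),
            sprintf("%.17g", as.numeric(r[-1L]))), collapse = ",")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_tp <- function(path) {
  df <- utils::read.csv(path)
  df$window_index <- as.integer(df$window_index)
  class(df) <- c("tp_curves", "data.frame")
  attr(df, "maxdim") <- sum(grepl("^tp[0-9]+$", names(df))) - 1L
  df
}

#' Write a JSON report for a full break test
#'
#' Serializes the per-dimension test results together with the exact run
#' configuration (window, permutations, kmax, alternative, seed, package
#' version), so any reported p-value can be reproduced from the report alone.
#'
#' @param result A [run_full_test()] result.
#' @param config Named list echoing the run configuration.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(result, config, path) {
  if (!inherits(result, "full_break_test")) stop("not a full_break_test result")
  tests <- lapply(result$tests, function(t) list(
    observed_hfd = t$observed_hfd,
    p_value = t$p_value,
    n_permutations = t$n_permutations,
    mean_permuted_hfd = mean(t$permuted_hfds)))
  report <- list(
    package = "tdabreak",
    version = as.character(utils::packageVersion("tdabreak")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    results = tests)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
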