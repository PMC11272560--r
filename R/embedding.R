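#' Construct a multivariate signal matrix
#'
#' Wraps a numeric matrix of a multivariate time series (rows = time samples,
#' columns = channels/components) together with its sampling rate. Time is
#' indexed from 0, so sample `i` (1-based row) occurs at `(i - 1) / sampling_rate`
#' seconds.
#'
#' @param values Numeric matrix, `T x P`, all entries finite, `T >= 2`, `P >= 1`.
#' @param sampling_rate Samples per second (default 1).
#' @return An object of class `signal_matrix` (a numeric matrix with a
#'   `sampling_rate` attribute).
#' @export
signal_matrix <- function(values, sampling_rate = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 1L)
    stop("signal must have at least 2 time samples and 1 channel")
  if (!all(is.finite(values)))
    stop("signal contains non-finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number")
  structure(values, sampling_rate = sampling_rate, class = c("signal_matrix", "matrix"))
}

as_signal_matrix <- function(x, sampling_rate = 1) {
  if (inherits(x, "signal_matrix")) return(x)
  signal_matrix(x, sampling_rate)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d samples x %d channels @ %g Hz\n",
              nrow(x), ncol(x), attr(x, "sampling_rate")))
  print(head(unclass(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... (%d more rows)\n", nrow(x) - 4L))
  invisible(x)
}

#' Slice a signal into windowed point clouds
#'
#' The localized point cloud embedding: each window of `width` consecutive
#' samples of a `T x P` signal is treated as `width` points in `R^P`. Windows
#' start every `stride` samples (default `stride = width`, non-overlapping);
#' a trailing partial window is dropped. No centering or rescaling is applied.
#'
#' @param signal A [signal_matrix()] or plain numeric matrix.
#' @param width Window width `w` (number of samples, `2 <= width <= T`).
#' @param stride Hop between window starts (default `width`).
#' @return A list of point clouds; each element has `points` (`width x P`
#'   matrix), `window_index` (1-based) and `end_time` (time of the window's
#'   last sample, 0-based sample index over sampling rate).
#' @examples
#' x <- signal_matrix(matrix(rnorm(60), 20, 3), sampling_rate = 10)
#' clouds <- make_point_clouds(x, width = 5)
#' length(clouds)  # 4 non-overlapping windows
#' @export
make_point_clouds <- function(signal, width, stride = width) {
  signal <- as_signal_matrix(signal)
  n <- nrow(signal)
  width <- as.integer(width)
  stride <- as.integer(stride)
  if (width < 2L || width > n)
    stop("width must satisfy 2 <= width <= number of samples")
  if (stride < 1L)
    stop("stride must be a positive integer")
  rate <- attr(signal, "sampling_rate")
  n_win <- (n - width) %/% stride + 1L
  vals <- unclass(signal)
  lapply(seq_len(n_win), function(i) {
    start <- (i - 1L) * stride + 1L
    rows <- start:(start + width - 1L)
    list(points = vals[rows, , drop = FALSE],
         window_index = i,
         end_time = (rows[width] - 1L) / rate)
  })
}
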