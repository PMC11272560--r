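#' Deviations of a total-persistence curve from its mean
#'
#' Centers the curve at its global sample mean. Under the no-break null these
#' deviations fluctuate around zero with no systematic drift.
#'
#' @param tp Numeric series (a total-persistence curve), length at least 3
#'   and not constant.
#' @return A list of class `deviation_series` with `d` (the centered series,
#'   summing to zero) and `mean_tp`.
#' @export
deviations <- function(tp) {
  tp <- as.numeric(tp)
  if (length(tp) < 3L) stop("need a series of length >= 3")
  if (max(tp) == min(tp))
    stop("degenerate input: constant total-persistence curve")
  m <- mean(tp)
  structure(list(d = tp - m, mean_tp = m), class = "deviation_series")
}

#' CUSUM of a deviation series
#'
#' Prefix sums of the deviations with a leading zero: `S(0) = 0`,
#' `S(t) = S(t-1) + D(t)`. Because the deviations are mean-centered the CUSUM
#' returns to zero at the end; under the null it behaves like a random-walk
#' bridge, while a structural break produces a systematic excursion.
#'
#' @param dev A [deviations()] result (or a plain numeric vector of
#'   deviations).
#' @return Numeric vector of length `length(d) + 1` starting at 0.
#' @export
cusum <- function(dev) {
  d <- if (inherits(dev, "deviation_series")) dev$d else as.numeric(dev)
  c(0, cumsum(d))
}

#' Permutation break test on one total-persistence curve
#'
#' Tests for a structural break in the mean of a total-persistence curve.
#' The statistic is the Higuchi fractal dimension of the CUSUM of
#' mean-centered deviations: under the no-break null the CUSUM is a
#' random-walk-like bridge with HFD near 1.5, while a break drags the CUSUM
#' into a smooth excursion with HFD toward 1. The reference distribution is
#' built by uniformly permuting the deviations `B` times and recomputing the
#' CUSUM and its HFD; the p-value uses the add-one formula
#' `(1 + #extreme) / (B + 1)`, counting ties as extreme, so it is never zero.
#'
#' With `alternative = "lower"` (default) a permuted HFD is extreme when it
#' is at most the observed one; `"two_sided"` compares `|HFD - 1.5|`.
#'
#' @param tp Numeric total-persistence curve, non-constant, length at least
#'   `2 * kmax + 2`.
#' @param B Number of permutations (at least 19; default 999).
#' @param kmax Higuchi scale cap passed to [estimate_hfd()] (default 10).
#' @param alternative `"lower"` or `"two_sided"`.
#' @param seed Optional integer seed for the permutation stream.
#' @return An object of class `break_test`: list with `observed_hfd`,
#'   `permuted_hfds` (length `B`), `p_value`, `alternative`,
#'   `n_permutations`, `seed`, `mean_tp`, `cusum`.
#' @examples
#' set.seed(11)
#' p_null <- hfd_break_test(rnorm(300, 10), B = 99)$p_value
#' @export
hfd_break_test <- function(tp, B = 999, kmax = 10,
                           alternative = c("lower", "two_sided"),
                           seed = NULL) {
  alternative <- match.arg(alternative)
  B <- as.integer(B)
  if (B < 19L) stop("need at least 19 permutations")
  tp <- as.numeric(tp)
  if (length(tp) < 2L * kmax + 2L)
    stop("total-persistence curve too short for the HFD scale range")
  dev <- deviations(tp)
  s_obs <- cusum(dev)
  observed <- estimate_hfd(s_obs, kmax = kmax)$hfd
  if (!is.null(seed)) set.seed(seed)
  permuted <- vapply(seq_len(B), function(b) {
    estimate_hfd(c(0, cumsum(sample(dev$d))), kmax = kmax)$hfd
  }, numeric(1))
  extreme <- switch(alternative,
    lower = permuted <= observed,
    two_sided = abs(permuted - 1.5) >= abs(observed - 1.5))
  structure(list(observed_hfd = observed,
                 permuted_hfds = permuted,
                 p_value = (1 + sum(extreme)) / (B + 1L),
                 alternative = alternative,
                 n_permutations = B,
                 seed = seed,
                 mean_tp = dev$mean_tp,
                 cusum = s_obs),
            class = "break_test")
}

#' @export
print.break_test <- function(x, ...) {
  cat(sprintf(
    "<break_test> HFD(CUSUM) = %.4f, mean permuted = %.4f, p = %.4g (%s, B = %d)\n",
    x$observed_hfd, mean(x$permuted_hfds), x$p_value, x$alternative,
    x$n_permutations))
  invisible(x)
}

#' Full pipeline: signal to per-dimension break tests
#'
#' Computes the time-varying total-persistence curves with
#' [tv_total_persistence()] and applies [hfd_break_test()] to each homology
#' dimension `k = 0..maxdim`. Each per-dimension test draws its permutations
#' from an independent stream derived from `seed`.
#'
#' @inheritParams tv_total_persistence
#' @inheritParams hfd_break_test
#' @return An object of class `full_break_test`: list with `curves` (the
#'   [tv_total_persistence()] output) and `tests` (one `break_test` per
#'   dimension, named `"0"`, `"1"`, ...).
#' @export
run_full_test <- function(signal, width, stride = width, maxdim = 2,
                          eps_max = "auto", B = 999, kmax = 10,
                          alternative = c("lower", "two_sided"),
                          seed = NULL) {
  alternative <- match.arg(alternative)
  curves <- tv_total_persistence(signal, width, stride, maxdim, eps_max)
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, maxdim + 1L)
  tests <- lapply(0:maxdim, function(k) {
    hfd_break_test(curves[[paste0("tp", k)]], B = B, kmax = kmax,
                   alternative = alternative,
                   seed = child_seeds[k + 1L])
  })
  names(tests) <- as.character(0:maxdim)
  structure(list(curves = curves, tests = tests, seed = seed),
            class = "full_break_test")
}

#' @export
print.full_break_test <- function(x, ...) {
  cat(sprintf("<full_break_test> %d windows\n", nrow(x$curves)))
  for (k in names(x$tests)) {
    t <- x$tests[[k]]
    cat(sprintf("  H%s: HFD = %.4f, p = %.4g\n", k, t$observed_hfd, t$p_value))
  }
  invisible(x)
}
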