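#' Generate one epoch of a synthetic 3-D signal
#'
#' Draws `n_samples` points from one of the simulation patterns. All patterns
#' live in R^3 (the third coordinate is 0 for the planar ones); isotropic
#' Gaussian observation noise with standard deviation `noise_sd` is added to
#' every coordinate except for the `gaussian` pattern, which is pure noise
#' already.
#'
#' Patterns and their `params`:
#' \describe{
#'   \item{gaussian}{i.i.d. N(0, `sd`^2) per coordinate (`sd = 1`). Accepts a
#'     `dim` override for the number of coordinates.}
#'   \item{circle}{uniform angles on the radius-`radius` circle in the
#'     xy-plane (`radius = 4`).}
#'   \item{sphere}{uniform on the radius-`radius` sphere, via normalized
#'     Gaussian triples (`radius = 2.5`).}
#'   \item{infinity}{lemniscate of Bernoulli with half-width `scale` in the
#'     xy-plane, uniform parameter angle (`scale = 4`).}
#'   \item{torus}{independent uniform angles on the torus with major radius
#'     `R` and minor radius `r` (`R = 3`, `r = 1`; requires `R > r`).}
#'   \item{spiral}{3-D spiral: radius grows linearly from `r0` to `r1` over
#'     `turns` revolutions while the height drifts across `z_range`
#'     (`r0 = 0.5`, `r1 = 4`, `turns = 4`, `z_range = c(-2, 2)`); the
#'     parameter is drawn uniformly so each window sees the whole trace.}
#' }
#'
#' Uses the session RNG; call [set.seed()] for reproducibility.
#'
#' @param pattern One of `"gaussian"`, `"circle"`, `"sphere"`, `"infinity"`,
#'   `"torus"`, `"spiral"`.
#' @param n_samples Number of rows to generate (positive integer).
#' @param params Named list overriding the pattern defaults above.
#' @param noise_sd Standard deviation of additive isotropic Gaussian noise
#'   (default 0; ignored for `gaussian`).
#' @return An `n_samples x 3` numeric matrix (or `n_samples x dim` for a
#'   Gaussian epoch with a `dim` override).
#' @examples
#' set.seed(1)
#' ring <- generate_epoch("circle", 100, params = list(radius = 4))
#' range(sqrt(rowSums(ring^2)))  # all exactly 4 without noise
#' @export
generate_epoch <- function(pattern, n_samples, params = list(), noise_sd = 0) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  p <- function(name, default) {
    v <- if (!is.null(params[[name]])) params[[name]] else default
    v
  }
  pos <- function(v, name) {
    if (!is.numeric(v) || any(v <= 0)) stop(sprintf("'%s' must be > 0", name))
    v
  }
  out <- switch(pattern,
    gaussian = {
      sd <- pos(p("sd", 1), "sd")
      dim <- as.integer(p("dim", 3L))
      matrix(rnorm(n_samples * dim, 0, sd), n_samples, dim)
    },
    circle = {
      r <- pos(p("radius", 4), "radius")
      theta <- runif(n_samples, 0, 2 * pi)
      cbind(r * cos(theta), r * sin(theta), 0)
    },
    sphere = {
      r <- pos(p("radius", 2.5), "radius")
      g <- matrix(rnorm(n_samples * 3L), n_samples, 3L)
      g * (r / sqrt(rowSums(g^2)))
    },
    infinity = {
      a <- pos(p("scale", 4), "scale")
      t <- runif(n_samples, 0, 2 * pi)
      den <- 1 + sin(t)^2
      cbind(a * cos(t) / den, a * sin(t) * cos(t) / den, 0)
    },
    torus = {
      R <- pos(p("R", 3), "R")
      r <- pos(p("r", 1), "r")
      if (R <= r) stop("torus requires major radius R > minor radius r")
      u <- runif(n_samples, 0, 2 * pi)
      v <- runif(n_samples, 0, 2 * pi)
      cbind((R + r * cos(v)) * cos(u), (R + r * cos(v)) * sin(u), r * sin(v))
    },
    spiral = {
      r0 <- pos(p("r0", 0.5), "r0")
      r1 <- pos(p("r1", 4), "r1")
      turns <- pos(p("turns", 4), "turns")
      zr <- p("z_range", c(-2, 2))
      u <- runif(n_samples)
      theta <- u * turns * 2 * pi
      rad <- r0 + (r1 - r0) * u
      cbind(rad * cos(theta), rad * sin(theta), zr[1] + (zr[2] - zr[1]) * u)
    },
    stop(sprintf("unknown pattern '%s'", pattern))
  )
  if (noise_sd > 0 && pattern != "gaussian")
    out <- out + matrix(rnorm(length(out), 0, noise_sd), nrow(out), ncol(out))
  out
}

#' Assemble a preset simulation scenario
#'
#' The two study designs used throughout the simulations, each 15,000 samples
#' of a 3-channel signal at 100 samples per second:
#' \describe{
#'   \item{example1}{five 30-second epochs of 3,000 samples: Gaussian(sd 1),
#'     circle (radius 4), Gaussian, sphere (radius 2.5), Gaussian; analysed
#'     with window width 50.}
#'   \item{example2}{three 50-second epochs of 5,000 samples: infinity-like,
#'     torus-like (R 3, r 1), spiral-like; analysed with window width 150.}
#' }
#' Manifold epochs carry additive observation noise with standard deviation
#' `noise_sd` so their point clouds are full-dimensional.
#'
#' @param name `"example1"` or `"example2"`.
#' @param noise_sd Observation-noise standard deviation on manifold epochs
#'   (default 0.1).
#' @return A list with `signal` (a [signal_matrix()] at 100 Hz) and `preset`
#'   (epoch metadata: pattern, samples, window width, sampling rate, epoch
#'   start/end times in seconds).
#' @examples
#' set.seed(7)
#' sc <- build_scenario("example1")
#' dim(sc$signal)  # 15000 x 3
#' @export
build_scenario <- function(name, noise_sd = 0.1) {
  epochs <- switch(name,
    example1 = list(
      list(pattern = "gaussian", n = 3000L, params = list(sd = 1)),
      list(pattern = "circle",   n = 3000L, params = list(radius = 4)),
      list(pattern = "gaussian", n = 3000L, params = list(sd = 1)),
      list(pattern = "sphere",   n = 3000L, params = list(radius = 2.5)),
      list(pattern = "gaussian", n = 3000L, params = list(sd = 1))),
    example2 = list(
      list(pattern = "infinity", n = 5000L, params = list(scale = 4)),
      list(pattern = "torus",    n = 5000L, params = list(R = 3, r = 1)),
      list(pattern = "spiral",   n = 5000L, params = list())),
    stop(sprintf("unknown scenario '%s'", name))
  )
  window_width <- if (name == "example1") 50L else 150L
  rate <- 100
  segs <- lapply(epochs, function(e)
    generate_epoch(e$pattern, e$n, e$params, noise_sd = noise_sd))
  sig <- signal_matrix(do.call(rbind, segs), sampling_rate = rate)
  ends <- cumsum(vapply(epochs, `[[`, integer(1), "n")) / rate
  preset <- list(
    name = name,
    epochs = data.frame(
      pattern = vapply(epochs, `[[`, character(1), "pattern"),
      n_samples = vapply(epochs, `[[`, integer(1), "n"),
      start_time = c(0, ends[-length(ends)]),
      end_time = ends),
    sampling_rate = rate,
    window_width = window_width,
    noise_sd = noise_sd)
  list(signal = sig, preset = preset)
}

#' Univariate reference processes for fractal-dimension calibration
#'
#' `generate_brownian()` returns a standard Brownian path: cumulative sums of
#' independent N(0, `dt`) increments, starting at 0. `generate_white_noise()`
#' returns i.i.d. N(0, `sd`^2) draws. `generate_smooth_curve()` evaluates the
#' smooth deterministic curve `x(t) = t cos(t^2 / 10)` on an even grid over
#' `[0, t_max]`.
#'
#' @param n_samples Series length (at least 2).
#' @param dt Increment variance per step (default `1 / n_samples`).
#' @param sd Noise standard deviation.
#' @param t_max Upper end of the evaluation grid.
#' @return A numeric vector of length `n_samples`.
#' @export
generate_brownian <- function(n_samples, dt = 1 / n_samples) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("n_samples must be >= 2")
  cumsum(c(0, rnorm(n_samples - 1L, 0, sqrt(dt))))
}

#' @rdname generate_brownian
#' @export
generate_white_noise <- function(n_samples, sd = 1) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("n_samples must be >= 2")
  rnorm(n_samples, 0, sd)
}

#' @rdname generate_brownian
#' @export
generate_smooth_curve <- function(n_samples, t_max = 30) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("n_samples must be >= 2")
  t <- seq(0, t_max, length.out = n_samples)
  t * cos(t^2 / 10)
}

#' Fractional Brownian motion by circulant embedding
#'
#' Exact synthesis of fractional Brownian motion with Hurst exponent
#' `hurst` on the grid `t_i = i * dt` via the Davies-Harte method: the
#' stationary fractional Gaussian noise increments are drawn with their exact
#' Toeplitz covariance embedded in a circulant matrix diagonalized by the FFT.
#' On the unit-`dt` scale `Var[B_H(t)] = t^(2H)`; `hurst = 0.5` reduces to
#' standard Brownian motion with independent increments of variance `dt`.
#'
#' @param n_samples Series length (at least 2); the path starts at 0.
#' @param hurst Hurst exponent in (0, 1).
#' @param dt Time step (default 1).
#' @return Numeric vector of length `n_samples`.
#' @examples
#' set.seed(3)
#' b <- generate_fbm(1024, hurst = 0.7)
#' @export
generate_fbm <- function(n_samples, hurst, dt = 1) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("hurst must lie strictly between 0 and 1")
  if (dt <= 0) stop("dt must be > 0")
  n <- n_samples - 1L  # number of increments
  h2 <- 2 * hurst
  acov <- function(h) 0.5 * (abs(h + 1)^h2 - 2 * abs(h)^h2 + abs(h - 1)^h2)
  if (n == 1L) {
    fgn <- rnorm(1L)
  } else {
    m <- 2L * n
    lam <- Re(fft(c(acov(0:n), acov((n - 1):1))))
    if (min(lam) < -1e-8 * max(lam))
      stop("circulant embedding is not non-negative definite")
    lam <- pmax(lam, 0)
    a <- rnorm(n + 1L)
    w <- complex(length.out = m)
    w[1L] <- sqrt(lam[1L] / m) * a[1L]
    w[n + 1L] <- sqrt(lam[n + 1L] / m) * a[n + 1L]
    k <- 2:n
    b <- rnorm(n - 1L)
    w[k] <- sqrt(lam[k] / (2 * m)) * complex(real = a[k], imaginary = b)
    w[m + 2L - k] <- Conj(w[k])
    fgn <- Re(fft(w))[1:n]
  }
  c(0, cumsum(fgn)) * dt^hurst
}
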