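#' Higuchi curve length at one scale and offset
#'
#' The normalized lag-`k` curve length of a univariate series starting at
#' offset `m` (1-based):
#' \deqn{L_m(k) = \frac{T - 1}{\lfloor (T-m)/k \rfloor \, k^2}
#'       \sum_{i=1}^{\lfloor (T-m)/k \rfloor} |X(m + ik) - X(m + (i-1)k)|}
#' `higuchi_length(x, k)` averages \eqn{L_m(k)} over the offsets
#' `m = 1, ..., k`.
#'
#' @param x Numeric vector (the series), 1-based time indexing.
#' @param m Offset, `1 <= m <= k`.
#' @param k Scale (lag), with `floor((T - m) / k) >= 1`.
#' @return A non-negative number (0 only for a locally constant series).
#' @examples
#' higuchi_length_m(c(0, 1, 0, 1, 0), m = 1, k = 1)  # 4
#' higuchi_length(seq_len(100), k = 5)               # (T - 1) / k = 19.8
#' @export
higuchi_length_m <- function(x, m, k) {
  T <- length(x)
  m <- as.integer(m)
  k <- as.integer(k)
  if (k < 1L || m < 1L || m > k) stop("need 1 <= m <= k")
  if ((T - m) %/% k < 1L) stop("scale k too large for the series length")
  idx <- seq.int(m, T, by = k)
  N <- length(idx) - 1L
  sum(abs(diff(x[idx]))) * (T - 1) / (N * k^2)
}

#' @rdname higuchi_length_m
#' @export
higuchi_length <- function(x, k) {
  k <- as.integer(k)
  mean(vapply(seq_len(k), function(m) higuchi_length_m(x, m, k), numeric(1)))
}

#' Higuchi fractal dimension of a univariate series
#'
#' Estimates the fractal dimension from the scaling law `L(k) ~ k^(-HFD)`:
#' the curve length [higuchi_length()] is computed at every integer scale
#' `k = 1, ..., kmax` and the HFD is the OLS slope of `log L(k)` on
#' `log(1/k)` (natural logs; the slope is base-invariant). Values near 1
#' indicate a smooth curve, 1.5 a random walk, and 2 white noise.
#'
#' @param x Numeric series, non-constant, with `length(x) >= 2 * kmax + 1`.
#' @param kmax Largest scale in the fit (default 10, at least 2).
#' @return An object of class `hfd_estimate`: a list with `hfd` (the slope),
#'   `lengths` (data frame of `k` and `L`), and `fit_r2`.
#' @examples
#' estimate_hfd(seq_len(1000))$hfd  # exactly 1 for a straight line
#' @export
estimate_hfd <- function(x, kmax = 10) {
  kmax <- as.integer(kmax)
  if (kmax < 2L) stop("kmax must be >= 2")
  T <- length(x)
  if (T < 2L * kmax + 1L)
    stop("series too short: need length >= 2 * kmax + 1")
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    s <- 0
    for (m in seq_len(k)) {
      idx <- seq.int(m, T, by = k)
      N <- length(idx) - 1L
      s <- s + sum(abs(diff(x[idx]))) * (T - 1) / (N * k * k)
    }
    L[k] <- s / k
  }
  if (any(L <= 0))
    stop("degenerate input: zero curve length at some scale (constant series?)")
  lx <- log(1 / seq_len(kmax))
  ly <- log(L)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  r2 <- cor(lx, ly)^2
  structure(list(hfd = slope,
                 lengths = data.frame(k = seq_len(kmax), L = L),
                 fit_r2 = r2,
                 kmax = kmax),
            class = "hfd_estimate")
}

#' @export
print.hfd_estimate <- function(x, ...) {
  cat(sprintf("<hfd_estimate> HFD = %.4f (kmax %d, fit R^2 = %.4f)\n",
              x$hfd, x$kmax, x$fit_r2))
  invisible(x)
}

#' Box-counting fractal dimension of a planar point set
#'
#' Covers the set with axis-aligned square grids of decreasing box size `r`
#' anchored at the bounding-box minimum, counts the occupied boxes `N_r`, and
#' estimates the dimension as the OLS slope of `log N_r` on `log(1/r)`.
#'
#' @param points A two-column numeric matrix of coordinates (at least 2
#'   distinct points).
#' @param scales Decreasing vector of at least 3 box sizes.
#' @return An object of class `boxcount_estimate`: list with `dim`, `counts`
#'   (data frame of `r` and `N`), and `fit_r2`.
#' @examples
#' grid <- as.matrix(expand.grid(seq(0, 1, 1 / 64), seq(0, 1, 1 / 64)))
#' box_counting_dim(grid, scales = c(1 / 2, 1 / 4, 1 / 8))$dim  # about 2
#' @export
box_counting_dim <- function(points, scales) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have 2 columns")
  if (nrow(unique(points)) < 2L) stop("need at least 2 distinct points")
  if (length(scales) < 3L) stop("need at least 3 scales")
  mins <- apply(points, 2L, min)
  rng <- apply(points, 2L, max) - mins
  N <- vapply(scales, function(r) {
    nb <- pmax(ceiling(rng / r), 1)
    ix <- pmin(floor((points[, 1L] - mins[1L]) / r), nb[1L] - 1)
    iy <- pmin(floor((points[, 2L] - mins[2L]) / r), nb[2L] - 1)
    nrow(unique(cbind(ix, iy)))
  }, numeric(1))
  lx <- log(1 / scales)
  ly <- log(N)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  structure(list(dim = slope,
                 counts = data.frame(r = scales, N = N),
                 fit_r2 = cor(lx, ly)^2),
            class = "boxcount_estimate")
}

#' @export
print.boxcount_estimate <- function(x, ...) {
  cat(sprintf("<boxcount_estimate> dim = %.4f (fit R^2 = %.4f)\n",
              x$dim, x$fit_r2))
  invisible(x)
}

#' Sierpinski triangle point set
#'
#' Deterministic level-`level` approximation of the Sierpinski triangle with
#' vertices (0,0), (1,0), (0,1): all `3^level` images of the origin under
#' `level`-fold compositions of the three halving maps. With dyadic box sizes
#' anchored at the origin the occupied-box counts are exactly `3^k`, making
#' the set a closed-form oracle (dimension `log 3 / log 2`) for
#' [box_counting_dim()].
#'
#' @param level Recursion depth (default 7).
#' @return A `3^level x 2` matrix of coordinates.
#' @export
sierpinski_points <- function(level = 7) {
  v <- rbind(c(0, 0), c(1, 0), c(0, 1))
  pts <- matrix(0, 1, 2)
  for (i in seq_len(level)) {
    pts <- do.call(rbind, lapply(1:3, function(j)
      sweep(pts / 2, 2L, v[j, ] / 2, "+")))
  }
  pts
}
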