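#' Vietoris-Rips persistence diagram of a point cloud
#'
#' Computes persistent homology of the Vietoris-Rips filtration of a Euclidean
#' point cloud, up to homology dimension `maxdim`, over Z/2 coefficients. The
#' engine uses persistent cohomology with clearing; dimension 0 is computed by
#' Kruskal/union-find, so the finite 0-dimensional deaths are exactly the
#' minimum-spanning-tree edge weights.
#'
#' Only features with strictly positive persistence are reported, plus
#' essential (infinite-death) classes. With `eps_max = "auto"` the filtration
#' is truncated at the cloud's enclosing radius (the smallest `r` such that
#' some point is within `r` of every other); at that scale the complex is a
#' cone, so the resulting diagram is identical to the one obtained from the
#' full filtration up to the maximum pairwise distance, and every class in
#' dimensions 1..`maxdim` has a finite death. A nonempty cloud always has
#' exactly one essential dimension-0 class (per connected component at the
#' truncation scale).
#'
#' @param cloud A numeric matrix of points (rows = points), or a point-cloud
#'   element as returned by [make_point_clouds()].
#' @param maxdim Maximum homology dimension, 0, 1 or 2 (default 2).
#' @param eps_max `"auto"` (default) or a positive numeric filtration cutoff.
#' @return A data frame of class `persistence_diagram` with columns
#'   `dimension`, `birth`, `death` (`Inf` for essential classes).
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 51)[-51]
#' circ <- cbind(4 * cos(theta), 4 * sin(theta), 0)
#' d <- rips_diagram(circ, maxdim = 1)
#' subset(d, dimension == 1)  # one prominent loop
#' @export
rips_diagram <- function(cloud, maxdim = 2, eps_max = "auto") {
  if (is.list(cloud) && !is.null(cloud$points)) cloud <- cloud$points
  cloud <- as.matrix(cloud)
  storage.mode(cloud) <- "double"
  if (nrow(cloud) < 2L) stop("point cloud must contain at least 2 points")
  if (!all(is.finite(cloud))) stop("point cloud contains non-finite coordinates")
  maxdim <- as.integer(maxdim)
  if (!maxdim %in% 0:2) stop("maxdim must be 0, 1 or 2")
  if (identical(eps_max, "auto")) {
    dm <- as.matrix(stats::dist(cloud))
    threshold <- min(apply(dm, 1L, max))  # enclosing radius
  } else {
    if (!is.numeric(eps_max) || length(eps_max) != 1L || !is.finite(eps_max) ||
        eps_max <= 0)
      stop("eps_max must be \"auto\" or a positive number")
    threshold <- eps_max
  }
  m <- rips_pairs_cpp(cloud, maxdim, threshold)
  out <- data.frame(dimension = as.integer(m[, 1L]),
                    birth = m[, 2L], death = m[, 3L])
  out <- out[order(out$dimension, out$birth, out$death), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("persistence_diagram", "data.frame")
  attr(out, "maxdim") <- maxdim
  attr(out, "eps_max") <- eps_max
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> %d features (maxdim %d)\n",
              nrow(x), attr(x, "maxdim")))
  for (k in sort(unique(x$dimension))) {
    sub <- x[x$dimension == k, ]
    cat(sprintf("  H%d: %d features, total persistence %.4g\n",
                k, nrow(sub), total_persistence(x, k)))
  }
  invisible(x)
}

#' Total persistence of a diagram in one homology dimension
#'
#' The sum of lifetimes `death - birth` over all finite-death features of
#' dimension `k`. Essential (infinite-death) classes are excluded, so the
#' value is always finite; an empty dimension contributes 0.
#'
#' @param diagram A [rips_diagram()] result (or any data frame with columns
#'   `dimension`, `birth`, `death`).
#' @param k Homology dimension.
#' @return A non-negative number.
#' @export
total_persistence <- function(diagram, k) {
  sub <- diagram[diagram$dimension == k & is.finite(diagram$death), , drop = FALSE]
  if (nrow(sub) == 0L) return(0)
  sum(sub$death - sub$birth)
}

#' Time-varying total persistence curves
#'
#' The pipeline's topological summary: slice the signal into windows with
#' [make_point_clouds()], compute each window's Rips diagram, and reduce it to
#' total persistence per homology dimension. The result is one curve
#' `TP_k(t)` per dimension `k = 0..maxdim`, indexed by window end-time.
#'
#' Windows whose points are all identical yield zero total persistence in
#' every dimension.
#'
#' @inheritParams make_point_clouds
#' @inheritParams rips_diagram
#' @return A data frame of class `tp_curves` with columns `window_index`,
#'   `end_time` and `tp0`, ..., up to `maxdim`. Missing dimensions beyond
#'   `maxdim` are omitted.
#' @export
tv_total_persistence <- function(signal, width, stride = width,
                                 maxdim = 2, eps_max = "auto") {
  clouds <- make_point_clouds(signal, width, stride)
  maxdim <- as.integer(maxdim)
  tp <- matrix(0, nrow = length(clouds), ncol = maxdim + 1L)
  for (i in seq_along(clouds)) {
    pts <- clouds[[i]]$points
    if (all(pts == rep(pts[1L, ], each = nrow(pts)))) next  # degenerate window
    d <- rips_diagram(pts, maxdim = maxdim, eps_max = eps_max)
    for (k in 0:maxdim) tp[i, k + 1L] <- total_persistence(d, k)
  }
  out <- data.frame(
    window_index = vapply(clouds, `[[`, integer(1), "window_index"),
    end_time = vapply(clouds, `[[`, numeric(1), "end_time"))
  for (k in 0:maxdim) out[[paste0("tp", k)]] <- tp[, k + 1L]
  class(out) <- c("tp_curves", "data.frame")
  attr(out, "maxdim") <- maxdim
  attr(out, "width") <- as.integer(width)
  attr(out, "stride") <- as.integer(stride)
  out
}

#' @export
print.tp_curves <- function(x, ...) {
  cat(sprintf("<tp_curves> %d windows (width %d, stride %d), maxdim %d\n",
              nrow(x), attr(x, "width"), attr(x, "stride"), attr(x, "maxdim")))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... (%d more windows)\n", nrow(x) - 5L))
  invisible(x)
}
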