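# Independent brute-force oracles used to cross-check the Rips engine and the
# Higuchi estimator on small inputs. Deliberately naive: full simplex
# enumeration and textbook left-to-right boundary-matrix reduction over Z/2.

# All subsets of 1..n of given size, as a list of integer vectors.
oracle_subsets <- function(n, size) {
  if (size > n) return(list())
  m <- utils::combn(n, size)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

# Persistence pairs of the full Vietoris-Rips filtration (no threshold) by
# standard boundary reduction. Returns data.frame(dimension, birth, death),
# zero-persistence pairs dropped, essential classes with death = Inf.
oracle_rips <- function(pts, maxdim = 2) {
  n <- nrow(pts)
  dm <- as.matrix(stats::dist(pts))
  simp <- list()
  for (size in 1:(maxdim + 2)) {
    for (vs in oracle_subsets(n, size)) {
      diam <- if (size == 1L) 0 else max(dm[vs, vs])
      simp[[length(simp) + 1L]] <- list(vs = vs, dim = size - 1L, diam = diam)
    }
  }
  # filtration order: diameter, then dimension (faces first), then lexicographic
  keys <- vapply(simp, function(s)
    paste(sprintf("%020.12f", s$diam), s$dim,
          paste(sprintf("%04d", s$vs), collapse = "")), character(1))
  ord <- order(vapply(simp, `[[`, numeric(1), "diam"),
               vapply(simp, `[[`, integer(1), "dim"),
               keys)
  simp <- simp[ord]
  pos <- new.env(hash = TRUE)
  for (i in seq_along(simp))
    assign(paste(simp[[i]]$vs, collapse = ","), i, envir = pos)
  # boundary columns as sorted row-index vectors
  cols <- lapply(simp, function(s) {
    if (s$dim == 0L) return(integer(0))
    sort(vapply(seq_along(s$vs), function(drop_i)
      get(paste(s$vs[-drop_i], collapse = ","), envir = pos), integer(1)))
  })
  low <- function(v) if (length(v)) v[length(v)] else 0L
  pivot_owner <- integer(length(cols))  # 0 = free
  pairs <- matrix(numeric(0), ncol = 2)
  paired <- logical(length(cols))
  for (j in seq_along(cols)) {
    v <- cols[[j]]
    while (length(v) && pivot_owner[low(v)] != 0L) {
      other <- cols[[pivot_owner[low(v)]]]
      v <- sort(c(setdiff(v, other), setdiff(other, v)))
    }
    cols[[j]] <- v
    if (length(v)) {
      pivot_owner[low(v)] <- j
      paired[low(v)] <- TRUE
      paired[j] <- TRUE
      pairs <- rbind(pairs, c(low(v), j))
    }
  }
  out <- data.frame(dimension = integer(0), birth = numeric(0), death = numeric(0))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (simp[[i]]$dim > maxdim) next
    b <- simp[[i]]$diam; d <- simp[[j]]$diam
    if (d > b) out <- rbind(out, data.frame(dimension = simp[[i]]$dim, birth = b, death = d))
  }
  for (j in seq_along(cols))
    if (!paired[j] && simp[[j]]$dim <= maxdim)
      out <- rbind(out, data.frame(dimension = simp[[j]]$dim,
                                   birth = simp[[j]]$diam, death = Inf))
  out[order(out$dimension, out$birth, out$death), , drop = FALSE]
}

# Direct transcription of the Higuchi length formula for one offset.
oracle_higuchi_lm <- function(x, m, k) {
  T <- length(x)
  N <- floor((T - m) / k)
  s <- 0
  for (i in seq_len(N)) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
  s * (T - 1) / (N * k^2)
}

# Sorted finite positive-persistence bars of one dimension, for comparisons.
bars_of <- function(diag, k) {
  sub <- diag[diag$dimension == k & is.finite(diag$death), , drop = FALSE]
  sub <- sub[sub$death > sub$birth, , drop = FALSE]
  sub <- sub[order(sub$birth, sub$death), , drop = FALSE]
  matrix(as.numeric(unlist(sub[, c("birth", "death")])), ncol = 2)
}
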