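test_that("two points at distance d give one finite and one infinite H0 bar", {
  d <- rips_diagram(rbind(c(0, 0), c(3, 0)), maxdim = 0)
  h0 <- d[d$dimension == 0, ]
  expect_equal(nrow(h0), 2L)
  expect_equal(sort(h0$birth), c(0, 0))
  expect_equal(sort(h0$death), c(3, Inf))
})

test_that("diagrams match the brute-force reduction oracle on small clouds", {
  set.seed(20)
  for (rep in 1:6) {
    n <- sample(5:11, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    fast <- rips_diagram(pts, maxdim = 2)
    slow <- oracle_rips(pts, maxdim = 2)
    for (k in 0:2)
      expect_equal(bars_of(fast, k), bars_of(slow, k), tolerance = 1e-9)
    expect_equal(sum(fast$dimension == 0 & !is.finite(fast$death)), 1L)
  }
})

test_that("TP0 equals the minimum-spanning-tree total weight", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:4) {
    n <- sample(6:12, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    d <- rips_diagram(pts, maxdim = 0)
    g <- igraph::graph_from_adjacency_matrix(as.matrix(dist(pts)),
                                             mode = "undirected",
                                             weighted = TRUE)
    mst_w <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(total_persistence(d, 0), mst_w, tolerance = 1e-10)
    expect_equal(sum(d$dimension == 0 & is.finite(d$death)), n - 1L)
  }
})

test_that("total persistence sums finite lifetimes and excludes infinite bars", {
  dg <- data.frame(dimension = c(1L, 1L), birth = c(0, 0.5), death = c(1, 2))
  expect_equal(total_persistence(dg, 1), 2.5)
  expect_equal(total_persistence(dg, 2), 0)
  dg0 <- data.frame(dimension = c(0L, 0L), birth = c(0, 0), death = c(Inf, 0.7))
  expect_equal(total_persistence(dg0, 0), 0.7)
  expect_equal(total_persistence(dg[0, ], 1), 0)
})

test_that("a dense noise-free circle has one dominant H1 feature dying near sqrt(3) r", {
  theta <- seq(0, 2 * pi, length.out = 51)[-51]
  circ <- cbind(4 * cos(theta), 4 * sin(theta), 0)
  d <- rips_diagram(circ, maxdim = 1)
  pers <- sort(bars_of(d, 1)[, 2] - bars_of(d, 1)[, 1], decreasing = TRUE)
  expect_gte(length(pers), 1L)
  if (length(pers) > 1L) expect_gt(pers[1], 3 * pers[2])
  expect_equal(max(bars_of(d, 1)[, 2]), sqrt(3) * 4, tolerance = 0.2)
})

test_that("a sphere cloud carries more H2 persistence than a matched Gaussian cloud", {
  set.seed(22)
  sph <- generate_epoch("sphere", 150, params = list(radius = 2.5))
  gau <- generate_epoch("gaussian", 150, params = list(sd = 1))
  tp2_sph <- total_persistence(rips_diagram(sph, maxdim = 2), 2)
  tp2_gau <- total_persistence(rips_diagram(gau, maxdim = 2), 2)
  expect_gt(tp2_sph, tp2_gau)
})

test_that("diagrams are scale-equivariant and invariant to point order", {
  set.seed(23)
  pts <- matrix(rnorm(12 * 3), 12, 3)
  base <- rips_diagram(pts, maxdim = 2)
  scaled <- rips_diagram(pts * 2.5, maxdim = 2)
  for (k in 0:2) {
    expect_equal(bars_of(scaled, k), 2.5 * bars_of(base, k), tolerance = 1e-9)
    expect_equal(total_persistence(scaled, k), 2.5 * total_persistence(base, k),
                 tolerance = 1e-9)
  }
  perm <- rips_diagram(pts[sample(12), ], maxdim = 2)
  for (k in 0:2)
    expect_equal(bars_of(perm, k), bars_of(base, k), tolerance = 1e-9)
})

test_that("tv_total_persistence aligns curves to window end-times", {
  set.seed(24)
  sig <- signal_matrix(matrix(rnorm(600), 200, 3), sampling_rate = 100)
  cv <- tv_total_persistence(sig, width = 50, maxdim = 1)
  expect_equal(nrow(cv), 4L)
  expect_named(cv, c("window_index", "end_time", "tp0", "tp1"))
  expect_equal(cv$end_time, c(0.49, 0.99, 1.49, 1.99))
  expect_true(all(cv$tp0 >= 0) && all(cv$tp1 >= 0))
})

test_that("a constant signal yields identically zero total persistence", {
  sig <- signal_matrix(matrix(1, 40, 3))
  cv <- tv_total_persistence(sig, width = 10, maxdim = 2)
  expect_true(all(cv$tp0 == 0) && all(cv$tp1 == 0) && all(cv$tp2 == 0))
})

test_that("rips_diagram validates its inputs", {
  expect_error(rips_diagram(matrix(1, 1, 2)), "at least 2")
  expect_error(rips_diagram(matrix(c(0, 1, NA, 1), 2, 2)), "non-finite")
  expect_error(rips_diagram(matrix(rnorm(10), 5, 2), maxdim = 3), "maxdim")
  expect_error(rips_diagram(matrix(rnorm(10), 5, 2), eps_max = -1), "eps_max")
})
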