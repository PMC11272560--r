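test_that("noise-free manifold epochs satisfy their defining equations", {
  set.seed(1)
  circ <- generate_epoch("circle", 200, params = list(radius = 4))
  expect_equal(sqrt(rowSums(circ^2)), rep(4, 200), tolerance = 1e-12)
  expect_equal(circ[, 3], rep(0, 200))

  sph <- generate_epoch("sphere", 200, params = list(radius = 2.5))
  expect_equal(sqrt(rowSums(sph^2)), rep(2.5, 200), tolerance = 1e-12)

  # lemniscate of Bernoulli: (x^2 + y^2)^2 = a^2 (x^2 - y^2)
  inf <- generate_epoch("infinity", 200, params = list(scale = 4))
  lhs <- (inf[, 1]^2 + inf[, 2]^2)^2
  rhs <- 16 * (inf[, 1]^2 - inf[, 2]^2)
  expect_equal(lhs, rhs, tolerance = 1e-8)

  # torus: (sqrt(x^2 + y^2) - R)^2 + z^2 = r^2
  tor <- generate_epoch("torus", 200, params = list(R = 3, r = 1))
  expect_equal((sqrt(tor[, 1]^2 + tor[, 2]^2) - 3)^2 + tor[, 3]^2,
               rep(1, 200), tolerance = 1e-12)
})

test_that("gaussian epochs match their nominal moments", {
  set.seed(2)
  g <- generate_epoch("gaussian", 3000, params = list(sd = 1))
  expect_equal(dim(g), c(3000L, 3L))
  band <- 4 / sqrt(3000)
  expect_true(all(abs(colMeans(g)) < band))
  expect_true(all(abs(apply(g, 2, sd) - 1) < band))
})

test_that("epoch generation validates its inputs", {
  expect_error(generate_epoch("hexagon", 10), "unknown pattern")
  expect_error(generate_epoch("circle", 0), "n_samples")
  expect_error(generate_epoch("circle", 10, params = list(radius = -1)), "> 0")
  expect_error(generate_epoch("torus", 10, params = list(R = 1, r = 2)),
               "R > minor")
})

test_that("scenario presets have the stated layout and are seed-reproducible", {
  set.seed(3)
  sc1 <- build_scenario("example1")
  expect_equal(dim(sc1$signal), c(15000L, 3L))
  expect_equal(sc1$preset$window_width, 50L)
  expect_equal(sc1$preset$epochs$n_samples, rep(3000L, 5))
  expect_equal(sc1$preset$epochs$pattern,
               c("gaussian", "circle", "gaussian", "sphere", "gaussian"))
  expect_equal(attr(sc1$signal, "sampling_rate"), 100)

  set.seed(4)
  sc2 <- build_scenario("example2")
  expect_equal(dim(sc2$signal), c(15000L, 3L))
  expect_equal(sc2$preset$window_width, 150L)
  expect_equal(sc2$preset$epochs$n_samples, rep(5000L, 3))

  set.seed(99); a <- build_scenario("example1")$signal
  set.seed(99); b <- build_scenario("example1")$signal
  expect_identical(unclass(a), unclass(b))
  expect_error(build_scenario("example9"), "unknown scenario")
})

test_that("univariate reference processes behave as specified", {
  set.seed(5)
  b <- generate_brownian(1000, dt = 0.01)
  expect_identical(b[1], 0)
  expect_equal(length(b), 1000L)

  w <- generate_white_noise(10000, sd = 3)
  expect_lt(abs(sd(w) - 3), 0.15)

  s <- generate_smooth_curve(10000, t_max = 30)
  t <- seq(0, 30, length.out = 10000)
  expect_equal(s, t * cos(t^2 / 10))
})

test_that("fBm has independent increments at H = 0.5 and the right variance scaling", {
  set.seed(6)
  n <- 2^12
  x <- generate_fbm(n, hurst = 0.5)
  inc <- diff(x)
  rho <- cor(inc[-1], inc[-length(inc)])
  expect_lt(abs(rho), 3 / sqrt(n))

  for (H in c(0.3, 0.7)) {
    set.seed(7)
    # pool increments over a few paths for a stable variance ratio
    v1 <- v8 <- numeric(0)
    for (r in 1:8) {
      x <- generate_fbm(n, hurst = H)
      v1 <- c(v1, diff(x, lag = 1))
      v8 <- c(v8, diff(x, lag = 8))
    }
    ratio <- var(v8) / var(v1)
    expect_lt(abs(ratio / 8^(2 * H) - 1), 0.15)
  }
  expect_error(generate_fbm(100, hurst = 1.2), "hurst")
  expect_error(generate_fbm(100, hurst = 0), "hurst")
})
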