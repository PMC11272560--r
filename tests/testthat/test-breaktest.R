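test_that("deviations center at the global mean and sum to zero", {
  d <- deviations(c(1, 2, 3))
  expect_equal(d$d, c(-1, 0, 1))
  expect_equal(d$mean_tp, 2)
  set.seed(40)
  tp <- rexp(57)
  expect_equal(sum(deviations(tp)$d), 0, tolerance = 1e-12)
  expect_error(deviations(c(5, 5, 5)), "degenerate")
  expect_error(deviations(c(1, 2)), "length")
})

test_that("cusum is the prefix sum with a leading zero, closing at zero", {
  expect_equal(cusum(c(1, -2, 1)), c(0, 1, -1, 0))
  expect_equal(cusum(c(-1, 0, 1)), c(0, -1, -1, 0))
  set.seed(41)
  d <- deviations(rnorm(30))
  s <- cusum(d)
  expect_equal(s[1], 0)
  expect_equal(diff(s), d$d)
  expect_equal(s[length(s)], 0, tolerance = 1e-12)
})

test_that("permutation p-values are valid, never zero, and seed-reproducible", {
  set.seed(42)
  tp <- rnorm(100, 10)
  r1 <- hfd_break_test(tp, B = 99, seed = 7)
  r2 <- hfd_break_test(tp, B = 99, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$permuted_hfds, r2$permuted_hfds)
  expect_gte(r1$p_value, 1 / 100)
  expect_lte(r1$p_value, 1)
  expect_length(r1$permuted_hfds, 99L)
  expect_error(hfd_break_test(tp, B = 10), "19")
  expect_error(hfd_break_test(rnorm(15), B = 99), "too short")
})

test_that("under the null the observed CUSUM HFD concentrates near 1.5", {
  set.seed(43)
  obs <- replicate(100, {
    estimate_hfd(cusum(deviations(rnorm(300, 10))))$hfd
  })
  expect_gt(mean(obs), 1.35)
  expect_lt(mean(obs), 1.65)
})

test_that("the permutation null is unchanged by pre-permuting the curve", {
  set.seed(44)
  tp <- rnorm(150, 10)
  a <- hfd_break_test(tp, B = 200, seed = 1)$permuted_hfds
  b <- hfd_break_test(sample(tp), B = 200, seed = 2)$permuted_hfds
  ks <- suppressWarnings(ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("an injected mean shift is detected with high power", {
  set.seed(45)
  rejected <- replicate(30, {
    tp <- rnorm(300, 10)
    tp[101:200] <- tp[101:200] + 3
    hfd_break_test(tp, B = 199)$p_value <= 0.05
  })
  expect_gte(mean(rejected), 0.9)
})

test_that("a pure-noise multivariate signal passes the full test as null", {
  set.seed(46)
  sig <- signal_matrix(matrix(rnorm(2500 * 3), 2500, 3), sampling_rate = 100)
  res <- run_full_test(sig, width = 50, maxdim = 1, B = 99, seed = 5)
  expect_named(res$tests, c("0", "1"))
  for (t in res$tests) {
    expect_gte(t$p_value, 1 / 100)
    expect_lte(t$p_value, 1)
    # permuted reference distribution centered at the random-walk dimension
    expect_equal(mean(t$permuted_hfds), 1.5, tolerance = 0.15)
  }
  # same master seed reproduces the p-values exactly
  set.seed(46)
  sig2 <- signal_matrix(matrix(rnorm(2500 * 3), 2500, 3), sampling_rate = 100)
  res2 <- run_full_test(sig2, width = 50, maxdim = 1, B = 99, seed = 5)
  expect_identical(vapply(res$tests, `[[`, numeric(1), "p_value"),
                   vapply(res2$tests, `[[`, numeric(1), "p_value"))
})

test_that("the torus epoch of example2 dominates its neighbours in H1 and H2", {
  set.seed(47)
  sc <- build_scenario("example2")
  # three windows sampled from each epoch (the full run is ~100 windows)
  clouds <- make_point_clouds(sc$signal, width = 150)
  pick <- c(5, 15, 25, 38, 48, 58, 72, 82, 92)
  epoch <- rep(1:3, each = 3)
  tp1 <- tp2 <- numeric(length(pick))
  for (i in seq_along(pick)) {
    d <- rips_diagram(clouds[[pick[i]]]$points, maxdim = 2)
    tp1[i] <- total_persistence(d, 1)
    tp2[i] <- total_persistence(d, 2)
  }
  expect_gt(mean(tp1[epoch == 2]), mean(tp1[epoch == 3]))
  expect_gt(mean(tp2[epoch == 2]), mean(tp2[epoch == 1]))
  expect_gt(mean(tp2[epoch == 2]), mean(tp2[epoch == 3]))
})
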