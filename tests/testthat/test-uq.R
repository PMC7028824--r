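test_that("sample_parameters honours degenerate and truncated normals", {
  d0 <- parameter_dists(lambda = c(0.005, 0), alpha = c(0.1, 0),
                        beta = c(3, 0))
  x <- sample_parameters(d0, 5)
  expect_equal(x$lambda, rep(0.005, 5))
  expect_equal(x$alpha, rep(0.1, 5))
  expect_equal(x$beta, rep(3, 5))

  set.seed(408)
  # heavy truncation: all draws must still be admissible, with a warning
  dt <- parameter_dists(lambda = c(0.001, 0.001), alpha = c(0, 0.1),
                        beta = c(0, 0.1))
  x <- suppressWarnings(sample_parameters(dt, 500))
  expect_true(all(x$lambda > 0))
  expect_true(all(x$alpha >= 0))
  expect_true(all(x$beta >= 0))
  expect_warning(sample_parameters(
    parameter_dists(alpha = c(-0.005, 0.01)), 200), "positivity")

  # draw means match the study distributions over many draws
  set.seed(409)
  dd <- parameter_dists()
  y <- sample_parameters(dd, 1e5)
  expect_lt(abs(mean(y$lambda) - 0.005), 3 * 0.001 / sqrt(1e5) + 2e-5)
  expect_lt(abs(mean(y$alpha) - 0.1), 3 * 0.02 / sqrt(1e5))
  expect_lt(abs(mean(y$beta) - 3), 3 * 0.6 / sqrt(1e5))
  # spread column read as standard deviation by default
  expect_lt(abs(sd(y$beta) - 0.6), 0.01)
  # variance reading is available and distinct
  dv <- parameter_dists(beta = c(3, 0.36), spread = "variance")
  expect_equal(unname(dv$beta["sd"]), 0.6)
})

test_that("estimator identities: mean, MCE, ECDF", {
  expect_equal(mc_mean(2), 2)
  expect_equal(mc_mean(c(0, 2)), 1)
  expect_equal(mc_mean(1:4), 2.5)
  expect_error(mc_mean(numeric(0)), "at least one")

  expect_equal(mc_error(c(0, 2)), 1)
  expect_equal(mc_error(c(1, 2, 3)), sqrt(1 / 3))
  expect_equal(mc_error(rep(7, 10)), 0)
  expect_error(mc_error(5), "at least two")

  expect_equal(empirical_cdf(c(1, 2, 3), 2), 2 / 3)
  expect_equal(empirical_cdf(c(1, 2, 3), 0.5), 0)
  expect_equal(empirical_cdf(c(1, 2, 3), 3), 1)
})

test_that("empirical_cdf satisfies the ECDF axioms and matches stats::ecdf", {
  set.seed(410)
  x <- rexp(101, 0.3)
  grid <- seq(0, max(x) * 1.2, length.out = 97)
  Fx <- empirical_cdf(x, grid)
  expect_true(all(diff(Fx) >= 0))
  expect_equal(Fx[1], 0)
  expect_equal(Fx[length(Fx)], 1)
  expect_equal(Fx, unname(stats::ecdf(x)(grid)))
  # exactly 0.5 at the sample median for odd N
  expect_equal(empirical_cdf(x, stats::median(x)), 51 / 101)
})

test_that("MCE shrinks as N^{-1/2}", {
  set.seed(411)
  x <- rexp(4000, 1)
  m1 <- mc_error(x[1:1000])
  m2 <- mc_error(x)
  expect_lt(abs(m1 / m2 - 2), 0.3)
})

test_that("run_study is reproducible and records per-trial draws", {
  lat <- build_lattice(c(12, 12))
  dd <- parameter_dists()
  s1 <- run_study(lat, dd, N = 6, f = 0.5, seed = 99)
  s2 <- run_study(lat, dd, N = 6, f = 0.5, seed = 99)
  expect_identical(s1$trials, s2$trials)       # same streams, same T_f
  expect_true(all(s1$trials$status == "ok"))
  expect_equal(nrow(s1$trials), 6L)
  expect_equal(s1$summary$N_done, 6L)
  expect_equal(s1$summary$mean, mean(s1$trials$T_f))
  expect_equal(s1$summary$mce, mc_error(s1$trials$T_f))

  # N = 1: mean defined, MCE absent
  s3 <- run_study(lat, dd, N = 1, seed = 5)
  expect_equal(s3$summary$mean, s3$trials$T_f)
  expect_true(is.na(s3$summary$mce))
})

test_that("correlate returns Pearson r with the t-test p-value", {
  lat <- build_lattice(c(12, 12))
  st <- run_study(lat, parameter_dists(), N = 12, seed = 17)
  for (w in c("lambda", "alpha", "beta")) {
    ct <- correlate(st, w)
    ref <- cor.test(st$trials[[w]], st$trials$T_f)
    expect_equal(ct$r, unname(ref$estimate))
    expect_equal(ct$p, ref$p.value)
  }
  # perfectly correlated series -> r = 1
  fake <- structure(list(trials = data.frame(
    trial = 1:5, lambda = 1:5, alpha = rnorm(5), beta = rnorm(5),
    T_f = 1:5, status = "ok")), class = "mc_study")
  expect_equal(correlate(fake, "lambda")$r, 1)
})
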