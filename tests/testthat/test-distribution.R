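test_that("log normalizing constant matches limits and the summation oracle", {
  expect_equal(cmp_log_z(1, 1), 1)                       # Z = e^lambda
  expect_equal(cmp_log_z(1e-12, 2), 0, tolerance = 1e-9) # only j = 0 survives
  # high-precision direct summation at the underdispersed reference point
  expect_equal(cmp_log_z(0.33189, 1.55024),
               log(oracle_z(0.33189, 1.55024)), tolerance = 1e-12)
  expect_equal(exp(cmp_log_z(0.33189, 1.55024)), 1.372, tolerance = 1e-3)
  # vectorized with recycling
  expect_equal(cmp_log_z(c(1, 2), 1), c(1, 2))
})

test_that("series domain guards reject divergent and invalid parameters", {
  expect_error(cmp_log_z(1.2, 0), "diverges")
  expect_error(cmp_log_z(-1, 1), "positive")
  expect_error(cmp_log_z(1, -0.5), "nonnegative")
  expect_silent(cmp_log_z(0.5, 0))  # geometric-like case is admitted
  expect_equal(cmp_log_z(0.5, 0), log(1 / (1 - 0.5)), tolerance = 1e-10)
  expect_error(cmp_log_z(5, 0.01, cmp_control(max_terms = 100)),
               "tail bound")
  expect_error(cmp_control(rel_tol = 2), "rel_tol")
  expect_error(cmp_control(max_terms = 10), "max_terms")
})

test_that("CMP pmf reduces to Poisson at nu = 1 and matches the oracle", {
  y <- 0:20
  for (lam in c(0.3, 1, 2.5)) {
    expect_equal(dcmp(y, lam, 1, log = TRUE), dpois(y, lam, log = TRUE),
                 tolerance = 1e-10)
  }
  # y = 0 pmf is 1/Z for any parameters
  expect_equal(dcmp(0, 0.7, 2.2, log = TRUE), -cmp_log_z(0.7, 2.2))
  expect_equal(dcmp(1, 0.33189, 1.55024),
               0.33189 / oracle_z(0.33189, 1.55024), tolerance = 1e-10)
})

test_that("pmf normalizes to one over a (lambda, nu) grid", {
  grid <- expand.grid(lambda = c(0.05, 0.3, 1, 2.5, 5),
                      nu = c(0.3, 0.5, 0.8, 1, 1.3, 1.55, 2, 2.5, 3, 0.4))
  for (i in seq_len(nrow(grid))) {
    # support long enough for the heaviest case (lambda 5, nu 0.3:
    # mean ~ 213, sd ~ 27)
    tot <- sum(dcmp(0:800, grid$lambda[i], grid$nu[i]))
    expect_equal(tot, 1, tolerance = 1e-8)
  }
})

test_that("zero-inflated pmf mixes a point mass at zero with the CMP pmf", {
  expect_equal(dzicmp(0, 2, 1, pi = 1), 1)
  expect_equal(dzicmp(3, 2, 1, pi = 1), 0)
  z <- oracle_z(0.33189, 1.55024)
  expect_equal(dzicmp(0, 0.33189, 1.55024, pi = 0.5), 0.5 + 0.5 / z,
               tolerance = 1e-10)
  expect_equal(dzicmp(0:50, 0.9, 0.7, pi = 0.25),
               0.25 * (0:50 == 0) + 0.75 * dcmp(0:50, 0.9, 0.7))
  expect_equal(sum(dzicmp(0:100, 1.4, 1.8, pi = 0.3)), 1, tolerance = 1e-8)
  expect_error(dzicmp(0, 1, 1, pi = 1.2), "0, 1")
})

test_that("exact moments match Poisson and the series oracle; approximation is as stated", {
  m <- cmp_moments(2, 1)
  expect_equal(m$mean, 2, tolerance = 1e-8)
  expect_equal(m$variance, 2, tolerance = 1e-8)
  for (lam in c(0.2, 1, 4)) {
    expect_equal(cmp_moments(lam, 1)$mean, lam, tolerance = 1e-8)
  }
  ex <- cmp_moments(0.33189, 1.55024)
  expect_equal(ex$mean, oracle_mean(0.33189, 1.55024), tolerance = 1e-8)
  expect_equal(ex$variance, oracle_var(0.33189, 1.55024), tolerance = 1e-8)
  expect_equal(ex$mean, 0.302, tolerance = 1e-3)
  ap <- cmp_moments(0.33189, 1.55024, method = "approx")
  expect_equal(ap$mean, 0.33189^(1 / 1.55024) - 0.55024 / (2 * 1.55024))
  expect_equal(ap$mean, 0.313, tolerance = 2e-3)   # differs from exact 0.302
  expect_error(cmp_moments(0.5, 0, method = "approx"), "nu = 0")
})

test_that("variance-to-mean ratio decreases in nu (about 1/nu)", {
  nus <- c(0.5, 1, 1.5, 2)
  for (lam in c(0.5, 1, 2)) {
    m <- cmp_moments(lam, nus)
    ratio <- m$variance / m$mean
    expect_true(all(diff(ratio) < 0))
    expect_gt(ratio[1], 1)   # overdispersed below nu = 1
    expect_lt(ratio[3], 1)   # underdispersed above nu = 1
  }
})

test_that("samplers are seed-reproducible and match their distributions", {
  expect_identical(rcmp(3, 0.5, 1.5, seed = 42), rcmp(3, 0.5, 1.5, seed = 42))
  expect_identical(rzicmp(5, 1, 2, 0.4, seed = 7), rzicmp(5, 1, 2, 0.4, seed = 7))
  expect_true(all(rzicmp(50, 2, 1, pi = 1, seed = 1) == 0))

  n <- 1e5
  y <- rcmp(n, 1, 1, seed = 11)                 # Poisson limit
  expect_lt(abs(mean(y) - 1), 4 * sqrt(1 / n))

  y <- rcmp(n, 0.33189, 1.55024, seed = 12)     # underdispersion
  expect_lt(var(y) / mean(y), 1)

  y <- rzicmp(n, 2, 1, pi = 0.3, seed = 13)     # closed-form zero mass
  expect_lt(abs(mean(y == 0) - (0.3 + 0.7 * exp(-2))),
            4 * sqrt(0.25 / n))
})

test_that("empirical pmf of ZICMP draws matches the pmf within Monte Carlo error", {
  n <- 1e5
  lam <- 1.2; nu <- 1.6; pi <- 0.25
  y <- rzicmp(n, lam, nu, pi, seed = 99)
  p <- dzicmp(0:10, lam, nu, pi)
  for (v in 0:10) {
    if (n * p[v + 1] >= 5) {
      se <- sqrt(p[v + 1] * (1 - p[v + 1]) / n)
      expect_lt(abs(mean(y == v) - p[v + 1]), 4 * se)
    }
  }
})
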