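test_that("the nested LRT is twice the log-likelihood gap, floored at zero", {
  ft <- thai_fatalities_2015()
  pois <- fit_poisson(ft)
  cmp <- fit_cmp(ft)
  out <- lrt_nested(pois, cmp)
  expect_equal(out$statistic, 2 * (cmp$loglik - pois$loglik))
  expect_equal(out$df, 1L)
  expect_equal(out$p.value,
               pchisq(out$statistic, 1, lower.tail = FALSE))

  same <- lrt_nested(pois, fit_zip(ft))   # identical logliks here
  expect_equal(same$statistic, 0, tolerance = 1e-4)
  expect_gt(same$p.value, 0.99)

  expect_error(lrt_nested(cmp, fit_zip(ft)), "not nested")
  expect_error(lrt_nested(cmp, pois), "not nested")
})

test_that("score test matches direct arithmetic and is expansion invariant", {
  ft <- thai_fatalities_2015()
  out <- zero_inflation_score_test(ft)
  n <- 20229; n0 <- 14641; ybar <- 6109 / n; p0 <- exp(-ybar)
  expect_equal(out$statistic,
               (n0 - n * p0)^2 / (n * p0 * (1 - p0) - n * ybar * p0^2))
  expect_equal(out$df, 1L)
  expect_identical(out$statistic,
                   zero_inflation_score_test(freq_to_records(ft))$statistic)

  # a table engineered so n0 equals the Poisson zero expectation exactly
  n <- 100; a <- 80; ybar <- log(n / a)
  cfg <- freq_table(0:2, c(a, 20 - (ybar * n - 20), ybar * n - 20))
  z <- zero_inflation_score_test(cfg)
  expect_equal(z$statistic, 0, tolerance = 1e-12)
})

test_that("score test degenerate denominator raises a described error", {
  expect_error(zero_inflation_score_test(freq_table(0, 5)), "positive sample mean")
})

test_that("Pearson statistic matches direct summation; degenerate fit gives zero", {
  ft <- thai_fatalities_2015()
  fit <- fit_poisson(ft)
  s <- freq_summary(ft <- thai_fatalities_2015())
  direct <- sum(ft$accidents * (ft$deaths - s$mean)^2 / s$mean)
  expect_equal(pearson_gof(fit), direct, tolerance = 1e-6)
  # equals (n-1) * variance / mean under the weighted convention
  expect_equal(direct, (s$n - 1) * s$variance / s$mean, tolerance = 1e-8)

  flat <- fit_poisson(tibble::tibble(deaths = rep(1L, 4)))
  expect_equal(pearson_gof(flat), 0, tolerance = 1e-10)
})

test_that("squared-deviation variant reproduces the approximate-mean sum", {
  ft <- thai_fatalities_2015()
  cmp <- fit_cmp(ft)
  lam <- exp(unname(cmp$parts$beta)); nu <- exp(unname(cmp$parts$delta))
  appm <- lam^(1 / nu) - (nu - 1) / (2 * nu)
  expect_equal(appm, 0.31343, tolerance = 1e-4)
  direct <- sum(ft$accidents * (ft$deaths - appm)^2)
  expect_equal(pearson_gof(cmp, variant = "squared_deviation"), direct,
               tolerance = 1e-6)
  expect_equal(direct, 5812.78, tolerance = 1e-5 * 5812.78)
})

test_that("Cramer's V is 1 for perfect association and near 0 under independence", {
  a <- rep(c("x", "y"), each = 10)
  expect_equal(cramers_v(a, a), 1)
  set.seed(8)
  n <- 1e5
  u <- sample(letters[1:3], n, replace = TRUE)
  v <- sample(letters[1:4], n, replace = TRUE)
  expect_lt(cramers_v(u, v), 0.02)
  expect_error(cramers_v(rep("x", 10), rep(c("u", "v"), 5)), "two observed levels")
  expect_error(cramers_v(a, a[1:5]), "equal length")
})

test_that("zero-inflation LRT is conservative under the no-inflation null", {
  reps <- 200
  set.seed(202)
  seeds <- sample.int(1e6, reps)
  rej <- vapply(seeds, function(s) {
    y <- rcmp(2000, exp(-1.1), 1.55, seed = s)
    ftab <- as_freq_table(y)
    out <- lrt_nested(fit_cmp(ftab), fit_zicmp(ftab), df = 1L)
    out$p.value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.10)
})

test_that("model comparison collects rows and the applicable tests", {
  ft <- thai_fatalities_2015()
  fits <- lapply(c("poisson", "cmp", "zip", "zicmp"), function(m) {
    fit_fatality_model(ft, model = m)
  })
  rep <- model_comparison(fits)
  expect_equal(rep$models$model, c("poisson", "cmp", "zip", "zicmp"))
  expect_equal(rep$models$n_params, c(1L, 2L, 2L, 3L))
  expect_equal(nrow(rep$tests), 5L)  # four LRTs plus the score test
  expect_true(any(grepl("score", rep$tests$method)))
  expect_true(all(is.na(rep$models$sq_dev_approx[c(1, 3)])))
  expect_false(any(is.na(rep$models$sq_dev_approx[c(2, 4)])))
  txt <- paste(capture.output(print(rep)), collapse = "\n")
  expect_match(txt, "Log-Likelihood")

  solo <- model_comparison(fits[[1]])
  expect_equal(nrow(solo$models), 1L)
  expect_false(any(grepl("LRT", solo$tests$method)))

  # purity: two independent datasets give independently computed rows
  r1 <- model_comparison(fit_poisson(toy_freq()))
  r2 <- model_comparison(fit_poisson(ft))
  expect_false(isTRUE(all.equal(r1$models$logLik, r2$models$logLik)))
  expect_equal(r1$models$logLik, glance(fit_poisson(toy_freq()))$logLik)
})
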