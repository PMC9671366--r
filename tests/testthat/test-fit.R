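test_that("intercept-only Poisson MLE is the log weighted mean, exactly", {
  ft <- toy_freq()
  fit <- fit_poisson(ft)
  ybar <- sum(ft$deaths * ft$accidents) / sum(ft$accidents)
  expect_equal(unname(fit$parts$beta), log(ybar), tolerance = 1e-12)
  expect_equal(fit$loglik, oracle_pois_ll(ft, ybar), tolerance = 1e-10)
  expect_equal(fit$aic, -2 * fit$loglik + 2)

  flat <- fit_poisson(tibble::tibble(deaths = rep(1L, 4)))
  expect_equal(unname(flat$parts$beta), 0, tolerance = 1e-10)
})

test_that("Poisson regression recovers a simulated rate", {
  set.seed(31)
  n <- 1e4
  dat <- tibble::tibble(deaths = rpois(n, 2))
  fit <- fit_poisson(dat)
  expect_lt(abs(unname(fit$parts$beta) - log(2)), 4 * sqrt(1 / (2 * n)))
  expect_true(fit$converged)
})

test_that("frequency-table and record-level fits are identical", {
  ft <- thai_fatalities_2015()
  rec <- freq_to_records(ft)
  expect_equal(nrow(rec), 20229L)
  for (m in c("poisson", "cmp", "zicmp")) {
    f1 <- fit_fatality_model(ft, model = m)
    f2 <- fit_fatality_model(rec, model = m)
    expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
    # boundary coefficients are not identified (any sufficiently negative
    # logit gives the same likelihood), so compare the interior ones;
    # with a boundary present the likelihood ridge limits coefficient
    # precision to ~1e-5 even though the loglik agrees to 1e-8
    keep <- !f1$boundary
    expect_equal(f1$coefficients[keep], f2$coefficients[keep],
                 tolerance = if (any(f1$boundary)) 1e-5 else 1e-6)
  }
})

test_that("maximized log-likelihoods respect the nesting chain", {
  for (dat in list(thai_fatalities_2015(), toy_freq())) {
    ll <- vapply(c("poisson", "cmp", "zip", "zicmp"), function(m) {
      fit_fatality_model(dat, model = m)$loglik
    }, numeric(1))
    expect_gte(ll["cmp"], ll["poisson"] - 1e-6)
    expect_gte(ll["zip"], ll["poisson"] - 1e-6)
    expect_gte(ll["zicmp"], ll["cmp"] - 1e-6)
    expect_gte(ll["zicmp"], ll["zip"] - 1e-6)
  }
})

test_that("CMP dispersion estimate is near zero on equidispersed data", {
  set.seed(5)
  dat <- tibble::tibble(deaths = rpois(5000, 1.5))
  fit <- fit_cmp(dat)
  d <- unname(fit$parts$delta)
  expect_lt(abs(d), 3 * unname(fit$se["delta_(Intercept)"]))
})

test_that("the CMP optimum is invariant to perturbed starting values", {
  ft <- thai_fatalities_2015()
  base <- fit_cmp(ft)
  for (shift in c(-0.5, 0.5)) {
    alt <- fit_cmp(ft, start = c(unname(base$parts$beta),
                                 unname(base$parts$delta) + shift))
    expect_equal(alt$coefficients, base$coefficients, tolerance = 1e-6)
    expect_equal(alt$loglik, base$loglik, tolerance = 1e-8)
  }
})

test_that("ZIP recovers a simulated zero-inflation fraction", {
  set.seed(17)
  n <- 1e4
  y <- ifelse(rbinom(n, 1, 0.3) == 1, 0L, rpois(n, 2))
  fit <- fit_zip(tibble::tibble(deaths = y))
  g <- unname(fit$parts$gamma)
  se <- unname(fit$se["gamma_(Intercept)"])
  expect_lt(abs(g - log(0.3 / 0.7)), 3 * se)
  expect_false(any(fit$boundary))
  # fitted marginal mean matches the sample mean (MLE moment condition)
  expect_equal(mean(predict(fit)), mean(y), tolerance = 1e-3)
})

test_that("ZIP collapses to Poisson when the data carry no excess zeros", {
  set.seed(21)   # a draw whose zero share sits below the Poisson bound
  dat <- tibble::tibble(deaths = rpois(4000, 1))
  p <- fit_poisson(dat)
  z <- fit_zip(dat)
  expect_lt(abs(z$loglik - p$loglik), 1e-4)
  expect_true(any(z$boundary))       # pi driven to the boundary
})

test_that("ZICMP reduces to CMP on CMP data and recovers its own truths", {
  # a CMP draw whose zero share sits below the fitted CMP zero
  # probability, so the zero part must collapse to the boundary
  set.seed(42)
  dat <- tibble::tibble(deaths = rcmp(5000, exp(-1.1), exp(0.44)))
  cmp <- fit_cmp(dat)
  zic <- fit_zicmp(dat)
  expect_true(any(zic$boundary))
  expect_lt(abs(zic$loglik - cmp$loglik), 1e-4)

  truth <- c(-0.44, 0.87, -0.97)
  dat <- simulate_accidents(2e4, beta = truth[1], delta = truth[2],
                            gamma = truth[3], seed = 43)
  fit <- fit_zicmp(dat)
  for (i in 1:3) {
    expect_lt(abs(unname(fit$coefficients[i]) - truth[i]),
              3 * unname(fit$se[i]))
  }
  expect_false(any(fit$boundary))
})

test_that("predicted means follow each model's expectation formula", {
  ft <- thai_fatalities_2015()
  s <- sum(ft$deaths * ft$accidents) / sum(ft$accidents)

  pois <- fit_poisson(ft)
  expect_equal(predict(pois), rep(s, 7), tolerance = 1e-8)
  expect_equal(unname(predict(pois)[1]), 0.302, tolerance = 1e-3)

  zic <- fit_zicmp(ft)
  expect_equal(mean(predict(zic)), s, tolerance = 1e-3)
  expect_equal(predict(zic),
               (1 - predict(zic, type = "pi")) *
                 cmp_moments(predict(zic, type = "lambda"),
                             predict(zic, type = "nu"))$mean)

  # structural-zero rows have expectation zero
  lamv <- c(2, 2); nuv <- c(1, 1); piv <- c(1, 0)
  expect_equal((1 - piv) * cmp_moments(lamv, nuv)$mean, c(0, 2),
               tolerance = 1e-8)
})

test_that("tidy and glance expose the fit in broom conventions", {
  fit <- fit_cmp(toy_freq())
  td <- tidy(fit)
  expect_equal(td$part, c("count", "dispersion"))
  expect_true(all(c("estimate", "std.error", "statistic", "p.value",
                    "boundary") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$model, "cmp")
  expect_equal(gl$AIC, -2 * gl$logLik + 2 * gl$n_params)
  expect_equal(gl$nobs, 100)
  expect_s3_class(autoplot(fit), "ggplot")
})
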