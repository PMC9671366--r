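#' Marginal level frequencies of the accident covariates
#'
#' The default marginals reproduce the observed 2015 Thailand accident
#' proportions of the six covariates (e.g. National highway 0.4319, Dry
#' 0.9270, Clear 0.9292, April 0.1829), stored as the observed counts out
#' of the 20,229 complete records.
#'
#' @return A tibble with columns `variable`, `level`, `prob`, level order
#'   matching [accident_coding()].
#' @examples
#' thai_marginals()
#' @export
thai_marginals <- function() {
  counts <- list(
    roadway_class = c(8737, 2738, 2977, 5777),
    road_surface = c(18752, 1477),
    road_section = c(13750, 2478, 4001),
    weather = c(18797, 792, 640),
    light = c(12360, 4615, 3254),
    month = c(2668, 1412, 1575, 3700, 1443, 1242, 1348, 1305, 1127, 1170,
              1206, 2033)
  )
  coding <- accident_coding()
  dplyr::bind_rows(purrr::imap(counts, function(k, v) {
    tibble::tibble(variable = v, level = coding[[v]], prob = k / sum(k))
  }))
}

check_marginals <- function(marginals) {
  if (!is.data.frame(marginals) ||
      !all(c("variable", "level", "prob") %in% names(marginals))) {
    abort("`marginals` needs columns `variable`, `level`, `prob`.")
  }
  for (v in unique(marginals$variable)) {
    p <- marginals$prob[marginals$variable == v]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(paste0("Probabilities for `", v,
                   "` must be nonnegative and sum to 1."))
    }
  }
  invisible(TRUE)
}

#' Simulate categorical accident covariates
#'
#' Draws each covariate independently from its marginal distribution.
#' Independence across variables is a deliberate simplification: the real
#' covariates show only weak pairwise association (Cramer's V at most
#' about 0.6), and joint dependence is not modelled.
#'
#' @param n Number of accident records.
#' @param marginals See [thai_marginals()].
#' @param seed Optional integer seed.
#' @return A tibble with `n` rows, one factor column per variable.
#' @examples
#' simulate_covariates(5, seed = 1)
#' @export
simulate_covariates <- function(n, marginals = thai_marginals(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_marginals(marginals)
  vars <- unique(marginals$variable)
  cols <- lapply(vars, function(v) {
    m <- marginals[marginals$variable == v, ]
    factor(sample(m$level, n, replace = TRUE, prob = m$prob),
           levels = m$level)
  })
  tibble::as_tibble(setNames(cols, vars))
}

#' Simulate death counts from a ZICMP regression
#'
#' Given covariate records and true coefficients, computes the row-wise
#' parameters \eqn{\lambda_i = \exp(X_i'\beta)},
#' \eqn{\nu_i = \exp(S_i'\delta)},
#' \eqn{\mathrm{logit}(\pi_i) = W_i'\gamma} and draws one ZICMP outcome
#' per row.  Omitting `gamma` forces \eqn{\pi = 0} (no structural zeros);
#' `delta = 0` with no `gamma` gives Poisson outcomes.
#'
#' @param data Records tibble conforming to `coding`.
#' @param beta Count-part coefficients, length matching the `count`
#'   design.
#' @param delta Dispersion-part coefficients (default 0, intercept-only).
#' @param gamma Zero-part coefficients, or `NULL` for no zero inflation.
#' @param count,dispersion,zero Formulas defining the three designs.
#' @param coding See [accident_coding()].
#' @param seed Optional integer seed.
#' @param control See [cmp_control()].
#' @return Integer vector of simulated deaths, one per row of `data`.
#' @examples
#' cov <- simulate_covariates(100, seed = 1)
#' simulate_fatalities(cov, beta = -1.1, delta = 0.44, seed = 2)[1:10]
#' @export
simulate_fatalities <- function(data, beta, delta = 0, gamma = NULL,
                                count = ~1, dispersion = ~1, zero = ~1,
                                coding = accident_coding(), seed = NULL,
                                control = cmp_control()) {
  if (!is.null(seed)) set.seed(seed)
  data$deaths <- 0L
  ds <- build_design(data, count = count, dispersion = dispersion,
                     zero = zero, coding = coding)
  dim_chk <- function(v, M, nm) {
    if (length(v) != ncol(M)) {
      abort(paste0("`", nm, "` must have length ", ncol(M),
                   " to match its design matrix."))
    }
  }
  dim_chk(beta, ds$X, "beta")
  dim_chk(delta, ds$S, "delta")
  lam <- exp(drop(ds$X %*% beta))
  nu <- exp(drop(ds$S %*% delta))
  if (is.null(gamma)) {
    pi <- rep(0, nrow(data))
  } else {
    dim_chk(gamma, ds$W, "gamma")
    pi <- 1 / (1 + exp(-drop(ds$W %*% gamma)))
  }
  rzicmp(nrow(data), lam, nu, pi, control = control)
}

#' Convenience wrapper: covariates plus ZICMP deaths in one call
#'
#' @inheritParams simulate_fatalities
#' @param n Number of records.
#' @param marginals See [thai_marginals()].
#' @return A records tibble with the covariates and a `deaths` column;
#'   the seed used is attached as attribute `"seed"`.
#' @examples
#' simulate_accidents(20, beta = -1.1, seed = 7)
#' @export
simulate_accidents <- function(n, beta, delta = 0, gamma = NULL,
                               count = ~1, dispersion = ~1, zero = ~1,
                               marginals = thai_marginals(),
                               coding = accident_coding(), seed = NULL,
                               control = cmp_control()) {
  if (!is.null(seed)) set.seed(seed)
  out <- simulate_covariates(n, marginals)
  out$deaths <- simulate_fatalities(out, beta = beta, delta = delta,
                                    gamma = gamma, count = count,
                                    dispersion = dispersion, zero = zero,
                                    coding = coding, control = control)
  attr(out, "seed") <- seed
  out
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates accident data at known coefficients, refits the
#' matching model, and summarizes bias and Wald confidence-interval
#' coverage per coefficient.  One master seed deterministically derives a
#' child seed per replicate, so the whole experiment is reproducible.
#' Replicates whose fit fails are counted and skipped, not fatal.
#'
#' @param model Model kind to fit (and simulate from).
#' @param beta,delta,gamma True coefficients (see
#'   [simulate_fatalities()]).
#' @param n Records per replicate.
#' @param reps Number of replicates (>= 2).
#' @param count,dispersion,zero Part formulas.
#' @param marginals,coding As in [simulate_accidents()].
#' @param seed Master seed.
#' @param conf_level Wald interval level (default 0.95).
#' @details Replicates whose maximum lands on the boundary of the
#'   parameter space (structural-zero probability collapsing to 0 or 1)
#'   have no valid Wald interval for the affected coefficients; their
#'   standard errors are `NA` and they are excluded from the coverage
#'   denominator.  The count of such replicates is returned in the
#'   `n_boundary` attribute and should be reported alongside coverage:
#'   a large value signals that the truths are too close to the boundary
#'   for Wald calibration to be meaningful at this sample size.
#' @return A tibble with one row per coefficient: `term`, `truth`,
#'   `mean_estimate`, `bias`, `empirical_se`, `mean_se`, `coverage`,
#'   `n_used` (replicates with a valid interval); attributes `reps`,
#'   `n`, `seed`, `n_failed`, `n_boundary`.
#' @examples
#' recovery_experiment("poisson", beta = -1.1, n = 500, reps = 3, seed = 1)
#' @export
recovery_experiment <- function(model = c("poisson", "cmp", "zip", "zicmp"),
                                beta, delta = 0, gamma = NULL,
                                n = 5000, reps = 50,
                                count = ~1, dispersion = ~1, zero = ~1,
                                marginals = thai_marginals(),
                                coding = accident_coding(), seed = 1L,
                                conf_level = 0.95) {
  model <- match.arg(model)
  if (reps < 2) abort("`reps` must be at least 2.")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, reps)
  truth <- switch(model,
    poisson = c(beta),
    cmp = c(beta, delta),
    zip = c(beta, gamma),
    zicmp = c(beta, delta, gamma)
  )
  sim_gamma <- if (model %in% c("zip", "zicmp")) gamma else NULL
  sim_delta <- if (model %in% c("cmp", "zicmp")) delta else 0

  one <- function(s) {
    dat <- simulate_accidents(n, beta = beta, delta = sim_delta,
                              gamma = sim_gamma, count = count,
                              dispersion = dispersion, zero = zero,
                              marginals = marginals, coding = coding,
                              seed = s)
    fit <- fit_fatality_model(dat, model = model, count = count,
                              dispersion = dispersion, zero = zero,
                              coding = coding)
    list(est = unname(fit$coefficients), se = unname(fit$se),
         boundary = any(fit$boundary))
  }
  results <- lapply(child, function(s) tryCatch(one(s), error = function(e) NULL))
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) abort("Every replicate failed to fit.")
  est <- do.call(rbind, lapply(results[ok], `[[`, "est"))
  se <- do.call(rbind, lapply(results[ok], `[[`, "se"))
  z <- qnorm(1 - (1 - conf_level) / 2)
  covered <- sweep(est - z * se, 2, truth, `<=`) &
    sweep(est + z * se, 2, truth, `>=`)     # NA where no valid interval

  terms <- flat_names(fit_template_parts(model, beta, delta, gamma))
  out <- tibble::tibble(
    term = terms,
    truth = truth,
    mean_estimate = colMeans(est),
    bias = colMeans(est) - truth,
    empirical_se = apply(est, 2, sd),
    mean_se = colMeans(se, na.rm = TRUE),
    coverage = colMeans(covered, na.rm = TRUE),
    n_used = colSums(!is.na(covered))
  )
  attr(out, "reps") <- reps
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  attr(out, "n_failed") <- sum(!ok)
  attr(out, "n_boundary") <- sum(vapply(results[ok], `[[`, logical(1),
                                        "boundary"))
  out
}

fit_template_parts <- function(model, beta, delta, gamma) {
  nm <- function(v, p) setNames(v, if (length(v)) paste0(p, seq_along(v)))
  switch(model,
    poisson = list(beta = nm(beta, "b")),
    cmp = list(beta = nm(beta, "b"), delta = nm(delta, "d")),
    zip = list(beta = nm(beta, "b"), gamma = nm(gamma, "g")),
    zicmp = list(beta = nm(beta, "b"), delta = nm(delta, "d"),
                 gamma = nm(gamma, "g"))
  )
}
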