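nesting_pairs <- list(
  poisson = c("cmp", "zip", "zicmp"),
  cmp = "zicmp",
  zip = "zicmp"
)

test_result <- function(method, statistic, df) {
  statistic <- max(statistic, 0)          # floor numerical noise
  tibble::tibble(method = method, statistic = statistic, df = df,
                 p.value = pchisq(statistic, df, lower.tail = FALSE))
}

#' Likelihood-ratio test between nested count models
#'
#' \eqn{-2\log\Lambda = 2\,(\ell_{full} - \ell_{restricted})}, referred to
#' a chi-squared distribution.  Valid pairs are Poisson within CMP, ZIP or
#' ZICMP; CMP within ZICMP (zero-inflation test); and ZIP within ZICMP
#' (dispersion test in the zero-inflated family).  The statistic is
#' floored at zero.  The chi-squared reference with the stated degrees of
#' freedom is used as-is; for tests of a boundary parameter
#' (\eqn{\pi = 0}) this is conservative.
#'
#' @param restricted,full Fitted models from [fit_fatality_model()], the
#'   first nested in the second.
#' @param df Degrees of freedom; defaults to the difference in parameter
#'   counts.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p.value`.
#' @examples
#' ft <- thai_fatalities_2015()
#' lrt_nested(fit_poisson(ft), fit_cmp(ft))
#' @export
lrt_nested <- function(restricted, full, df = NULL) {
  rk <- restricted$kind
  fk <- full$kind
  if (!fk %in% nesting_pairs[[rk]]) {
    abort(paste0("`", rk, "` is not nested in `", fk, "`."))
  }
  if (is.null(df)) df <- full$n_params - restricted$n_params
  test_result(paste0("LRT: ", rk, " vs ", fk),
              2 * (full$loglik - restricted$loglik), df)
}

#' Score test for zero inflation in a Poisson distribution
#'
#' Tests whether the observed number of zeros exceeds what the Poisson
#' distribution fitted by its mean allows, using only the null fit:
#' \deqn{S = (n_0 - n p_0)^2 / (n p_0 (1 - p_0) - n \bar y p_0^2)}
#' with \eqn{p_0 = e^{-\bar y}}.  Under \eqn{H_0: \pi = 0}, \eqn{S} is
#' asymptotically chi-squared with one degree of freedom.  Invariant to
#' whether the data arrive as records or as a frequency table.
#'
#' @param data A [freq_table()], records tibble with a `deaths` column, or
#'   integer outcome vector.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p.value`.
#' @examples
#' zero_inflation_score_test(thai_fatalities_2015())
#' @export
zero_inflation_score_test <- function(data) {
  s <- freq_summary(as_freq_table(data))
  if (s$mean <= 0) abort("The score test requires a positive sample mean.")
  p0 <- exp(-s$mean)
  denom <- s$n * p0 * (1 - p0) - s$n * s$mean * p0^2
  if (denom <= 0) {
    abort("Degenerate score-test denominator: the Poisson zero probability leaves no free variation in the zero count.")
  }
  test_result("score test for zero inflation",
              (s$n0 - s$n * p0)^2 / denom, 1L)
}

#' Generalized Pearson goodness-of-fit statistic
#'
#' The default `"pearson"` variant is
#' \eqn{\sum_i w_i (y_i - E(Y_i))^2 / E(Y_i)} with \eqn{E(Y_i)} the
#' model's expected outcome (exact series mean for CMP-family models).
#' The `"squared_deviation"` variant is the frequency-weighted sum of
#' squared deviations about the *asymptotic-approximation* CMP mean,
#' without scaling by the mean; it exists solely to reproduce a reporting
#' convention for CMP-family fits in which deviations are left unscaled,
#' and is labelled accordingly in [model_comparison()] output.
#'
#' @param fit A `fatality_fit`.
#' @param newdata Optional records/design to evaluate on (default: the
#'   training design).
#' @param variant `"pearson"` (default) or `"squared_deviation"`.
#' @return A single number.
#' @examples
#' pearson_gof(fit_poisson(thai_fatalities_2015()))
#' @export
pearson_gof <- function(fit, newdata = NULL,
                        variant = c("pearson", "squared_deviation")) {
  variant <- match.arg(variant)
  ds <- if (is.null(newdata)) fit$design else
    resolve_design(newdata, fit$design$formulas$count,
                   fit$design$formulas$dispersion, fit$design$formulas$zero,
                   NULL, fit$design$coding, "deaths")
  if (variant == "squared_deviation") {
    mu <- fitted_mean(fit, ds, approx = fit$kind %in% c("cmp", "zicmp"))
    return(sum(ds$w * (ds$y - mu)^2))
  }
  mu <- fitted_mean(fit, ds)
  if (any(mu <= 0)) abort("Nonpositive fitted mean in the Pearson statistic.")
  sum(ds$w * (ds$y - mu)^2 / mu)
}

#' Cramer's V association between two categorical variables
#'
#' \eqn{V = \sqrt{\chi^2 / (n (\min(r, c) - 1))}} from the contingency
#' chi-squared statistic (without continuity correction); a value in
#' \[0, 1\] used to screen covariate pairs for multicollinearity.
#'
#' @param a,b Equal-length categorical vectors, each with at least two
#'   observed levels.
#' @return A single number in \[0, 1\].
#' @examples
#' cramers_v(c("x", "x", "y", "y"), c("u", "u", "v", "v"))  # 1
#' @export
cramers_v <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  tab <- table(a, b)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("Both variables need at least two observed levels.")
  }
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
  sqrt(unname(chi) / (sum(tab) * (min(dim(tab)) - 1L)))
}

#' Model-comparison report across fitted count models
#'
#' Stacks one [glance.fatality_fit()] row per fit and, where the relevant
#' pairs are present, appends the dispersion likelihood-ratio test
#' (Poisson vs CMP and/or ZIP vs ZICMP), the zero-inflation
#' likelihood-ratio test (CMP vs ZICMP, Poisson vs ZIP) and the score
#' test for zero inflation computed from the data of the first fit.
#' Boundary flags on zero-part coefficients propagate into the `boundary`
#' column.
#'
#' @param ... `fatality_fit` objects (or a single list of them).
#' @param score_data Optional data for the score test; defaults to the
#'   outcome of the first fit.
#' @return A list of class `"model_comparison"` with tibbles `models`,
#'   `coefficients` and `tests`.
#' @examples
#' ft <- thai_fatalities_2015()
#' model_comparison(fit_poisson(ft), fit_cmp(ft))
#' @export
model_comparison <- function(..., score_data = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "fatality_fit")) {
    fits <- fits[[1]]
  }
  if (!length(fits)) abort("At least one fitted model is required.")
  kinds <- vapply(fits, function(f) f$kind, character(1))
  if (anyDuplicated(kinds)) abort("Duplicate model kinds supplied.")
  names(fits) <- kinds

  models <- dplyr::bind_rows(lapply(fits, glance))
  models$boundary <- vapply(fits, function(f) any(f$boundary), logical(1))
  # reproduction-only variant: unscaled squared deviations about the
  # asymptotic-approximation CMP mean (see ?pearson_gof)
  models$sq_dev_approx <- vapply(fits, function(f) {
    if (f$kind %in% c("cmp", "zicmp")) {
      pearson_gof(f, variant = "squared_deviation")
    } else {
      NA_real_
    }
  }, numeric(1))
  coefs <- dplyr::bind_rows(lapply(fits, function(f) {
    dplyr::mutate(tidy(f), model = f$kind, .before = 1)
  }))

  tests <- list()
  pair <- function(r, f) r %in% kinds && f %in% kinds
  if (pair("poisson", "cmp")) {
    tests <- c(tests, list(lrt_nested(fits$poisson, fits$cmp, df = 1L)))
  }
  if (pair("zip", "zicmp")) {
    tests <- c(tests, list(lrt_nested(fits$zip, fits$zicmp, df = 1L)))
  }
  if (pair("poisson", "zip")) {
    tests <- c(tests, list(lrt_nested(fits$poisson, fits$zip, df = 1L)))
  }
  if (pair("cmp", "zicmp")) {
    tests <- c(tests, list(lrt_nested(fits$cmp, fits$zicmp, df = 1L)))
  }
  if (is.null(score_data)) {
    ds <- fits[[1]]$design
    score_data <- freq_table_from_weighted(ds$y, ds$w)
  }
  tests <- c(tests, list(zero_inflation_score_test(score_data)))

  structure(list(models = models, coefficients = coefs,
                 tests = dplyr::bind_rows(tests)),
            class = "model_comparison")
}

freq_table_from_weighted <- function(y, w) {
  agg <- tapply(w, y, sum)
  freq_table(as.integer(names(agg)), as.numeric(agg))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}

# plain-text rendering of the comparison block (fits as columns)
format_comparison <- function(x) {
  m <- x$models
  num <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  rows <- rbind(
    `Log-Likelihood` = num(m$logLik),
    AIC = num(m$AIC),
    `Pearson chi-squared` = num(m$pearson),
    `Sq.dev (approx mean)` = ifelse(is.na(m$sq_dev_approx), "-",
                                    num(m$sq_dev_approx)),
    `#Parameters` = as.character(m$n_params),
    Boundary = ifelse(m$boundary, "yes", "no")
  )
  colnames(rows) <- toupper(m$model)
  widths <- pmax(nchar(colnames(rows)), apply(nchar(rows), 2, max))
  lab_w <- max(nchar(rownames(rows)))
  pad <- function(s, w) formatC(s, width = w)
  header <- paste(c(pad("", lab_w),
                    mapply(pad, colnames(rows), widths)), collapse = "  ")
  body <- apply(cbind(rownames(rows), rows), 1, function(r) {
    paste(c(pad(r[1], lab_w), mapply(pad, r[-1], widths)), collapse = "  ")
  })
  tests <- sprintf("%s: statistic = %.2f, df = %d, p %s",
                   x$tests$method, x$tests$statistic, x$tests$df,
                   ifelse(x$tests$p.value < 1e-4, "< 0.0001",
                          sprintf("= %.4f", x$tests$p.value)))
  c(header, unname(body), "", tests)
}
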