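#' @export
print.fatality_fit <- function(x, digits = 4, ...) {
  cat("<fatality_fit> ", toupper(x$kind), " regression\n", sep = "")
  cat("  log-likelihood: ", formatC(x$loglik, format = "f", digits = 2),
      "   AIC: ", formatC(x$aic, format = "f", digits = 2),
      "   parameters: ", x$n_params, "\n", sep = "")
  cat("  Pearson chi-squared: ", formatC(x$pearson, format = "f", digits = 2),
      "   converged: ", x$converged, "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
logLik.fatality_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = object$nobs, class = "logLik")
}

#' @export
coef.fatality_fit <- function(object, ...) object$coefficients

#' @export
vcov.fatality_fit <- function(object, ...) object$vcov

# per-row (lambda, nu, pi) on the response scale
linear_params <- function(fit, ds) {
  p <- fit$parts
  lam <- exp(as.vector(ds$X %*% p$beta))
  nu <- if (!is.null(p$delta)) exp(as.vector(ds$S %*% p$delta)) else rep(1, length(lam))
  pi <- if (!is.null(p$gamma)) {
    ez <- as.vector(ds$W %*% p$gamma)
    1 / (1 + exp(-ez))
  } else {
    rep(0, length(lam))
  }
  list(lambda = lam, nu = nu, pi = pi)
}

# expected outcome per row; approx = TRUE uses the asymptotic CMP mean
fitted_mean <- function(fit, ds = fit$design, approx = FALSE) {
  lp <- linear_params(fit, ds)
  base <- switch(fit$kind,
    poisson = lp$lambda,
    zip = lp$lambda,
    cmp = ,
    zicmp = {
      key <- complex(real = lp$lambda, imaginary = lp$nu)
      ui <- !duplicated(key)
      m <- cmp_moments(lp$lambda[ui], lp$nu[ui],
                       method = if (approx) "approx" else "exact",
                       control = fit$control$series)$mean
      m[match(key, key[ui])]
    }
  )
  (1 - lp$pi) * base
}

#' Predict expected deaths (or model parameters) from a fitted model
#'
#' @param object A [fit_fatality_model()] fit.
#' @param newdata Optional new records tibble (or design); defaults to the
#'   training design.
#' @param type `"mean"` for the expected outcome per row (Poisson:
#'   \eqn{\lambda}; CMP: exact series mean; ZIP: \eqn{(1-\pi)\lambda};
#'   ZICMP: \eqn{(1-\pi)} times the exact CMP mean), or `"lambda"`,
#'   `"nu"`, `"pi"` for the linked parameters.
#' @param ... Unused.
#' @return A numeric vector, one value per row.
#' @export
predict.fatality_fit <- function(object, newdata = NULL,
                                 type = c("mean", "lambda", "nu", "pi"), ...) {
  type <- match.arg(type)
  ds <- if (is.null(newdata)) {
    object$design
  } else if (inherits(newdata, "design_set")) {
    newdata
  } else {
    if (!"deaths" %in% names(newdata)) newdata$deaths <- 0L
    f <- object$design$formulas
    build_design(newdata, count = f$count, dispersion = f$dispersion,
                 zero = f$zero, coding = object$design$coding)
  }
  if (ncol(ds$X) != ncol(object$design$X)) {
    abort("`newdata` design does not match the fitted coefficients.")
  }
  if (type == "mean") return(fitted_mean(object, ds))
  linear_params(object, ds)[[type]]
}

#' Tidy coefficient table for a fitted count model
#'
#' One row per estimated coefficient, in the broom convention, with a
#' `part` column identifying the model component: `count`
#' (\eqn{\beta}, log link on \eqn{\lambda}), `dispersion` (\eqn{\delta},
#' log link on \eqn{\nu}) or `zero` (\eqn{\gamma}, logit link on
#' \eqn{\pi}).
#'
#' @param x A `fatality_fit`.
#' @param ... Unused.
#' @return A tibble with columns `part`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `boundary`.
#' @method tidy fatality_fit
#' @export
tidy.fatality_fit <- function(x, ...) {
  part_label <- c(beta = "count", delta = "dispersion", gamma = "zero")
  rows <- purrr::imap(x$parts, function(v, nm) {
    tibble::tibble(part = part_label[[nm]], term = names(v), estimate = unname(v))
  })
  out <- dplyr::bind_rows(rows)
  out$std.error <- unname(x$se)
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  out$boundary <- unname(x$boundary)
  out
}

#' One-row model summary
#'
#' @param x A `fatality_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `logLik`, `AIC`, `pearson`,
#'   `n_params`, `nobs`, `converged`.
#' @method glance fatality_fit
#' @export
glance.fatality_fit <- function(x, ...) {
  tibble::tibble(model = x$kind, logLik = x$loglik, AIC = x$aic,
                 pearson = x$pearson, n_params = x$n_params,
                 nobs = x$nobs, converged = x$converged)
}

#' Observed vs fitted frequency plot
#'
#' Compares the observed frequency distribution of the outcome with the
#' frequencies implied by the fitted model (expected number of
#' observations per count value, averaged over the design rows).
#'
#' @param object A `fatality_fit`.
#' @param max_count Largest count value displayed (default: observed
#'   maximum).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fatality_fit
#' @export
autoplot.fatality_fit <- function(object, max_count = NULL, ...) {
  ds <- object$design
  if (is.null(max_count)) max_count <- max(ds$y)
  yv <- 0:max_count
  lp <- linear_params(object, ds)
  n <- sum(ds$w)
  expected <- vapply(yv, function(v) {
    sum(ds$w * dzicmp(v, lp$lambda, lp$nu, lp$pi,
                      control = object$control$series))
  }, numeric(1))
  obs <- vapply(yv, function(v) sum(ds$w[ds$y == v]), numeric(1))
  df <- tibble::tibble(
    deaths = rep(yv, 2L),
    accidents = c(obs, expected),
    source = rep(c("observed", "fitted"), each = length(yv))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deaths, y = .data$accidents,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "deaths per accident", y = "number of accidents",
                  fill = NULL,
                  title = paste(toupper(object$kind),
                                "fit: observed vs fitted frequencies")) +
    ggplot2::theme_minimal()
}
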