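#' Control parameters for model fitting
#'
#' @param rel_tol,max_terms Series truncation settings passed to
#'   [cmp_control()].
#' @param max_iter Maximum quasi-Newton iterations (default 500).
#' @param reltol Relative log-likelihood convergence tolerance for the
#'   optimizer.
#' @param logit_clamp Absolute bound on the zero-part linear predictor
#'   (logit scale).  Beyond it the structural-zero probability is
#'   numerically 0 or 1 and the likelihood is flat.
#' @param boundary_tol Zero-part coefficients whose absolute value exceeds
#'   this are flagged as boundary estimates; their Wald standard errors
#'   are unreliable because the likelihood is nearly flat there.
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(rel_tol = 1e-12, max_terms = 10000L, max_iter = 500L,
                        reltol = 1e-12, logit_clamp = 30, boundary_tol = 10) {
  structure(list(series = cmp_control(rel_tol, max_terms),
                 max_iter = as.integer(max_iter), reltol = reltol,
                 logit_clamp = logit_clamp, boundary_tol = boundary_tol),
            class = "fit_control")
}

log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(pmin(x, 35))))

# log(exp(a) + exp(b)) elementwise, stable
lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

resolve_design <- function(data, count, dispersion, zero, weights, coding,
                           response) {
  if (inherits(data, "design_set")) return(data)
  build_design(data, count = count, dispersion = dispersion, zero = zero,
               weights = weights, coding = coding, response = response)
}

# weighted log-likelihoods; par is the concatenated coefficient vector
split_par <- function(par, dims) {
  out <- list()
  i <- 0L
  for (nm in names(dims)) {
    out[[nm]] <- par[i + seq_len(dims[[nm]])]
    i <- i + dims[[nm]]
  }
  out
}

loglik_poisson <- function(par, ds) {
  lam <- exp(drop(ds$X %*% par))
  sum(ds$w * (-lam + ds$y * log(lam) - lgamma(ds$y + 1)))
}

loglik_cmp <- function(par, ds, control) {
  p <- split_par(par, c(beta = ncol(ds$X), delta = ncol(ds$S)))
  eta <- drop(ds$X %*% p$beta)
  nu <- exp(drop(ds$S %*% p$delta))
  lz <- cmp_log_z(exp(eta), nu, control$series)
  sum(ds$w * (ds$y * eta - nu * lgamma(ds$y + 1) - lz))
}

loglik_zip <- function(par, ds, control) {
  p <- split_par(par, c(beta = ncol(ds$X), gamma = ncol(ds$W)))
  eta <- drop(ds$X %*% p$beta)
  lam <- exp(eta)
  ez <- drop(ds$W %*% p$gamma)
  ez <- pmin(pmax(ez, -control$logit_clamp), control$logit_clamp)
  z <- ds$y == 0
  ll <- numeric(length(ds$y))
  ll[z] <- lse2(ez[z], -lam[z])
  ll[!z] <- ds$y[!z] * eta[!z] - lam[!z] - lgamma(ds$y[!z] + 1)
  sum(ds$w * (ll - log1pexp(ez)))
}

# analytic scores; each returns the gradient of the *log-likelihood*
grad_cmp <- function(par, ds, control) {
  p <- split_par(par, c(beta = ncol(ds$X), delta = ncol(ds$S)))
  lam <- exp(drop(ds$X %*% p$beta))
  nu <- exp(drop(ds$S %*% p$delta))
  st <- cmp_series_stats(lam, nu, control$series)
  r_eta <- ds$w * (ds$y - st$mean)
  r_s <- ds$w * nu * (st$elogfact - lgamma(ds$y + 1))
  c(drop(crossprod(ds$X, r_eta)), drop(crossprod(ds$S, r_s)))
}

grad_zip <- function(par, ds, control) {
  p <- split_par(par, c(beta = ncol(ds$X), gamma = ncol(ds$W)))
  lam <- exp(drop(ds$X %*% p$beta))
  ez <- pmin(pmax(drop(ds$W %*% p$gamma), -control$logit_clamp),
             control$logit_clamp)
  pr <- 1 / (1 + exp(-ez))
  z <- ds$y == 0
  q <- exp(ez - lse2(ez, -lam))          # structural share of a zero
  r_eta <- ifelse(z, -(1 - q) * lam, ds$y - lam) * ds$w
  r_g <- (ifelse(z, q, 0) - pr) * ds$w
  c(drop(crossprod(ds$X, r_eta)), drop(crossprod(ds$W, r_g)))
}

grad_zicmp <- function(par, ds, control) {
  p <- split_par(par, c(beta = ncol(ds$X), delta = ncol(ds$S),
                        gamma = ncol(ds$W)))
  lam <- exp(drop(ds$X %*% p$beta))
  nu <- exp(drop(ds$S %*% p$delta))
  st <- cmp_series_stats(lam, nu, control$series)
  ez <- pmin(pmax(drop(ds$W %*% p$gamma), -control$logit_clamp),
             control$logit_clamp)
  pr <- 1 / (1 + exp(-ez))
  z <- ds$y == 0
  q <- exp(ez - lse2(ez, -st$logz))
  cw <- ifelse(z, 1 - q, 1)              # weight of the CMP component
  r_eta <- ifelse(z, -cw * st$mean, ds$y - st$mean) * ds$w
  r_s <- cw * nu * (st$elogfact - ifelse(z, 0, lgamma(ds$y + 1))) * ds$w
  r_g <- (ifelse(z, q, 0) - pr) * ds$w
  c(drop(crossprod(ds$X, r_eta)), drop(crossprod(ds$S, r_s)),
    drop(crossprod(ds$W, r_g)))
}

loglik_zicmp <- function(par, ds, control) {
  p <- split_par(par, c(beta = ncol(ds$X), delta = ncol(ds$S),
                        gamma = ncol(ds$W)))
  eta <- drop(ds$X %*% p$beta)
  nu <- exp(drop(ds$S %*% p$delta))
  lz <- cmp_log_z(exp(eta), nu, control$series)
  ez <- drop(ds$W %*% p$gamma)
  ez <- pmin(pmax(ez, -control$logit_clamp), control$logit_clamp)
  z <- ds$y == 0
  ll <- numeric(length(ds$y))
  ll[z] <- lse2(ez[z], -lz[z])
  ll[!z] <- ds$y[!z] * eta[!z] - nu[!z] * lgamma(ds$y[!z] + 1) - lz[!z]
  sum(ds$w * (ll - log1pexp(ez)))
}

start_values <- function(kind, ds) {
  pois <- glm.fit(ds$X, ds$y, weights = ds$w, family = poisson(),
                  control = list(epsilon = 1e-14, maxit = 100))
  beta0 <- unname(pois$coefficients)
  if (kind == "poisson") return(beta0)
  if (kind == "cmp") return(c(beta0, rep(0, ncol(ds$S))))
  # zero part: logit of the excess-zero fraction under the Poisson fit
  p0 <- sum(ds$w * exp(-pois$fitted.values)) / sum(ds$w)
  f0 <- sum(ds$w[ds$y == 0]) / sum(ds$w)
  pi0 <- max(f0 - p0, 1e-3)
  g0 <- c(log(pi0 / (1 - pi0)), rep(0, ncol(ds$W) - 1L))
  if (kind == "zip") return(c(beta0, g0))
  c(beta0, rep(0, ncol(ds$S)), g0)
}

part_names <- list(
  poisson = c("beta"),
  cmp = c("beta", "delta"),
  zip = c("beta", "gamma"),
  zicmp = c("beta", "delta", "gamma")
)

part_dims <- function(kind, ds) {
  d <- c(beta = ncol(ds$X), delta = ncol(ds$S), gamma = ncol(ds$W))
  d[part_names[[kind]]]
}

#' Fit a count regression model for accident fatalities
#'
#' Maximum-likelihood fitting of one of four nested count models for a
#' nonnegative integer outcome such as deaths per crash:
#' \describe{
#'   \item{poisson}{log link, \eqn{\lambda_i = \exp(X_i'\beta)}.}
#'   \item{cmp}{Conway-Maxwell-Poisson; adds a dispersion part
#'     \eqn{\nu_i = \exp(S_i'\delta)}; \eqn{\nu > 1} captures
#'     underdispersion.}
#'   \item{zip}{zero-inflated Poisson; adds a structural-zero part
#'     \eqn{\mathrm{logit}(\pi_i) = W_i'\gamma}.}
#'   \item{zicmp}{zero-inflated CMP with all three parts.}
#' }
#' The models nest: Poisson is CMP with \eqn{\delta = 0} and ZIP/ZICMP
#' with \eqn{\pi = 0}, so the maximized log-likelihoods are ordered
#' accordingly.
#'
#' Optimization is quasi-Newton (BFGS) on the unconstrained coefficient
#' scale, initialized from the Poisson fit (\eqn{\delta} at zero,
#' \eqn{\gamma} at the logit of the excess-zero fraction).  Standard
#' errors come from the inverse numerical Hessian of the negative
#' log-likelihood at the optimum.  When the data carry no evidence of
#' structural zeros the zero-part intercept drifts to the negative
#' boundary; such coefficients are flagged (`boundary`) and their Wald
#' standard errors should not be trusted.
#'
#' @param data A records tibble, a [freq_table()], or a prebuilt
#'   [build_design()] object.
#' @param model One of `"poisson"`, `"cmp"`, `"zip"`, `"zicmp"`.
#' @param count,dispersion,zero One-sided formulas for the three model
#'   parts (ignored when `data` is already a design).
#' @param weights Optional case weights.
#' @param coding Categorical level coding, see [accident_coding()].
#' @param response Outcome column name (default `"deaths"`).
#' @param start Optional starting coefficient vector.
#' @param control See [fit_control()].
#' @return An object of class `"fatality_fit"`; see [tidy.fatality_fit()]
#'   and [glance.fatality_fit()] for tibble summaries.
#' @examples
#' fit <- fit_fatality_model(thai_fatalities_2015(), model = "cmp")
#' glance(fit)
#' @export
fit_fatality_model <- function(data, model = c("poisson", "cmp", "zip", "zicmp"),
                               count = ~1, dispersion = ~1, zero = ~1,
                               weights = NULL, coding = accident_coding(),
                               response = "deaths", start = NULL,
                               control = fit_control()) {
  kind <- match.arg(model)
  ds <- resolve_design(data, count, dispersion, zero, weights, coding,
                       response)
  if (all(ds$y == 0)) {
    abort("All outcomes are zero: the count-part rate is not identifiable.")
  }
  if (kind %in% c("zip", "zicmp") && !any(ds$y == 0)) {
    warn("No zero outcomes observed: the zero part sits at the boundary.")
  }
  dims <- part_dims(kind, ds)
  raw_nll <- switch(kind,
    poisson = function(p) -loglik_poisson(p, ds),
    cmp = function(p) -loglik_cmp(p, ds, control),
    zip = function(p) -loglik_zip(p, ds, control),
    zicmp = function(p) -loglik_zicmp(p, ds, control)
  )
  raw_gr <- switch(kind,
    poisson = function(p) {
      lam <- exp(drop(ds$X %*% p))
      drop(crossprod(ds$X, ds$w * (ds$y - lam)))
    },
    cmp = function(p) grad_cmp(p, ds, control),
    zip = function(p) grad_zip(p, ds, control),
    zicmp = function(p) grad_zicmp(p, ds, control)
  )
  # line-search steps can wander into overflow or series-divergence
  # territory; a large finite penalty makes the optimizer back off
  nll <- function(p) {
    v <- tryCatch(raw_nll(p), error = function(e) Inf)
    if (is.finite(v)) v else 1e15
  }
  ngr <- function(p) {
    g <- tryCatch(-raw_gr(p), error = function(e) NULL)
    if (is.null(g) || any(!is.finite(g))) rep(0, length(p)) else g
  }
  user_start <- start
  if (is.null(start)) start <- start_values(kind, ds)
  if (length(start) != sum(dims)) {
    abort(paste0("`start` must have length ", sum(dims), " for this design."))
  }
  run_opt <- function(p0) {
    optim(p0, nll, gr = ngr, method = "BFGS",
          control = list(maxit = control$max_iter, reltol = control$reltol))
  }
  if (kind == "poisson") {
    # the Poisson MLE is an ordinary GLM solve; no quasi-Newton needed
    pois <- glm.fit(ds$X, ds$y, weights = ds$w, family = poisson(),
                    control = list(epsilon = 1e-14, maxit = 100))
    opt <- list(par = unname(pois$coefficients),
                value = nll(unname(pois$coefficients)),
                convergence = if (pois$converged) 0L else 1L)
  } else {
    starts <- list(start)
    if (kind %in% c("zip", "zicmp") && is.null(user_start)) {
      # the zero-mass / count-rate trade-off makes the likelihood a
      # curved ridge; a short pi grid of moment-informed starts avoids
      # stalling on it
      ybar <- sum(ds$w * ds$y) / sum(ds$w)
      for (pi0 in c(0.1, 0.3)) {
        b0 <- c(log(ybar / (1 - pi0)), rep(0, ncol(ds$X) - 1L))
        g0 <- c(log(pi0 / (1 - pi0)), rep(0, ncol(ds$W) - 1L))
        starts <- c(starts, list(switch(kind,
          zip = c(b0, g0),
          zicmp = c(b0, rep(0, ncol(ds$S)), g0)
        )))
      }
    }
    opts <- lapply(starts, run_opt)
    opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
    # a restart resets the Hessian approximation, which recovers slow
    # progress along the flat ridge that appears when pi collapses to 0
    o2 <- run_opt(opt$par)
    if (o2$value <= opt$value) opt <- o2
  }
  if (kind %in% c("zip", "zicmp")) {
    # explicit no-inflation candidate: the boundary pi = 0 is outside the
    # logit parameter space, so the optimizer cannot reach it on its own
    gi <- sum(dims[names(dims) != "gamma"]) + seq_len(dims[["gamma"]])
    cand <- opt$par
    cand[gi] <- c(-control$logit_clamp, rep(0, length(gi) - 1L))
    v_cand <- nll(cand)
    o3 <- run_opt(cand)                  # re-optimize the other parts too
    if (o3$value <= v_cand && o3$value < opt$value) {
      opt <- o3
    } else if (v_cand < opt$value) {
      opt <- list(par = cand, value = v_cand, convergence = 0L)
    }
  }
  parts <- split_par(opt$par, dims)
  cn <- list(beta = colnames(ds$X), delta = colnames(ds$S),
             gamma = colnames(ds$W))
  for (nm in names(parts)) names(parts[[nm]]) <- cn[[nm]]

  boundary <- rep(FALSE, length(opt$par))
  if ("gamma" %in% names(dims)) {
    gi <- sum(dims[names(dims) != "gamma"]) + seq_len(dims[["gamma"]])
    boundary[gi] <- abs(opt$par[gi]) >= control$boundary_tol
  }

  k <- length(opt$par)
  h <- tryCatch(optimHess(opt$par, nll, gr = ngr), error = function(e) NULL)
  vc <- if (!is.null(h)) tryCatch(solve(h), error = function(e) NULL)
  if (is.null(vc)) {
    # boundary coefficients flatten the likelihood and can make the full
    # Hessian singular; invert the interior block and leave them NA
    vc <- matrix(NA_real_, k, k)
    keep <- !boundary
    if (!is.null(h) && any(keep)) {
      sub <- tryCatch(solve(h[keep, keep, drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(sub)) vc[keep, keep] <- sub
    }
  }
  dvc <- diag(vc)
  se <- rep(NA_real_, k)
  ok_d <- is.finite(dvc) & dvc > 0
  se[ok_d] <- sqrt(dvc[ok_d])

  ll <- -opt$value
  fit <- structure(list(
    kind = kind,
    parts = parts,
    coefficients = setNames(opt$par, flat_names(parts)),
    se = setNames(se, flat_names(parts)),
    vcov = vc,
    loglik = ll,
    aic = -2 * ll + 2 * k,
    n_params = k,
    converged = opt$convergence == 0L,
    boundary = setNames(boundary, flat_names(parts)),
    design = ds,
    nobs = sum(ds$w),
    control = control,
    call = match.call()
  ), class = "fatality_fit")
  fit$pearson <- pearson_gof(fit)
  fit
}

flat_names <- function(parts) {
  unlist(lapply(names(parts), function(nm) {
    paste0(nm, "_", names(parts[[nm]]))
  }), use.names = FALSE)
}

#' @rdname fit_fatality_model
#' @param ... Passed on to [fit_fatality_model()].
#' @export
fit_poisson <- function(data, ...) fit_fatality_model(data, "poisson", ...)

#' @rdname fit_fatality_model
#' @export
fit_cmp <- function(data, ...) fit_fatality_model(data, "cmp", ...)

#' @rdname fit_fatality_model
#' @export
fit_zip <- function(data, ...) fit_fatality_model(data, "zip", ...)

#' @rdname fit_fatality_model
#' @export
fit_zicmp <- function(data, ...) fit_fatality_model(data, "zicmp", ...)
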