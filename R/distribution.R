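#' Conway-Maxwell-Poisson probability mass function
#'
#' \eqn{\Pr(Y=y) = \lambda^y / ((y!)^\nu Z(\lambda,\nu))}.  `nu = 1`
#' recovers the Poisson pmf exactly; `nu > 1` concentrates mass around the
#' mode (underdispersion), `nu < 1` spreads it out (overdispersion).
#'
#' @param x Vector of nonnegative integer quantiles.
#' @param lambda,nu CMP parameters (see [cmp_log_z()]).
#' @param log Return log-probabilities?
#' @param control Series truncation settings, see [cmp_control()].
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' dcmp(0:5, lambda = 2, nu = 1)  # identical to dpois(0:5, 2)
#' dcmp(0:5, lambda = 0.33189, nu = 1.55024)
#' @export
dcmp <- function(x, lambda, nu, log = FALSE, control = cmp_control()) {
  check_cmp_params(lambda, nu)
  nn <- max(length(x), length(lambda), length(nu))
  x <- rep_len(x, nn)
  lambda <- rep_len(lambda, nn)
  nu <- rep_len(nu, nn)
  if (any(x != floor(x) & is.finite(x))) {
    warn("non-integer x in dcmp: returning probability 0")
  }
  lp <- rep(-Inf, nn)
  ok <- is.finite(x) & x >= 0 & x == floor(x)
  lz <- cmp_log_z(lambda[ok], nu[ok], control)
  lp[ok] <- x[ok] * log(lambda[ok]) - nu[ok] * lgamma(x[ok] + 1) - lz
  if (log) lp else exp(lp)
}

#' Zero-inflated CMP probability mass function
#'
#' A mixture of a point mass at zero with probability `pi` and a
#' CMP(`lambda`, `nu`) distribution with probability `1 - pi`:
#' \eqn{\Pr(Y=0) = \pi + (1-\pi)/Z(\lambda,\nu)} and
#' \eqn{\Pr(Y=y) = (1-\pi)\lambda^y/((y!)^\nu Z)} for \eqn{y > 0}.
#' `pi = 0` reduces to the CMP pmf; `nu = 1` in addition reduces to the
#' zero-inflated Poisson pmf.
#'
#' @inheritParams dcmp
#' @param pi Zero-inflation probability in \[0, 1\] (structural,
#'   "always-zero" component).
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' dzicmp(0:3, lambda = 2, nu = 1, pi = 0.3)
#' @export
dzicmp <- function(x, lambda, nu, pi, log = FALSE, control = cmp_control()) {
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1)) {
    abort("`pi` must lie in [0, 1].")
  }
  nn <- max(length(x), length(lambda), length(nu), length(pi))
  x <- rep_len(x, nn)
  pi <- rep_len(pi, nn)
  base <- dcmp(x, rep_len(lambda, nn), rep_len(nu, nn), log = FALSE,
               control = control)
  p <- (1 - pi) * base + pi * as.numeric(x == 0)
  if (log) base::log(p) else p
}

#' CMP moments: exact series or asymptotic approximation
#'
#' The exact mean and variance are \eqn{\sum_j j\,p(j)} and
#' \eqn{\sum_j j^2 p(j) - E(Y)^2} over the truncated support.  The
#' asymptotic approximations are
#' \eqn{E(Y) \approx \lambda^{1/\nu} - (\nu-1)/(2\nu)} and
#' \eqn{Var(Y) \approx \lambda^{1/\nu}/\nu}; they are accurate for
#' \eqn{\lambda^{1/\nu}} large but materially biased at small rates (for
#' \eqn{\lambda \approx 0.33, \nu \approx 1.55} the approximate mean is
#' 0.313 while the exact mean is 0.302), which is why both forms are kept.
#'
#' @inheritParams dcmp
#' @param method `"exact"` (default, series summation) or `"approx"`
#'   (asymptotic closed form; rejected for `nu = 0`).
#' @return A tibble with columns `lambda`, `nu`, `mean`, `variance`.
#' @examples
#' cmp_moments(2, 1)                          # Poisson: mean = var = 2
#' cmp_moments(0.33189, 1.55024, "approx")    # mean ~ 0.313
#' cmp_moments(0.33189, 1.55024, "exact")     # mean ~ 0.302
#' @export
cmp_moments <- function(lambda, nu, method = c("exact", "approx"),
                        control = cmp_control()) {
  method <- match.arg(method)
  check_cmp_params(lambda, nu)
  nn <- max(length(lambda), length(nu))
  lambda <- rep_len(lambda, nn)
  nu <- rep_len(nu, nn)
  if (method == "approx") {
    if (any(nu == 0)) {
      abort("The asymptotic moment approximation is undefined for nu = 0.")
    }
    mu <- lambda^(1 / nu) - (nu - 1) / (2 * nu)
    v <- lambda^(1 / nu) / nu
  } else {
    mm <- vapply(seq_len(nn), function(i) {
      sup <- cmp_support(lambda[i], nu[i], control)
      p <- dcmp(sup, lambda[i], nu[i], control = control)
      m1 <- sum(sup * p)
      c(m1, sum(sup^2 * p) - m1^2)
    }, numeric(2))
    mu <- mm[1, ]
    v <- mm[2, ]
  }
  tibble::tibble(lambda = lambda, nu = nu, mean = mu, variance = v)
}

# log Z, E[Y] and E[ln Y!] per observation, deduped over (lambda, nu)
# pairs; the two expectations drive the analytic score of the CMP family
cmp_series_stats <- function(lambda, nu, control = cmp_control()) {
  key <- complex(real = lambda, imaginary = nu)
  uk <- unique(key)
  idx <- match(uk, key)
  st <- vapply(idx, function(i) {
    sup <- cmp_support(lambda[i], nu[i], control)
    lz <- cmp_log_z(lambda[i], nu[i], control)
    p <- exp(sup * log(lambda[i]) - nu[i] * lgamma(sup + 1) - lz)
    c(lz, sum(sup * p), sum(lgamma(sup + 1) * p))
  }, numeric(3))
  pos <- match(key, uk)
  list(logz = st[1, pos], mean = st[2, pos], elogfact = st[3, pos])
}

# truncated support covering all but ~rel_tol of the mass
cmp_support <- function(lambda, nu, control = cmp_control()) {
  lz <- cmp_log_z(lambda, nu, control)
  mode_j <- if (nu > 0) lambda^(1 / nu) else lambda / (1 - lambda)
  j <- max(20L, ceiling(4 * mode_j + 20))
  log_tol <- log(control$rel_tol)
  repeat {
    if (j * log(lambda) - nu * lgamma(j + 1) - lz < log_tol - log1p(j)) break
    j <- j * 2L
    if (j > control$max_terms) {
      abort("CMP support truncation exceeded `max_terms`.")
    }
  }
  0:j
}

#' Sample from the CMP distribution
#'
#' Draws by inversion of the cumulative pmf over the truncated support, so
#' results are exact (up to series tolerance) and stable under a fixed RNG
#' seed.  Uses R's global random number stream; call [set.seed()] or pass
#' `seed` for reproducibility.
#'
#' @param n Number of draws.
#' @param lambda,nu CMP parameters; vectors are recycled to length `n`
#'   for row-specific draws.
#' @param seed Optional integer seed applied via [set.seed()] before
#'   drawing.
#' @param control See [cmp_control()].
#' @return Integer vector of length `n`.
#' @examples
#' rcmp(5, lambda = 0.33, nu = 1.55, seed = 1)
#' @export
rcmp <- function(n, lambda, nu, seed = NULL, control = cmp_control()) {
  if (!is.null(seed)) set.seed(seed)
  check_cmp_params(lambda, nu)
  lambda <- rep_len(lambda, n)
  nu <- rep_len(nu, n)
  u <- runif(n)
  out <- integer(n)
  key <- complex(real = lambda, imaginary = nu)
  for (k in unique(key)) {
    idx <- which(key == k)
    i <- idx[1L]
    sup <- cmp_support(lambda[i], nu[i], control)
    cdf <- pmin(cumsum(dcmp(sup, lambda[i], nu[i], control = control)), 1)
    cdf[length(cdf)] <- 1
    out[idx] <- findInterval(u[idx], cdf) # P(U <= cdf[j]) inverts the cdf
  }
  out
}

#' Sample from the zero-inflated CMP distribution
#'
#' Two-stage draw: a Bernoulli(`pi`) structural zero, otherwise a CMP
#' draw by cdf inversion (see [rcmp()]).
#'
#' @inheritParams rcmp
#' @param pi Zero-inflation probability in \[0, 1\], recycled to length
#'   `n`.
#' @return Integer vector of length `n`.
#' @examples
#' rzicmp(10, lambda = 2, nu = 1, pi = 0.3, seed = 1)
#' @export
rzicmp <- function(n, lambda, nu, pi, seed = NULL, control = cmp_control()) {
  if (!is.null(seed)) set.seed(seed)
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1)) {
    abort("`pi` must lie in [0, 1].")
  }
  pi <- rep_len(pi, n)
  structural <- rbinom(n, 1L, pi) == 1L
  y <- rcmp(n, lambda, nu, control = control)
  y[structural] <- 0L
  y
}
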