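# Independent brute-force oracles: direct (non-log) summation of the CMP
# series, kept deliberately simpler than the package's log-sum-exp path.

oracle_z <- function(lambda, nu, jmax = 50) {
  j <- 0:jmax
  sum(lambda^j / factorial(j)^nu)
}

oracle_pmf <- function(y, lambda, nu, jmax = 50) {
  lambda^y / factorial(y)^nu / oracle_z(lambda, nu, jmax)
}

oracle_mean <- function(lambda, nu, jmax = 50) {
  j <- 0:jmax
  p <- lambda^j / factorial(j)^nu
  sum(j * p) / sum(p)
}

oracle_var <- function(lambda, nu, jmax = 50) {
  j <- 0:jmax
  p <- lambda^j / factorial(j)^nu
  p <- p / sum(p)
  sum(j^2 * p) - sum(j * p)^2
}

# weighted Poisson log-likelihood by direct arithmetic
oracle_pois_ll <- function(freq, lambda) {
  sum(freq$accidents *
        (-lambda + freq$deaths * log(lambda) - lgamma(freq$deaths + 1)))
}

# a small frequency table used across tests (underdispersed, zero heavy)
toy_freq <- function() freq_table(deaths = 0:3, accidents = c(60, 30, 8, 2))
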