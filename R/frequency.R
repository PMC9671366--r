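#' Construct a count frequency table
#'
#' A frequency table records, for each distinct outcome value (deaths per
#' accident), the number of accidents observed with that value.  Model
#' fitting on a frequency table is exactly equivalent to fitting the
#' expanded record-level data with case weights equal to the frequencies.
#'
#' @param deaths Distinct nonnegative integer outcome values.
#' @param accidents Nonnegative counts of observations per value.
#' @return A tibble with columns `deaths` and `accidents` and class
#'   `"freq_table"`.
#' @examples
#' freq_table(deaths = 0:2, accidents = c(10, 5, 1))
#' @export
freq_table <- function(deaths, accidents) {
  if (length(deaths) != length(accidents)) {
    abort("`deaths` and `accidents` must have equal length.")
  }
  if (any(deaths < 0) || any(deaths != floor(deaths))) {
    abort("`deaths` must be distinct nonnegative integers.")
  }
  if (anyDuplicated(deaths)) abort("`deaths` values must be distinct.")
  if (any(accidents < 0)) abort("`accidents` counts must be nonnegative.")
  out <- tibble::tibble(deaths = as.integer(deaths),
                        accidents = as.numeric(accidents))
  out <- dplyr::arrange(out, .data$deaths)
  class(out) <- c("freq_table", class(out))
  out
}

is_freq_table <- function(x) {
  inherits(x, "freq_table") ||
    (is.data.frame(x) && all(c("deaths", "accidents") %in% names(x)) &&
       ncol(x) == 2L && !anyDuplicated(x$deaths))
}

#' Deaths-per-accident frequency distribution, Thailand 2015
#'
#' The marginal distribution of human deaths per road traffic accident
#' among the 20,229 complete accident records collected by Thailand's
#' Department of Disaster Prevention and Mitigation for 2015: 72.38% of
#' crashes were non-fatal, and no crash killed more than six people.
#' The total death toll is 6,109, and the sample variance is below the
#' mean -- the distribution is underdispersed.
#'
#' @return A [freq_table()] tibble with 7 rows (deaths 0 through 6).
#' @examples
#' thai_fatalities_2015()
#' sum(thai_fatalities_2015()$accidents)  # 20229
#' @export
thai_fatalities_2015 <- function() {
  freq_table(deaths = 0:6,
             accidents = c(14641, 5218, 285, 45, 23, 8, 9))
}

#' Expand a frequency table to record-level data
#'
#' @param freq A [freq_table()] or any two-column data frame with columns
#'   `deaths` and `accidents`.
#' @return A tibble with one `deaths` row per accident.
#' @examples
#' freq_to_records(freq_table(0:1, c(3, 2)))
#' @export
freq_to_records <- function(freq) {
  freq <- as_freq_table(freq)
  tibble::tibble(deaths = rep(freq$deaths, times = freq$accidents))
}

#' Coerce to a frequency table
#'
#' Accepts an existing frequency table, a record-level data frame with a
#' `deaths` column (tabulated), or a bare integer vector of outcomes.
#'
#' @param x Object to coerce.
#' @return A [freq_table()] tibble.
#' @export
as_freq_table <- function(x) {
  if (inherits(x, "freq_table")) return(x)
  if (is.data.frame(x) && all(c("deaths", "accidents") %in% names(x)) &&
      !anyDuplicated(x$deaths)) {
    return(freq_table(x$deaths, x$accidents))
  }
  if (is.data.frame(x) && "deaths" %in% names(x)) x <- x$deaths
  if (is.numeric(x)) {
    tab <- table(x)
    return(freq_table(as.integer(names(tab)), as.numeric(tab)))
  }
  abort("Cannot coerce `x` to a frequency table.")
}

freq_summary <- function(freq) {
  n <- sum(freq$accidents)
  mean <- sum(freq$deaths * freq$accidents) / n
  ss <- sum(freq$accidents * (freq$deaths - mean)^2)
  list(n = n, n0 = sum(freq$accidents[freq$deaths == 0]),
       mean = mean, variance = ss / (n - 1))
}
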