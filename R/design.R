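#' Default categorical coding for accident covariates
#'
#' Ordered level labels for the six road/environment covariates; the first
#' level of each variable is the baseline of its treatment (dummy) coding.
#' Baselines are National highway, Dry, Straight, Clear, Day and January.
#'
#' @return A named list of character vectors (class `"accident_coding"`).
#' @examples
#' accident_coding()$road_surface
#' @export
accident_coding <- function() {
  structure(list(
    roadway_class = c("National highway", "Rural highway", "Urban road",
                      "Local street"),
    road_surface = c("Dry", "Wet"),
    road_section = c("Straight", "Curve", "Crossing and others"),
    weather = c("Clear", "Fog", "Rain"),
    light = c("Day", "Night with light", "Night without light"),
    month = month.name
  ), class = "accident_coding")
}

apply_coding <- function(data, coding) {
  for (v in intersect(names(coding), names(data))) {
    x <- as.character(data[[v]])
    bad <- which(!is.na(x) & !x %in% coding[[v]])
    if (length(bad)) {
      abort(paste0(
        "Unknown level ", encodeString(x[bad[1]], quote = '"'),
        " for variable `", v, "` at record ", bad[1],
        if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)")
      ))
    }
    data[[v]] <- factor(x, levels = coding[[v]])
  }
  data
}

part_matrix <- function(formula, data) {
  if (is.null(formula)) formula <- ~1
  mf <- model.frame(formula, data, na.action = NULL, drop.unused.levels = FALSE)
  if (anyNA(mf)) abort("Missing values in model covariates are not supported.")
  model.matrix(formula, mf)
}

#' Build the three-part design for a count regression
#'
#' Assembles the outcome vector, case weights and the three design
#' matrices used by the zero-inflated CMP family: `X` for the count part
#' (log link on the rate \eqn{\lambda}), `S` for the dispersion part (log
#' link on \eqn{\nu}) and `W` for the zero part (logit link on the
#' structural-zero probability \eqn{\pi}).  Categorical covariates use
#' treatment coding with the baseline level first, in deterministic
#' variable-then-level order.
#'
#' A [freq_table()] input is expanded to one row per distinct count value
#' with weight equal to its frequency; this requires intercept-only
#' formulas.
#'
#' @param data A records tibble (one row per accident), or a
#'   [freq_table()].
#' @param count,dispersion,zero One-sided formulas for each model part;
#'   default intercept-only.
#' @param weights Optional positive case weights (default 1 per row).
#' @param coding Level coding; see [accident_coding()].  Variables absent
#'   from the coding keep their observed factor levels.
#' @param response Name of the outcome column (default `"deaths"`).
#' @return A list of class `"design_set"` with elements `y`, `w`, `X`,
#'   `S`, `W`, `coding`, `formulas`.
#' @examples
#' build_design(thai_fatalities_2015())
#' @export
build_design <- function(data, count = ~1, dispersion = ~1, zero = ~1,
                         weights = NULL, coding = accident_coding(),
                         response = "deaths") {
  if (is_freq_table(data)) {
    ft <- as_freq_table(data)
    only_icpt <- function(f) length(attr(terms(f), "term.labels")) == 0L
    if (!all(vapply(list(count, dispersion, zero), only_icpt, logical(1)))) {
      abort("A frequency table supports intercept-only formulas; expand to records for covariate models.")
    }
    data <- tibble::tibble(deaths = ft$deaths)
    weights <- ft$accidents
    response <- "deaths"
  }
  if (!response %in% names(data)) {
    abort(paste0("Outcome column `", response, "` not found in `data`."))
  }
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    abort("The outcome must be a nonnegative integer count.")
  }
  y <- as.numeric(y)
  n <- length(y)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0)) {
    abort("`weights` must be positive, finite, one per observation.")
  }
  data <- apply_coding(data, coding)
  ds <- list(
    y = y, w = w,
    X = part_matrix(count, data),
    S = part_matrix(dispersion, data),
    W = part_matrix(zero, data),
    coding = coding,
    formulas = list(count = count, dispersion = dispersion, zero = zero)
  )
  for (m in c("X", "S", "W")) {
    if (qr(ds[[m]])$rank < ncol(ds[[m]])) {
      abort(paste0("Design matrix `", m, "` is rank deficient; ",
                   "check for collinear or constant covariates."))
    }
  }
  class(ds) <- "design_set"
  ds
}
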