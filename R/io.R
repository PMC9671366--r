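#' Read record-level accident data from delimited text
#'
#' Expects a comma-separated UTF-8 file with a header row, one row per
#' accident.  Column names can be remapped via `col_map`, and integer
#' level codes translated to labels via `code_map` (the packaged default
#' maps code 1, 2, ... to the levels of [accident_coding()] in order,
#' which matches the published variable coding).  Unknown codes or
#' non-integer fatality counts raise an error naming the offending row.
#'
#' @param path File path.
#' @param coding Target level coding, see [accident_coding()].
#' @param col_map Optional named character vector mapping file column
#'   names to canonical names (`c(fatalities = "deaths", ...)` means the
#'   file's `fatalities` column becomes `deaths`).
#' @param code_map Optional named list: per variable, a named vector from
#'   file codes to level labels.  `NULL` applies the positional default
#'   only to integer-coded columns.
#' @return A typed records tibble.
#' @export
read_accidents <- function(path, coding = accident_coding(), col_map = NULL,
                           code_map = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (from in names(col_map)) {
      if (from %in% names(raw)) {
        names(raw)[names(raw) == from] <- col_map[[from]]
      }
    }
  }
  if (!"deaths" %in% names(raw)) {
    abort("No `deaths` column after applying `col_map`.")
  }
  y <- raw$deaths
  bad <- which(!is.finite(y) | y < 0 | y != floor(y))
  if (length(bad)) {
    abort(paste0("Non-integer or negative fatality count at row ", bad[1]))
  }
  raw$deaths <- as.integer(y)
  for (v in intersect(names(coding), names(raw))) {
    x <- raw[[v]]
    map <- if (!is.null(code_map) && v %in% names(code_map)) {
      code_map[[v]]
    } else if (is.numeric(x)) {
      setNames(coding[[v]], seq_along(coding[[v]]))  # positional default
    } else {
      NULL
    }
    if (!is.null(map)) {
      idx <- match(as.character(x), names(map))
      bad <- which(is.na(idx) & !is.na(x))
      if (length(bad)) {
        abort(paste0("Unmappable code ", encodeString(as.character(x[bad[1]]),
                                                      quote = '"'),
                     " for `", v, "` at row ", bad[1]))
      }
      raw[[v]] <- unname(map[idx])
    }
  }
  apply_coding(tibble::as_tibble(raw), coding)
}

#' Read a count frequency table from delimited text
#'
#' Two numeric columns (first: count value, second: frequency), a header
#' row, distinct nonnegative integer values.
#'
#' @param path File path.
#' @return A validated [freq_table()].
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2L) abort("Expected two columns: value, count.")
  freq_table(deaths = raw[[1]], accidents = raw[[2]])
}

#' Write accident records to delimited text
#'
#' Comma-separated, UTF-8, header row; the dialect [read_accidents()]
#' reads back.  Factors are written as labels, so a round trip reproduces
#' the records exactly.
#'
#' @param data Records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accidents <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Run the full fitting-and-testing pipeline
#'
#' Fits every requested model to the data, runs the applicable
#' likelihood-ratio and score tests, and (optionally) writes the
#' comparison report as a machine-readable CSV/JSON pair plus a
#' plain-text table.  Individual fit failures are reported per model and
#' do not stop the remaining models.
#'
#' @param data Records tibble, [freq_table()], or a path to either (a
#'   two-column file is read as a frequency table).
#' @param models Character vector of model kinds (default all four).
#' @param count,dispersion,zero Part formulas.
#' @param coding See [accident_coding()].
#' @param out_dir Optional output directory; created if missing.
#' @param control See [fit_control()].
#' @param quiet Suppress stage logging?
#' @return A [model_comparison()] object (with a `fits` attribute),
#'   invisibly if `out_dir` is given.
#' @examples
#' run_pipeline(thai_fatalities_2015(), models = c("poisson", "cmp"))
#' @export
run_pipeline <- function(data, models = c("poisson", "cmp", "zip", "zicmp"),
                         count = ~1, dispersion = ~1, zero = ~1,
                         coding = accident_coding(), out_dir = NULL,
                         control = fit_control(), quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  if (is.character(data)) {
    hdr <- names(readr::read_csv(data, n_max = 0, show_col_types = FALSE))
    data <- if (length(hdr) == 2L) read_frequency_table(data)
            else read_accidents(data, coding = coding)
  }
  n <- if (is_freq_table(data)) sum(data$accidents) else nrow(data)
  say("read: %s observations", format(n, big.mark = ","))

  models <- match.arg(models, c("poisson", "cmp", "zip", "zicmp"),
                      several.ok = TRUE)
  fits <- list()
  for (m in models) {
    say("fit: %s", m)
    f <- tryCatch(
      fit_fatality_model(data, model = m, count = count,
                         dispersion = dispersion, zero = zero,
                         coding = coding, control = control),
      error = function(e) {
        warn(paste0("Model `", m, "` failed to fit: ", conditionMessage(e)))
        NULL
      })
    if (!is.null(f)) fits[[m]] <- f
  }
  if (!length(fits)) abort("No model could be fitted.")
  say("test + compare: %d models", length(fits))
  cmpn <- model_comparison(fits)
  attr(cmpn, "fits") <- fits

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cmpn$models, file.path(out_dir, "models.csv"),
                     progress = FALSE)
    readr::write_csv(cmpn$coefficients, file.path(out_dir, "coefficients.csv"),
                     progress = FALSE)
    readr::write_csv(cmpn$tests, file.path(out_dir, "tests.csv"),
                     progress = FALSE)
    writeLines(format_comparison(cmpn), file.path(out_dir, "comparison.txt"))
    jsonlite::write_json(
      list(models = cmpn$models, tests = cmpn$tests),
      file.path(out_dir, "results.json"),
      dataframe = "rows", digits = NA, auto_unbox = TRUE
    )
    say("write: %s (%.1fs)", out_dir,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    return(invisible(cmpn))
  }
  cmpn
}
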