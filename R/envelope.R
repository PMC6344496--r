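#' Read raw age/performance records from CSV
#'
#' Expects a header with columns `age` and `value` and optionally
#' `subject_id` and `sex` (comma-separated, UTF-8, decimal point). Ages
#' are in the native discretisation unit of the series (years for humans,
#' months for horses and greyhounds, weeks for mice and mouse lemurs).
#'
#' @param path Path to the CSV file.
#' @param age_unit Native age unit: `"years"`, `"months"` or `"weeks"`.
#' @param value_unit Optional free-text unit label (e.g. `"m.s-1"`).
#' @return A tibble of records with attributes `age_unit` and `value_unit`.
#' @export
read_performance_csv <- function(path, age_unit = c("years", "months", "weeks"),
                                 value_unit = NA_character_) {
  age_unit <- match.arg(age_unit)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("Malformed CSV `", path, "`: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(df) == 0L) stop("Empty records file: ", path, call. = FALSE)
  if (!all(c("age", "value") %in% names(df))) {
    stop("CSV must have columns `age` and `value` (header required).",
         call. = FALSE)
  }
  bad <- which(!is.finite(df$age) | !is.finite(df$value) | df$age < 0)
  if (length(bad) > 0L) {
    stop("Invalid record at data line ", bad[1],
         ": age must be non-negative and value finite.", call. = FALSE)
  }
  as_performance_series(df, age_unit = age_unit, value_unit = value_unit)
}

# tag a records tibble with series metadata
as_performance_series <- function(df, age_unit, value_unit = NA_character_,
                                  species = NA_character_,
                                  trait = NA_character_) {
  out <- tibble::as_tibble(df)
  attr(out, "age_unit") <- age_unit
  attr(out, "value_unit") <- value_unit
  attr(out, "species") <- species
  attr(out, "trait") <- trait
  class(out) <- c("performance_series", class(out))
  out
}

#' @export
print.performance_series <- function(x, ...) {
  cat("Performance series:", nrow(x), "records, ages in",
      attr(x, "age_unit") %||% "unknown units", "\n")
  NextMethod()
}

WEEKS_PER_YEAR <- 52.1775  # weeks per year-of-life convention (~365.25/7)

#' Convert record ages to years
#'
#' Divides week ages by 52.1775 (365.25/7) and month ages by 12; years
#' pass through unchanged. Performance values are untouched.
#'
#' @param series A records data frame with an `age` column (e.g. from
#'   [read_performance_csv()] or [simulate_population()]).
#' @param age_unit Native unit of the `age` column; defaults to the
#'   series' `age_unit` attribute.
#' @param weeks_per_year Conversion constant, default 365.25/7.
#' @return The same records with `age` in years and the unit updated.
#' @export
#' @examples
#' df <- data.frame(age = c(18, 24), value = c(1, 2))
#' convert_ages(df, age_unit = "months")
convert_ages <- function(series, age_unit = NULL,
                         weeks_per_year = WEEKS_PER_YEAR) {
  stopifnot(is.data.frame(series), "age" %in% names(series))
  age_unit <- age_unit %||% attr(series, "age_unit")
  if (is.null(age_unit) || !age_unit %in% c("years", "months", "weeks")) {
    stop("Unknown age unit: ", deparse(age_unit),
         " (must be years, months or weeks).", call. = FALSE)
  }
  div <- switch(age_unit, years = 1, months = 12, weeks = weeks_per_year)
  out <- dplyr::mutate(tibble::as_tibble(series), age = .data$age / div)
  attr(out, "age_unit") <- "years"
  for (a in c("value_unit", "species", "trait")) {
    attr(out, a) <- attr(series, a)
  }
  if (inherits(series, "performance_series")) {
    class(out) <- unique(c("performance_series", class(out)))
  }
  out
}

#' Per-age top-performance envelope
#'
#' Reduces raw records to the fitting target: the best performance in each
#' age bin. Records are grouped into half-open bins
#' \eqn{[kw, (k+1)w)} of width `bin_width` in the native age unit, the
#' per-bin maximum value is kept, empty bins are omitted, and ages are
#' reported at bin centers converted to years.
#'
#' @param series A records data frame with columns `age` (native units)
#'   and `value`.
#' @param bin_width Bin width in native age units; default 1 (one year,
#'   month or week).
#' @param age_unit Native unit of `age`; defaults to the series attribute,
#'   falling back to `"years"`.
#' @param weeks_per_year Conversion constant for week ages.
#' @return A tibble of class `envelope_series` with columns `age` (bin
#'   center, years), `value` (bin maximum) and `n` (records per bin),
#'   sorted by age; attributes carry the source metadata.
#' @export
#' @examples
#' df <- data.frame(age = c(5, 5, 6), value = c(3, 4, 2))
#' top_envelope(df)
top_envelope <- function(series, bin_width = 1, age_unit = NULL,
                         weeks_per_year = WEEKS_PER_YEAR) {
  stopifnot(is.data.frame(series))
  if (!all(c("age", "value") %in% names(series))) {
    stop("`series` must have columns `age` and `value`.", call. = FALSE)
  }
  if (nrow(series) == 0L) stop("Empty series.", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("`bin_width` must be a single positive number.", call. = FALSE)
  }
  age_unit <- age_unit %||% attr(series, "age_unit") %||% "years"
  div <- switch(age_unit, years = 1, months = 12, weeks = weeks_per_year,
                stop("Unknown age unit: ", age_unit, call. = FALSE))
  env <- series |>
    tibble::as_tibble() |>
    dplyr::mutate(.bin = floor(.data$age / bin_width)) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(value = max(.data$value), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(age = (.data$.bin + 0.5) * bin_width / div) |>
    dplyr::arrange(.data$age) |>
    dplyr::select("age", "value", "n")
  as_envelope_series(env,
                     age_unit_native = age_unit,
                     bin_width = bin_width,
                     value_unit = attr(series, "value_unit"),
                     species = attr(series, "species"),
                     trait = attr(series, "trait"))
}

as_envelope_series <- function(df, age_unit_native = "years", bin_width = 1,
                               value_unit = NA_character_,
                               species = NA_character_,
                               trait = NA_character_) {
  out <- tibble::as_tibble(df)
  if (!"n" %in% names(out)) out$n <- 1L
  attr(out, "age_unit_native") <- age_unit_native
  attr(out, "bin_width") <- bin_width
  attr(out, "value_unit") <- value_unit
  attr(out, "species") <- species
  attr(out, "trait") <- trait
  class(out) <- unique(c("envelope_series", class(out)))
  out
}

#' @export
print.envelope_series <- function(x, ...) {
  cat("Top-performance envelope:", nrow(x), "age bins (ages in years)\n")
  NextMethod()
}

#' Upper concave hull of an envelope
#'
#' Optional post-processing that keeps only the points on the upper convex
#' hull of the (age, value) envelope, i.e. the concave majorant. The
#' default pipeline uses the raw per-bin maxima; this stricter geometric
#' reduction is provided for sensitivity analyses.
#'
#' @param env An `envelope_series` tibble from [top_envelope()].
#' @return The subset of envelope rows on the upper concave hull.
#' @export
upper_concave_hull <- function(env) {
  stopifnot(is.data.frame(env), all(c("age", "value") %in% names(env)))
  env <- dplyr::arrange(tibble::as_tibble(env), .data$age)
  n <- nrow(env)
  if (n <= 2L) return(env)
  # monotone-chain upper hull on (age, value)
  keep <- integer(0)
  for (i in seq_len(n)) {
    while (length(keep) >= 2L) {
      j <- keep[length(keep)]
      k <- keep[length(keep) - 1L]
      cross <- (env$age[j] - env$age[k]) * (env$value[i] - env$value[k]) -
        (env$value[j] - env$value[k]) * (env$age[i] - env$age[k])
      if (cross >= 0) keep <- keep[-length(keep)] else break
    }
    keep <- c(keep, i)
  }
  env[keep, ]
}

#' Plot an envelope series
#'
#' @param object An `envelope_series` tibble.
#' @param ... Unused.
#' @return A ggplot object showing top performance against age.
#' @method autoplot envelope_series
#' @export
autoplot.envelope_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Age (years)", y = "Top performance") +
    ggplot2::theme_minimal()
}
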