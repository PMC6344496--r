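#' Published parameter sets for the 17 age-performance series
#'
#' Returns the packaged table of fitted dimensionless shape parameters
#' (\eqn{\alpha_0^*}, \eqn{\alpha_r^*}, \eqn{\beta_r^*}, \eqn{t_d}) for
#' the 17 performance series spanning humans, mice, mouse lemurs,
#' greyhounds and thoroughbreds, together with the published peak ages
#' and growth time constants \eqn{1/\alpha_r}. A `peak_consistent` flag
#' marks rows whose published peak age is reproduced (within ±0.15 year)
#' by maximising the curve at the published parameters; a handful of
#' rows are internally inconsistent or unit-ambiguous (notably the
#' greyhound peak, printed in what appear to be different units than its
#' lifespan) and carry `peak_consistent = FALSE`.
#'
#' @return A tibble with one row per series: `name`, `alpha0_star`,
#'   `alphar_star`, `betar_star`, `td` (years), `peak_published` (years),
#'   `tau_published` (years), `age_unit` (native discretisation of the
#'   raw records), `value_unit`, `species`, `peak_computed`,
#'   `peak_consistent`.
#' @export
#' @examples
#' series_fixtures()
series_fixtures <- function() {
  path <- system.file("extdata", "series_parameters.csv", package = "imapr",
                      mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tab$peak_computed <- vapply(seq_len(nrow(tab)), function(i) {
    u <- peak_u(tab$alpha0_star[i], tab$alphar_star[i], tab$betar_star[i])
    as.numeric(u) * tab$td[i]
  }, numeric(1))
  tab$peak_consistent <- abs(tab$peak_computed - tab$peak_published) <= 0.15
  tab
}

#' Load one published series fixture by name
#'
#' @param name Series label, e.g. `"100 m"`, `"Chess"`, `"Mouse males"`;
#'   see [series_fixtures()] for the full list. Matching is
#'   case-insensitive.
#' @return A list with elements `name`, `shape` (an [imap_shape()] with
#'   `scale_inf = 1`; only the dimensionless shape was published),
#'   `peak_published` (years), `tau_published` (years), `age_unit`,
#'   `value_unit`, `species` and `peak_consistent`.
#' @export
#' @examples
#' fx <- load_fixture("100 m")
#' peak_age(fx$shape)
load_fixture <- function(name) {
  tab <- series_fixtures()
  i <- match(tolower(name), tolower(tab$name))
  if (is.na(i)) {
    stop("Unknown series `", name, "`. Valid names: ",
         paste(tab$name, collapse = ", "), ".", call. = FALSE)
  }
  row <- tab[i, ]
  list(
    name = row$name,
    shape = imap_shape(row$alpha0_star, row$alphar_star, row$betar_star,
                       td = row$td, scale_inf = 1),
    peak_published = row$peak_published,
    tau_published = row$tau_published,
    age_unit = row$age_unit,
    value_unit = row$value_unit,
    species = row$species,
    peak_consistent = row$peak_consistent
  )
}

#' Simulate a noisy top-performance envelope from a model shape
#'
#' Generates envelope values
#' \eqn{y_j = \mathrm{scale}_\infty \, x(t_j/t_d)(1 + \epsilon_j)} with
#' multiplicative Gaussian noise \eqn{\epsilon_j \sim N(0,
#' \mathrm{noise\_scale})}, truncated by redrawing so values stay
#' strictly positive. This is the quick generator for fitting tests; for
#' ranking-style cohort structure see [simulate_population()].
#'
#' @param shape An [imap_shape()] object (the ground truth).
#' @param ages Age grid in years; defaults to 100 ages evenly spanning 1%
#'   to 80% of the lifespan `td`, emulating the observed span of the
#'   collected series. Grid points at or beyond `td` produce clamped
#'   zeros and are flagged in the `past_td` column.
#' @param noise_scale Relative standard deviation of the multiplicative
#'   noise (default 0.01).
#' @param seed Integer seed; output is reproducible given the seed.
#' @return An `envelope_series` tibble with columns `age`, `value`, `n`
#'   and `past_td`.
#' @export
#' @examples
#' env <- simulate_envelope(load_fixture("100 m")$shape, seed = 42)
simulate_envelope <- function(shape, ages = NULL, noise_scale = 0.01,
                              seed = 1) {
  stopifnot(inherits(shape, "imap_shape"), noise_scale >= 0)
  ages <- ages %||% seq(0.01 * shape$td, 0.80 * shape$td, length.out = 100)
  check_ages(ages)
  curve <- as.numeric(imap_reduced(ages / shape$td, shape)) * shape$scale_inf
  past <- ages >= shape$td
  values <- withr::with_seed(seed, {
    v <- curve * (1 + stats::rnorm(length(ages), sd = noise_scale))
    # truncate at 0: redraw noise for non-positive values of live ages
    bad <- which(v <= 0 & !past)
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      v[bad] <- curve[bad] * (1 + stats::rnorm(length(bad), sd = noise_scale))
      bad <- which(v <= 0 & !past)
      guard <- guard + 1L
    }
    v[past] <- 0
    v
  })
  out <- as_envelope_series(
    tibble::tibble(age = ages, value = values, n = 1L, past_td = past)
  )
  attr(out, "seed") <- seed
  out
}

#' Simulate individual performance records below a model envelope
#'
#' Emulates ranking-style cohort data: for each age bin, `n_per_age`
#' individual records are drawn at
#' \eqn{y = \mathrm{curve}(t) (1 - |\delta|)} with
#' \eqn{\delta \sim N(0, \mathrm{noise\_scale})} — every individual
#' performs at or below the top-performer curve, and the per-bin maximum
#' converges to the curve as `n_per_age` grows.
#'
#' @inheritParams simulate_envelope
#' @param ages Age-bin centers in years; default as in
#'   [simulate_envelope()].
#' @param n_per_age Individuals per age bin (default 25).
#' @param noise_scale Relative scale of the performance deficit
#'   (default 0.05).
#' @return A `performance_series` tibble with columns `age`, `value`,
#'   `subject_id`, `sex` (ages in years).
#' @export
#' @examples
#' pop <- simulate_population(load_fixture("Chess")$shape,
#'                            n_per_age = 10, seed = 3)
#' top_envelope(pop)
simulate_population <- function(shape, ages = NULL, n_per_age = 25,
                                noise_scale = 0.05, seed = 1) {
  stopifnot(inherits(shape, "imap_shape"), noise_scale >= 0)
  if (!is.numeric(n_per_age) || n_per_age < 1) {
    stop("`n_per_age` must be at least 1.", call. = FALSE)
  }
  n_per_age <- as.integer(n_per_age)
  ages <- ages %||% seq(0.01 * shape$td, 0.80 * shape$td, length.out = 100)
  check_ages(ages)
  curve <- as.numeric(imap_reduced(ages / shape$td, shape)) * shape$scale_inf
  df <- withr::with_seed(seed, {
    purrr::map_dfr(seq_along(ages), function(j) {
      deficit <- abs(stats::rnorm(n_per_age, sd = noise_scale))
      tibble::tibble(
        age = ages[j],
        value = curve[j] * pmax(1 - deficit, 0),
        subject_id = sprintf("a%03d_i%04d", j, seq_len(n_per_age)),
        sex = NA_character_
      )
    })
  })
  out <- as_performance_series(df, age_unit = "years")
  attr(out, "seed") <- seed
  out
}
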