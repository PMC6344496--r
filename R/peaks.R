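#' Age of peak performance
#'
#' Locates the unique interior maximiser of the dimensionless curve
#' \eqn{x(u)} and returns it in years, \eqn{t_{peak} = u^* t_d}. Setting
#' \eqn{d \log x / du = 0} gives the stationarity condition
#' \deqn{\alpha_0^* e^{-\alpha_r^* u} =
#'       \frac{\beta_r^* e^{\beta_r^* (u - 1)}}{1 - e^{\beta_r^* (u - 1)}}}
#' whose left side decreases and right side increases on \eqn{(0, 1)}, so a
#' sign change brackets the unique root, solved to absolute tolerance
#' 1e-8 on \eqn{u}. When no sign change exists the curve is monotone on
#' \eqn{[0, 1]} and the boundary argmax is returned with a `degenerate`
#' attribute; if root-finding fails a dense-grid argmax is used instead.
#'
#' @param s An [imap_shape()] object.
#' @return Peak age in years, with attribute `u` (the normalised peak age)
#'   and, when no interior maximum exists, attribute `degenerate = TRUE`.
#' @seealso [normalized_peak()], [time_constant()]
#' @export
#' @examples
#' s <- imap_shape(34.26, 21.40, 2.19, td = 124.13)
#' peak_age(s)  # about 25 years
peak_age <- function(s) {
  stopifnot(inherits(s, "imap_shape"))
  u <- peak_u(s$alpha0_star, s$alphar_star, s$betar_star)
  out <- unname(u) * s$td
  attributes(out) <- attributes(u)
  attr(out, "u") <- unname(u)
  out
}

# normalised peak age u* in (0,1); attributes flag degenerate cases
peak_u <- function(a0s, ars, brs, tol = 1e-10) {
  # log-derivative of x(u): growth gain minus decline loss
  g <- function(u) {
    a0s * exp(-ars * u) + brs * exp(brs * (u - 1)) / expm1(brs * (u - 1))
  }
  lo <- 1e-12
  hi <- 1 - 1e-12
  glo <- g(lo)
  ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
    # monotone on [0,1]: boundary argmax (decreasing if g(0) < 0)
    u <- if (is.finite(glo) && glo <= 0) 0 else {
      grid <- seq(0, 1, length.out = 1e5)
      s <- imap_shape(a0s, ars, brs, td = 1)
      grid[which.max(imap_reduced(grid, s))]
    }
    attr(u, "degenerate") <- TRUE
    return(u)
  }
  root <- tryCatch(
    stats::uniroot(g, c(lo, hi), tol = tol)$root,
    error = function(e) NA_real_
  )
  if (is.na(root)) {
    # fallback: dense-grid maximisation of the curve itself
    grid <- seq(0, 1, length.out = 1e6)
    x <- imap_reduced_raw(grid, a0s, ars, brs)
    root <- grid[which.max(x)]
  }
  root
}

#' Normalised age of peak performance
#'
#' The peak age expressed as a fraction of the estimated lifespan,
#' \eqn{u^* = t_{peak}/t_d \in (0, 1)}. It depends only on the three
#' dimensionless shape parameters, not on \eqn{t_d} itself.
#'
#' @param s An [imap_shape()] object.
#' @return The normalised peak age (fraction of lifespan).
#' @export
#' @examples
#' s <- imap_shape(22.37, 25.09, 2.36, td = 185)
#' normalized_peak(s)  # about 0.1625
normalized_peak <- function(s) {
  stopifnot(inherits(s, "imap_shape"))
  u <- peak_u(s$alpha0_star, s$alphar_star, s$betar_star)
  out <- unname(u)
  if (isTRUE(attr(u, "degenerate"))) attr(out, "degenerate") <- TRUE
  out
}

#' Growth time constant
#'
#' The e-folding time of the declining growth rate,
#' \eqn{\tau = 1/\alpha_r = t_d/\alpha_r^*} (years), comparable to the
#' time constants of organismal growth curves.
#'
#' @param s An [imap_shape()] object.
#' @return \eqn{\tau} in years.
#' @export
#' @examples
#' time_constant(imap_shape(34.26, 21.40, 2.19, td = 124.13))  # 5.80
time_constant <- function(s) {
  stopifnot(inherits(s, "imap_shape"))
  s$td / s$alphar_star
}

#' Derived quantities for a table of model shapes
#'
#' Computes, for each row of a shape table, the age of peak performance,
#' the normalised peak (fraction of lifespan), the growth time constant
#' \eqn{\tau = t_d/\alpha_r^*} and the asymptotic population ratio
#' \eqn{N_\infty/N_0 = e^{\alpha_0^*/\alpha_r^*}}.
#'
#' @param shapes A data frame with columns `alpha0_star`, `alphar_star`,
#'   `betar_star`, `td` and optionally `name` — e.g. the output of
#'   [series_fixtures()].
#' @return A tibble with one row per input shape and columns `name` (if
#'   present), `peak_age`, `normalized_peak`, `tau`, `ninf_ratio`.
#' @export
#' @examples
#' peak_summary(series_fixtures())
peak_summary <- function(shapes) {
  stopifnot(is.data.frame(shapes))
  need <- c("alpha0_star", "alphar_star", "betar_star", "td")
  if (!all(need %in% names(shapes))) {
    stop("`shapes` must have columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  out <- purrr::pmap_dfr(
    shapes[need],
    function(alpha0_star, alphar_star, betar_star, td) {
      s <- imap_shape(alpha0_star, alphar_star, betar_star, td = td)
      u <- normalized_peak(s)
      tibble::tibble(
        peak_age = u * td,
        normalized_peak = as.numeric(u),
        tau = time_constant(s),
        ninf_ratio = exp(alpha0_star / alphar_star)
      )
    }
  )
  if ("name" %in% names(shapes)) {
    out <- dplyr::bind_cols(tibble::tibble(name = shapes$name), out)
  }
  out
}
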