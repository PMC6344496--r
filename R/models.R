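#' Moore double-exponential performance curve
#'
#' Evaluates \eqn{P(t) = a(1 - e^{-bt}) + c(1 - e^{dt})}. Performance is
#' non-negative by definition, so negative raw values (the decline term
#' eventually dominates) are clamped to zero by default; the returned
#' vector carries a logical `clamped` attribute marking where clamping
#' occurred. Fitting works on the unclamped values (`clamp = FALSE`).
#'
#' @param t Age(s) in years, non-negative.
#' @param p A [moore_params()] object.
#' @param clamp Clamp negative values to 0? Default `TRUE`.
#' @return Numeric vector of performance values with attribute `clamped`.
#' @export
#' @examples
#' p <- moore_params(a = 1, b = 1, c = 1, d = 0.1)
#' moore_performance(1, p)
moore_performance <- function(t, p, clamp = TRUE) {
  stopifnot(inherits(p, "moore_params"))
  check_ages(t)
  raw <- p$a * (-expm1(-p$b * t)) + p$c * (-expm1(p$d * t))
  finish_clamped(raw, clamp)
}

#' Siler total mortality hazard
#'
#' Evaluates \eqn{q(t) = a_1 e^{-b_1 t} + a_2 + a_3 e^{b_3 t}}: the sum of
#' immature, mature and senescent hazard components.
#'
#' @param t Age(s) in years, non-negative.
#' @param p A [siler_params()] object. The mature component `a2` may also
#'   be supplied per age (recycled against `t`) to support age-dependent
#'   substitutions such as [siler_equivalent_a2()].
#' @param a2 Optional numeric override of the mature hazard, possibly
#'   age-dependent (same length as `t` or length 1). Defaults to `p$a2`.
#' @return Numeric vector of hazard values.
#' @export
siler_hazard <- function(t, p, a2 = NULL) {
  stopifnot(inherits(p, "siler_params"))
  check_ages(t)
  if (is.null(a2)) a2 <- p$a2
  p$a1 * exp(-p$b1 * t) + a2 + p$a3 * exp(p$b3 * t)
}

#' Age-dependent mature hazard linking the Siler and Moore forms
#'
#' Replacing the constant mature hazard \eqn{a_2} of the Siler model by
#' \deqn{a_2(t) = a_1 + a_3 - 2 a_1 e^{-b_1 t} - 2 a_3 e^{b_3 t}}
#' turns the total hazard into the Moore double-exponential form
#' \eqn{a_1(1 - e^{-b_1 t}) + a_3(1 - e^{b_3 t})}, which is how the
#' mortality-hazard structure carries over to performance curves.
#'
#' @param t Age(s) in years, non-negative.
#' @param a1,b1 Immature hazard amplitude and decay rate.
#' @param a3,b3 Senescent hazard amplitude and growth rate.
#' @return Numeric vector \eqn{a_2(t)} (can be negative).
#' @export
siler_equivalent_a2 <- function(t, a1, b1, a3, b3) {
  check_ages(t)
  if (any(c(a1, b1, a3, b3) < 0)) {
    stop("Hazard parameters must be non-negative.", call. = FALSE)
  }
  a1 + a3 - 2 * a1 * exp(-b1 * t) - 2 * a3 * exp(b3 * t)
}

#' Declining cell-population growth rate
#'
#' \eqn{\alpha(t) = \alpha_0 e^{-\alpha_r t}}: replicative senescence makes
#' the per-capita growth rate decay exponentially, so the population
#' saturates (see [asymptotic_population()]).
#'
#' @param t Age(s) in years, non-negative.
#' @param alpha0 Initial growth rate (1/year), strictly positive.
#' @param alphar Strength of saturation (1/year), strictly positive.
#' @return Numeric vector of growth rates, strictly decreasing in `t`.
#' @export
imap_growth_rate <- function(t, alpha0, alphar) {
  check_ages(t)
  if (alpha0 <= 0 || alphar <= 0) {
    stop("`alpha0` and `alphar` must be strictly positive.", call. = FALSE)
  }
  alpha0 * exp(-alphar * t)
}

#' Declining cell functionality
#'
#' \eqn{\beta(t) = \beta_0 (1 - e^{\beta_r (t - t_d)})}: average cell
#' functionality erodes with age and reaches exactly zero at the time of
#' death \eqn{t_d}. Values beyond \eqn{t_d} are negative; clamping is left
#' to the performance level so that fitting can use the smooth form.
#'
#' @param t Age(s) in years, non-negative.
#' @param beta0 Baseline functionality, strictly positive.
#' @param betar Strength of the decline (1/year), strictly positive.
#' @param td Time of death (years), strictly positive.
#' @return Numeric vector of functionality values.
#' @export
imap_senescence <- function(t, beta0, betar, td) {
  check_ages(t)
  if (beta0 <= 0 || betar <= 0 || td <= 0) {
    stop("`beta0`, `betar` and `td` must be strictly positive.", call. = FALSE)
  }
  beta0 * (-expm1(betar * (t - td)))
}

#' Integrative age-performance curve (dimensional form)
#'
#' Evaluates
#' \deqn{P(t) = \mathrm{scale} \cdot e^{(\alpha_0/\alpha_r)(1 - e^{-\alpha_r t})}
#'       \cdot (1 - e^{\beta_r (t - t_d)})}
#' the product of saturating population growth and declining cell
#' functionality. \eqn{P(t_d) = 0}; beyond \eqn{t_d} the raw value is
#' negative and is clamped to zero by default (attribute `clamped`).
#'
#' @param t Age(s) in years, non-negative.
#' @param p An [imap_params()] object.
#' @param clamp Clamp negative values (ages past `td`) to 0? Default `TRUE`.
#' @return Numeric vector of performance values with attribute `clamped`.
#' @export
#' @examples
#' p <- imap_params(scale = 1, alpha0 = 0.276, alphar = 0.172,
#'                  betar = 0.0176, td = 124.13)
#' imap_performance(c(0, 25, 124.13), p)
imap_performance <- function(t, p, clamp = TRUE) {
  stopifnot(inherits(p, "imap_params"))
  check_ages(t)
  raw <- p$scale * exp((p$alpha0 / p$alphar) * (-expm1(-p$alphar * t))) *
    (-expm1(p$betar * (t - p$td)))
  finish_clamped(raw, clamp)
}

#' Dimensionless reduced performance curve
#'
#' Evaluates
#' \deqn{x(u) = e^{-(\alpha_0^*/\alpha_r^*) e^{-\alpha_r^* u}}
#'       (1 - e^{\beta_r^* (u - 1)})}
#' on normalised age \eqn{u = t/t_d \in [0, 1]}, with \eqn{x(1) = 0}. The
#' dimensional curve is recovered as
#' \eqn{P(t) = \mathrm{scale}_\infty \, x(t/t_d)}. Values at \eqn{u > 1}
#' are clamped to 0 by default (attribute `clamped`).
#'
#' @param u Normalised age(s), non-negative.
#' @param s An [imap_shape()] object.
#' @param clamp Clamp negative values (`u > 1`) to 0? Default `TRUE`.
#' @return Numeric vector of dimensionless performance values with
#'   attribute `clamped`.
#' @export
#' @examples
#' s <- imap_shape(50, 15, 10, td = 1)
#' imap_reduced(c(0, 0.5, 1), s)
imap_reduced <- function(u, s, clamp = TRUE) {
  stopifnot(inherits(s, "imap_shape"))
  if (!is.numeric(u) || any(!is.finite(u)) || any(u < 0)) {
    stop("Normalised age `u` must be finite and non-negative.", call. = FALSE)
  }
  raw <- imap_reduced_raw(u, s$alpha0_star, s$alphar_star, s$betar_star)
  finish_clamped(raw, clamp)
}

# unclamped reduced curve on bare parameters; the fitting workhorse
imap_reduced_raw <- function(u, a0s, ars, brs) {
  exp(-(a0s / ars) * exp(-ars * u)) * (-expm1(brs * (u - 1)))
}

#' Specification of one cell type for the multi-type performance model
#'
#' In the general model each non-interacting cell type grows as
#' \eqn{dN_i/dt = \alpha_i(t) N_i} and contributes
#' \eqn{\Phi_i \beta_i(t) N_i(t)} to the observed performance.
#'
#' @param phi Contribution per cell \eqn{\Phi_i} (performance units/cell).
#' @param n0 Initial population \eqn{N_i(0)}, non-negative.
#' @param growth_rate_fn Function of age returning \eqn{\alpha_i(t)} (1/year).
#' @param senescence_fn Function of age returning \eqn{\beta_i(t)}.
#' @return An object of class `cell_type`.
#' @seealso [multitype_performance()]
#' @export
cell_type <- function(phi, n0, growth_rate_fn, senescence_fn) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi)) {
    stop("`phi` must be a single finite number.", call. = FALSE)
  }
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0) || n0 < 0) {
    stop("`n0` must be a single non-negative number.", call. = FALSE)
  }
  stopifnot(is.function(growth_rate_fn), is.function(senescence_fn))
  structure(list(phi = phi, n0 = n0, growth_rate_fn = growth_rate_fn,
                 senescence_fn = senescence_fn),
            class = "cell_type")
}

#' Performance of a sum of non-interacting cell populations
#'
#' Integrates \eqn{dN_i/dt = \alpha_i(t) N_i(t)} for each type via the
#' closed form \eqn{N_i(t) = N_i(0) \exp(\int_0^t \alpha_i)} (the integral
#' evaluated by adaptive quadrature) and returns
#' \eqn{P(t) = \sum_i \Phi_i \beta_i(t) N_i(t)} on the age grid.
#'
#' @param t_grid Sorted, non-negative ages (years).
#' @param types Non-empty list of [cell_type()] objects.
#' @return A tibble with columns `age` and `performance`.
#' @export
#' @examples
#' ct <- cell_type(phi = 1, n0 = 100,
#'                 growth_rate_fn = function(t) rep(0.1, length(t)),
#'                 senescence_fn = function(t) rep(1, length(t)))
#' multitype_performance(0:5, list(ct))
multitype_performance <- function(t_grid, types) {
  check_ages(t_grid)
  if (is.unsorted(t_grid)) {
    stop("`t_grid` must be sorted in ascending order.", call. = FALSE)
  }
  if (!is.list(types) || length(types) == 0L) {
    stop("`types` must be a non-empty list of cell_type objects.", call. = FALSE)
  }
  if (inherits(types, "cell_type")) types <- list(types)
  perf <- rep(0, length(t_grid))
  for (ct in types) {
    stopifnot(inherits(ct, "cell_type"))
    # cumulative integral of alpha over consecutive grid intervals
    cumint <- numeric(length(t_grid))
    prev_t <- 0
    acc <- 0
    for (k in seq_along(t_grid)) {
      if (t_grid[k] > prev_t) {
        acc <- acc + stats::integrate(ct$growth_rate_fn, prev_t, t_grid[k],
                                      rel.tol = 1e-10, abs.tol = 1e-12)$value
      }
      cumint[k] <- acc
      prev_t <- t_grid[k]
    }
    n_t <- ct$n0 * exp(cumint)
    stopifnot(all(n_t >= 0))
    perf <- perf + ct$phi * ct$senescence_fn(t_grid) * n_t
  }
  tibble::tibble(age = t_grid, performance = perf)
}

# --- internal helpers -------------------------------------------------------

check_ages <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("Ages must be finite and non-negative.", call. = FALSE)
  }
  invisible(t)
}

finish_clamped <- function(raw, clamp) {
  clamped_at <- raw < 0
  out <- if (clamp) pmax(raw, 0) else raw
  attr(out, "clamped") <- clamped_at
  out
}
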