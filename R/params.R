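#' Parameter set for the Moore double-exponential performance curve
#'
#' The Moore curve describes the inverted-U age-performance pattern as the
#' sum of a saturating growth term and an accelerating decline term,
#' \eqn{P(t) = a(1 - e^{-bt}) + c(1 - e^{dt})}, with all four constants
#' strictly positive and no explicit time of death.
#'
#' @param a Amplitude of the growth term (performance units).
#' @param b Growth rate constant (1/year).
#' @param c Amplitude of the decline term (performance units).
#' @param d Decline rate constant (1/year).
#'
#' @return An object of class `moore_params`.
#' @seealso [moore_performance()]
#' @export
#' @examples
#' moore_params(a = 10, b = 0.3, c = 0.5, d = 0.05)
moore_params <- function(a, b, c, d) {
  p <- list(a = a, b = b, c = c, d = d)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("Moore parameter `", nm, "` must be a single strictly positive number.",
           call. = FALSE)
    }
  }
  structure(p, class = "moore_params")
}

#' Parameter set for the Siler mortality hazard
#'
#' The Siler model decomposes the total hazard into an exponentially
#' decaying immature component, a constant mature component and an
#' exponentially growing senescent component:
#' \eqn{q(t) = a_1 e^{-b_1 t} + a_2 + a_3 e^{b_3 t}}.
#'
#' @param a1 Immature hazard amplitude (1/year).
#' @param b1 Immature hazard decay rate (1/year).
#' @param a2 Constant mature hazard (1/year).
#' @param a3 Senescent hazard amplitude (1/year).
#' @param b3 Senescent hazard growth rate (1/year).
#'
#' @return An object of class `siler_params`.
#' @seealso [siler_hazard()], [siler_equivalent_a2()]
#' @export
siler_params <- function(a1, b1, a2, a3, b3) {
  p <- list(a1 = a1, b1 = b1, a2 = a2, a3 = a3, b3 = b3)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("Siler parameter `", nm, "` must be a single non-negative number.",
           call. = FALSE)
    }
  }
  structure(p, class = "siler_params")
}

#' Dimensional parameter set for the integrative age-performance model
#'
#' The integrative model multiplies a saturating cell-population growth
#' factor by a declining cell-functionality factor that reaches zero at an
#' explicit time of death:
#' \deqn{P(t) = \beta_0 N_0 \, e^{(\alpha_0/\alpha_r)(1 - e^{-\alpha_r t})}
#'       (1 - e^{\beta_r (t - t_d)})}
#' The product \eqn{\beta_0 N_0} (baseline functionality times baseline cell
#' count) enters only as an overall scale, so it is carried as a single
#' `scale` parameter. The age axis is anchored at \eqn{t_0 = 0}.
#'
#' @param scale Baseline scale \eqn{\beta_0 N_0} (performance units).
#' @param alpha0 Initial growth rate \eqn{\alpha_0} (1/year).
#' @param alphar Strength of growth saturation \eqn{\alpha_r} (1/year).
#' @param betar Strength of functionality decline \eqn{\beta_r} (1/year).
#' @param td Time of death \eqn{t_d} (years).
#'
#' @return An object of class `imap_params`.
#' @seealso [imap_performance()], [nondimensionalize()]
#' @export
#' @examples
#' imap_params(scale = 1, alpha0 = 0.276, alphar = 0.172,
#'             betar = 0.0176, td = 124.13)
imap_params <- function(scale, alpha0, alphar, betar, td) {
  p <- list(scale = scale, alpha0 = alpha0, alphar = alphar,
            betar = betar, td = td)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("Model parameter `", nm, "` must be a single strictly positive number.",
           call. = FALSE)
    }
  }
  structure(p, class = "imap_params")
}

#' Dimensionless shape parameters of the integrative model
#'
#' Rescaling age by the time of death (\eqn{u = t/t_d}) and the rates by
#' \eqn{t_d} reduces the model to a three-parameter dimensionless curve
#' \deqn{x(u) = e^{-(\alpha_0^*/\alpha_r^*) e^{-\alpha_r^* u}}
#'       (1 - e^{\beta_r^* (u - 1)})}
#' with \eqn{x(1) = 0}. `scale_inf` is the normalising constant
#' \eqn{\beta_0 N_\infty} that maps the dimensionless curve back to
#' performance units; `td` is retained for redimensionalisation.
#'
#' @param alpha0_star \eqn{\alpha_0^* = \alpha_0 t_d} (dimensionless).
#' @param alphar_star \eqn{\alpha_r^* = \alpha_r t_d} (dimensionless).
#' @param betar_star \eqn{\beta_r^* = \beta_r t_d} (dimensionless).
#' @param td Time of death (years).
#' @param scale_inf Normalising constant \eqn{\beta_0 N_\infty}
#'   (performance units). Defaults to 1 (pure shape).
#'
#' @return An object of class `imap_shape`.
#' @seealso [imap_reduced()], [peak_age()], [redimensionalize()]
#' @export
#' @examples
#' imap_shape(alpha0_star = 34.26, alphar_star = 21.40,
#'            betar_star = 2.19, td = 124.13)
imap_shape <- function(alpha0_star, alphar_star, betar_star, td,
                       scale_inf = 1) {
  p <- list(alpha0_star = alpha0_star, alphar_star = alphar_star,
            betar_star = betar_star, td = td, scale_inf = scale_inf)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("Shape parameter `", nm, "` must be a single strictly positive number.",
           call. = FALSE)
    }
  }
  structure(p, class = "imap_shape")
}

#' @export
print.moore_params <- function(x, ...) {
  cat("Moore curve parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.siler_params <- function(x, ...) {
  cat("Siler hazard parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.imap_params <- function(x, ...) {
  cat("Integrative age-performance model, dimensional parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.imap_shape <- function(x, ...) {
  cat("Integrative age-performance model, dimensionless shape:\n")
  print(unlist(x))
  invisible(x)
}

#' Convert dimensional model parameters to dimensionless shape
#'
#' Applies \eqn{\alpha_0^* = \alpha_0 t_d}, \eqn{\alpha_r^* = \alpha_r t_d},
#' \eqn{\beta_r^* = \beta_r t_d} and
#' \eqn{\mathrm{scale}_\infty = \beta_0 N_0 \, e^{\alpha_0^*/\alpha_r^*}}
#' (the asymptotic-population normalisation).
#'
#' @param p An [imap_params()] object.
#' @return An [imap_shape()] object.
#' @seealso [redimensionalize()]
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "imap_params"))
  a0s <- p$alpha0 * p$td
  ars <- p$alphar * p$td
  imap_shape(
    alpha0_star = a0s,
    alphar_star = ars,
    betar_star = p$betar * p$td,
    td = p$td,
    scale_inf = p$scale * exp(a0s / ars)
  )
}

#' Convert dimensionless shape back to dimensional parameters
#'
#' Inverse of [nondimensionalize()]; the roundtrip is an identity to
#' machine precision.
#'
#' @param s An [imap_shape()] object.
#' @return An [imap_params()] object.
#' @export
redimensionalize <- function(s) {
  stopifnot(inherits(s, "imap_shape"))
  imap_params(
    scale = s$scale_inf * exp(-s$alpha0_star / s$alphar_star),
    alpha0 = s$alpha0_star / s$td,
    alphar = s$alphar_star / s$td,
    betar = s$betar_star / s$td,
    td = s$td
  )
}

#' Asymptotic cell population under saturating growth
#'
#' With growth rate \eqn{\alpha(t) = \alpha_0 e^{-\alpha_r t}} the cell
#' population saturates at \eqn{N_\infty = N_0 e^{\alpha_0/\alpha_r}}.
#'
#' @param n0 Initial population size (cells), strictly positive.
#' @param alpha0 Initial growth rate (1/year).
#' @param alphar Strength of saturation (1/year).
#' @return The asymptotic population size; always at least `n0`.
#' @export
#' @examples
#' asymptotic_population(1e6, alpha0 = 2, alphar = 0.5)
asymptotic_population <- function(n0, alpha0, alphar) {
  if (!is.numeric(n0) || any(n0 <= 0)) {
    stop("`n0` must be strictly positive.", call. = FALSE)
  }
  if (alpha0 <= 0 || alphar <= 0) {
    stop("Growth rates `alpha0` and `alphar` must be strictly positive.",
         call. = FALSE)
  }
  n0 * exp(alpha0 / alphar)
}
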