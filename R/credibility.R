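#' Draw parameter vectors from a fit's multivariate-normal uncertainty
#'
#' Samples `n_draws` parameter vectors from the multivariate normal
#' centered at the estimates with the fitted covariance matrix. Draws
#' violating the positivity constraints of the model parameters are
#' rejected and redrawn so that exactly `n_draws` valid vectors are
#' returned; the rejection count is reported. If more than half of the
#' proposals are rejected the covariance is inconsistent with the
#' parameter domain and the sampler aborts.
#'
#' @param fit A `perf_fit` object with a positive semidefinite covariance.
#' @param n_draws Number of valid draws to return (default 1e5, matching
#'   the published Monte-Carlo design).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return A numeric matrix (`n_draws` rows, one column per parameter)
#'   with attributes `n_rejected` and `seed`.
#' @export
sample_parameters <- function(fit, n_draws = 1e5, seed = 1) {
  stopifnot(inherits(fit, "perf_fit"), n_draws >= 1)
  mu <- fit$par
  sigma <- fit$covariance
  if (any(!is.finite(sigma))) {
    stop("Fit covariance contains non-finite entries.", call. = FALSE)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("Covariance matrix is not positive semidefinite.", call. = FALSE)
  }
  withr::with_seed(seed, {
    kept <- matrix(numeric(0), ncol = length(mu))
    n_rejected <- 0L
    n_proposed <- 0L
    while (nrow(kept) < n_draws) {
      need <- n_draws - nrow(kept)
      batch <- MASS::mvrnorm(max(need, 2L), mu = mu, Sigma = sigma)
      if (is.null(dim(batch))) batch <- matrix(batch, nrow = 1)
      ok <- apply(batch, 1, function(r) all(r > 0))
      n_proposed <- n_proposed + nrow(batch)
      n_rejected <- n_rejected + sum(!ok)
      kept <- rbind(kept, batch[ok, , drop = FALSE])
      if (n_proposed >= 100L && n_rejected / n_proposed > 0.5) {
        stop("More than 50% of multivariate-normal draws violate positivity; ",
             "the covariance is inconsistent with the parameter domain.",
             call. = FALSE)
      }
    }
    kept <- kept[seq_len(n_draws), , drop = FALSE]
    colnames(kept) <- names(mu)
    attr(kept, "n_rejected") <- n_rejected
    attr(kept, "seed") <- seed
    kept
  })
}

#' Pointwise credibility envelope over Monte-Carlo curves
#'
#' Evaluates the model curve for every drawn parameter vector on an age
#' grid and returns the pointwise minimum and maximum over draws — the
#' envelope containing every iteration. Curves are clamped at zero
#' (performance is non-negative). A conventional quantile band is
#' available as an option.
#'
#' @param draws Parameter matrix from [sample_parameters()] (columns named
#'   as the fitted parameters).
#' @param model `"imap1"` or `"moore"`.
#' @param age_grid Non-empty numeric vector of ages (years).
#' @param type `"envelope"` (pointwise min/max over all draws, the
#'   default) or `"quantile"`.
#' @param level Coverage for `type = "quantile"` (default 0.95).
#' @return A tibble of class `credibility_envelope` with columns `age`,
#'   `lower`, `upper`; attributes `n_draws`, `n_rejected`, `seed`.
#' @export
credibility_envelope <- function(draws, model = c("imap1", "moore"), age_grid,
                                 type = c("envelope", "quantile"),
                                 level = 0.95) {
  model <- match.arg(model)
  type <- match.arg(type)
  if (length(age_grid) == 0L || !is.numeric(age_grid)) {
    stop("`age_grid` must be a non-empty numeric vector.", call. = FALSE)
  }
  draws <- as.matrix(draws)
  if (nrow(draws) < 1L) stop("Need at least one draw.", call. = FALSE)
  curves <- apply(draws, 1, function(par) {
    par <- stats::setNames(as.numeric(par), colnames(draws))
    eval_curve(model, par, age_grid)
  })
  curves <- matrix(curves, nrow = length(age_grid))  # ages x draws
  if (type == "envelope") {
    lower <- apply(curves, 1, min)
    upper <- apply(curves, 1, max)
  } else {
    a <- (1 - level) / 2
    qs <- apply(curves, 1, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    lower <- qs[1, ]
    upper <- qs[2, ]
  }
  out <- tibble::tibble(age = age_grid, lower = lower, upper = upper)
  attr(out, "n_draws") <- nrow(draws)
  attr(out, "n_rejected") <- attr(draws, "n_rejected") %||% NA_integer_
  attr(out, "seed") <- attr(draws, "seed") %||% NA_integer_
  attr(out, "model") <- model
  attr(out, "type") <- type
  class(out) <- unique(c("credibility_envelope", class(out)))
  out
}

# clamped model curve at a bare named parameter vector
eval_curve <- function(model, par, t) {
  if (model == "imap1") {
    raw <- par[["scale_inf"]] *
      imap_reduced_raw(t / par[["td"]], par[["alpha0_star"]],
                       par[["alphar_star"]], par[["betar_star"]])
  } else {
    raw <- par[["a"]] * (-expm1(-par[["b"]] * t)) +
      par[["c"]] * (-expm1(par[["d"]] * t))
  }
  pmax(raw, 0)
}

#' Monte-Carlo credibility envelope for a fitted curve
#'
#' Convenience wrapper: samples parameters from the fit's covariance
#' ([sample_parameters()]) and builds the pointwise envelope
#' ([credibility_envelope()]), adding the fitted curve itself.
#'
#' @inheritParams sample_parameters
#' @inheritParams credibility_envelope
#' @param age_grid Ages (years); defaults to 200 points spanning the
#'   fitted ages extended 15% beyond the largest one.
#' @return A `credibility_envelope` tibble with an extra `fitted` column.
#' @export
#' @examples
#' s <- load_fixture("100 m")$shape
#' env <- simulate_envelope(s, noise_scale = 0.01, seed = 1)
#' fit <- fit_imap(env)
#' band <- credibility_band(fit, n_draws = 200, seed = 7)
credibility_band <- function(fit, age_grid = NULL, n_draws = 1e5, seed = 1,
                             type = c("envelope", "quantile"), level = 0.95) {
  stopifnot(inherits(fit, "perf_fit"))
  age_grid <- age_grid %||%
    seq(min(fit$data$age), 1.15 * max(fit$data$age), length.out = 200)
  draws <- sample_parameters(fit, n_draws = n_draws, seed = seed)
  band <- credibility_envelope(draws, model = fit$model, age_grid = age_grid,
                               type = type, level = level)
  band$fitted <- predict(fit, age_grid)
  band
}

#' @export
print.credibility_envelope <- function(x, ...) {
  cat(sprintf("Credibility envelope (%s, %s): %d draws, %s rejected\n",
              attr(x, "model") %||% "?", attr(x, "type") %||% "envelope",
              attr(x, "n_draws") %||% NA,
              format(attr(x, "n_rejected") %||% NA)))
  NextMethod()
}

#' Plot a credibility envelope
#'
#' @param object A `credibility_envelope` tibble (ideally from
#'   [credibility_band()], which adds the fitted curve).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot credibility_envelope
#' @export
autoplot.credibility_envelope <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::labs(x = "Age (years)", y = "Performance") +
    ggplot2::theme_minimal()
  if ("fitted" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                                colour = "steelblue")
  }
  p
}
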