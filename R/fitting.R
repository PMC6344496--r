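#' Fit the integrative age-performance model to an envelope
#'
#' Minimises \eqn{\sum_j (y_j - \mathrm{scale}_\infty \, x(t_j/t_d))^2}
#' over \eqn{(\mathrm{scale}_\infty, \alpha_0^*, \alpha_r^*, \beta_r^*,
#' t_d)} by the Levenberg-Marquardt algorithm, in the dimensionless
#' parameterisation that conditions the search well. All parameters are
#' bounded positive and \eqn{t_d} is constrained above the largest
#' observed age. The covariance of the estimates is
#' \eqn{\hat\sigma^2 (J^\top J)^{-1}} from the Jacobian at the optimum.
#'
#' @param env An envelope data frame with columns `age` (years) and
#'   `value` (e.g. from [top_envelope()] or [simulate_envelope()]).
#' @param init Optional [imap_shape()] starting point. The default start
#'   places the shape parameters in the range typical of long-lived
#'   series (\eqn{\alpha_0^* = 30}, \eqn{\alpha_r^* = 20},
#'   \eqn{\beta_r^* = 3}) with \eqn{t_d = 1.2 \max(t)} and
#'   \eqn{\mathrm{scale}_\infty = 1.05 \max(y)}.
#' @param bounds Optional list with elements `lower` and `upper`, named
#'   vectors over `c(scale_inf, alpha0_star, alphar_star, betar_star, td)`.
#' @param weights Optional per-bin weights (e.g. the envelope's `n`
#'   column); default unweighted.
#' @param n_starts Number of jittered multi-starts (default 1, i.e. the
#'   single default start); the best optimum by residual sum of squares
#'   is kept. Jitter is deterministic given `seed`.
#' @param seed Seed for multi-start jitter.
#' @return A `perf_fit` object; see [tidy.perf_fit()] and
#'   [glance.perf_fit()].
#' @export
#' @examples
#' s <- load_fixture("100 m")$shape
#' env <- simulate_envelope(s, noise_scale = 0.01, seed = 1)
#' fit <- fit_imap(env)
#' glance(fit)
fit_imap <- function(env, init = NULL, bounds = NULL, weights = NULL,
                     n_starts = 1, seed = 1) {
  env <- check_envelope_for_fit(env, n_params = 5L)
  t <- env$age
  y <- env$value
  model_fn <- function(par, t) {
    par[["scale_inf"]] *
      imap_reduced_raw(t / par[["td"]], par[["alpha0_star"]],
                       par[["alphar_star"]], par[["betar_star"]])
  }
  start <- if (is.null(init)) {
    c(scale_inf = 1.05 * max(y), alpha0_star = 30, alphar_star = 20,
      betar_star = 3, td = 1.2 * max(t))
  } else {
    stopifnot(inherits(init, "imap_shape"))
    c(scale_inf = init$scale_inf, alpha0_star = init$alpha0_star,
      alphar_star = init$alphar_star, betar_star = init$betar_star,
      td = init$td)
  }
  lower <- c(scale_inf = 1e-6 * max(y), alpha0_star = 1e-6,
             alphar_star = 1e-6, betar_star = 1e-6,
             td = max(t) * (1 + 1e-6))
  upper <- c(scale_inf = 1e4 * max(y), alpha0_star = 1e4,
             alphar_star = 1e4, betar_star = 1e4, td = 50 * max(t))
  if (!is.null(bounds)) {
    lower[names(bounds$lower)] <- bounds$lower
    upper[names(bounds$upper)] <- bounds$upper
  }
  start <- pmin(pmax(start, lower), upper)
  res <- lm_multistart(model_fn, start, lower, upper, t, y, weights,
                       n_starts, seed)
  finish_fit(res, model = "imap1", env = env, model_fn = model_fn)
}

#' Fit the Moore double-exponential curve to an envelope
#'
#' Levenberg-Marquardt least squares for
#' \eqn{P(t) = a(1 - e^{-bt}) + c(1 - e^{dt})} with positivity bounds on
#' all four constants. The unclamped curve is used during optimisation.
#'
#' @inheritParams fit_imap
#' @param init Optional [moore_params()] starting point.
#' @return A `perf_fit` object.
#' @export
fit_moore <- function(env, init = NULL, bounds = NULL, weights = NULL,
                      n_starts = 1, seed = 1) {
  env <- check_envelope_for_fit(env, n_params = 4L)
  t <- env$age
  y <- env$value
  model_fn <- function(par, t) {
    par[["a"]] * (-expm1(-par[["b"]] * t)) +
      par[["c"]] * (-expm1(par[["d"]] * t))
  }
  t_at_max <- t[which.max(y)]
  start <- if (is.null(init)) {
    c(a = 1.2 * max(y), b = 3 / max(t_at_max, 1e-3),
      c = 0.05 * max(y), d = 1 / max(t))
  } else {
    stopifnot(inherits(init, "moore_params"))
    c(a = init$a, b = init$b, c = init$c, d = init$d)
  }
  lower <- c(a = 1e-9, b = 1e-9, c = 1e-9, d = 1e-9)
  upper <- c(a = 1e6 * max(y), b = 1e4, c = 1e6 * max(y), d = 1e4)
  if (!is.null(bounds)) {
    lower[names(bounds$lower)] <- bounds$lower
    upper[names(bounds$upper)] <- bounds$upper
  }
  start <- pmin(pmax(start, lower), upper)
  res <- lm_multistart(model_fn, start, lower, upper, t, y, weights,
                       n_starts, seed)
  finish_fit(res, model = "moore", env = env, model_fn = model_fn)
}

# shared Levenberg-Marquardt driver with optional jittered multi-start
lm_multistart <- function(model_fn, start, lower, upper, t, y, weights,
                          n_starts, seed) {
  w <- if (is.null(weights)) rep(1, length(y)) else {
    stopifnot(length(weights) == length(y), all(weights > 0))
    weights
  }
  sw <- sqrt(w)
  resid_fn <- function(par) sw * (y - model_fn(par, t))
  starts <- list(start)
  if (n_starts > 1) {
    jitters <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        start * exp(stats::rnorm(length(start), sd = 0.3))
      })
    })
    starts <- c(starts, lapply(jitters, function(s) {
      pmin(pmax(stats::setNames(s, names(start)), lower), upper)
    }))
  }
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) {
      best <- list(fit = fit, ss = ss, start = s0)
    }
  }
  if (is.null(best)) {
    stop("Levenberg-Marquardt optimisation failed from every start.",
         call. = FALSE)
  }
  c(best, list(t = t, y = y, w = w, resid_fn = resid_fn,
               lower = lower, upper = upper))
}

# assemble the perf_fit object: covariance, metrics, diagnostics
finish_fit <- function(res, model, env, model_fn) {
  fit <- res$fit
  par <- stats::setNames(as.numeric(fit$par), names(fit$par))
  fitted_vals <- model_fn(par, res$t)
  residuals <- res$y - fitted_vals
  n <- length(res$y)
  p <- length(par)
  converged <- fit$info %in% 1:4
  covariance <- fit_covariance(model_fn, par, res$t, res$w, residuals, n, p)
  metrics <- goodness_of_fit(res$y, fitted_vals, n_params = p)
  structure(
    list(
      model = model,
      par = par,
      estimates = if (model == "imap1") {
        imap_shape(par[["alpha0_star"]], par[["alphar_star"]],
                   par[["betar_star"]], td = par[["td"]],
                   scale_inf = par[["scale_inf"]])
      } else {
        moore_params(par[["a"]], par[["b"]], par[["c"]], par[["d"]])
      },
      covariance = covariance,
      fitted = fitted_vals,
      residuals = residuals,
      data = tibble::tibble(age = res$t, value = res$y),
      metrics = metrics,
      converged = converged,
      n_obs = n,
      message = fit$message,
      niter = fit$niter
    ),
    class = "perf_fit"
  )
}

# sigma^2 (J'J)^-1 with a central-difference Jacobian of the model curve
fit_covariance <- function(model_fn, par, t, w, residuals, n, p) {
  if (n <= p) return(matrix(NA_real_, p, p, dimnames = list(names(par), names(par))))
  J <- matrix(0, nrow = n, ncol = p)
  h <- pmax(abs(par), 1e-4) * 1e-6
  for (k in seq_len(p)) {
    up <- par; up[k] <- up[k] + h[k]
    dn <- par; dn[k] <- dn[k] - h[k]
    J[, k] <- sqrt(w) * (model_fn(up, t) - model_fn(dn, t)) / (2 * h[k])
  }
  sigma2 <- sum(w * residuals^2) / (n - p)
  jtj <- crossprod(J)
  vc <- tryCatch(sigma2 * solve(jtj), error = function(e) sigma2 * MASS::ginv(jtj))
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(names(par), names(par))
  vc
}

check_envelope_for_fit <- function(env, n_params) {
  stopifnot(is.data.frame(env))
  if (!all(c("age", "value") %in% names(env))) {
    stop("Envelope must have columns `age` and `value`.", call. = FALSE)
  }
  env <- dplyr::arrange(tibble::as_tibble(env), .data$age)
  if (nrow(env) < n_params + 1L) {
    stop("Under-determined fit: need at least ", n_params + 1L,
         " envelope points, got ", nrow(env), ".", call. = FALSE)
  }
  if (stats::var(env$value) == 0) {
    stop("Degenerate envelope: all values identical.", call. = FALSE)
  }
  env
}

#' Goodness-of-fit metrics for a fitted curve
#'
#' Computes \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, the adjusted
#' \eqn{R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)}, \eqn{RMSE = \sqrt{SS_{res}/n}}
#' and the small-sample corrected Akaike criterion
#' \eqn{AICc = n \ln(SS_{res}/n) + 2k + 2k(k+1)/(n-k-1)} where
#' \eqn{k = p + 1} counts the fitted curve parameters plus the error
#' variance.
#'
#' @param observed,fitted Numeric vectors of equal length.
#' @param n_params Number of fitted curve parameters \eqn{p}.
#' @return A list with elements `r2`, `adj_r2`, `rmse`, `aicc`.
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3, 4, 5), c(1.1, 1.9, 3, 4.2, 4.9), n_params = 1)
goodness_of_fit <- function(observed, fitted, n_params) {
  stopifnot(length(observed) == length(fitted), n_params >= 0)
  n <- length(observed)
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("Zero total variance: R-squared undefined.", call. = FALSE)
  }
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- if (n - n_params - 1 > 0) {
    1 - (1 - r2) * (n - 1) / (n - n_params - 1)
  } else {
    NA_real_
  }
  k <- n_params + 1  # + error variance
  aicc <- if (n - k - 1 > 0 && ss_res > 0) {
    n * log(ss_res / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  } else if (n - k - 1 > 0) {
    -Inf
  } else {
    NA_real_
  }
  list(r2 = r2, adj_r2 = adj_r2, rmse = sqrt(ss_res / n), aicc = aicc)
}

#' Dynamic time warping distance between two curves
#'
#' Classic dynamic-programming DTW with absolute-difference local cost,
#' symmetric steps (match, insert, delete), no warping window and no
#' slope constraint; returns the accumulated cost of the optimal
#' alignment path.
#'
#' @param a,b Non-empty numeric vectors (curves sampled on grids).
#' @return The DTW distance (non-negative; 0 for identical sequences).
#' @export
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))  # 1
dtw_distance <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) > 0, length(b) > 0)
  n <- length(a)
  m <- length(b)
  prev <- rep(Inf, m)
  for (i in seq_len(n)) {
    cur <- rep(Inf, m)
    cost_row <- abs(a[i] - b)
    for (j in seq_len(m)) {
      best_prev <- if (i == 1 && j == 1) {
        0
      } else {
        min(if (i > 1) prev[j] else Inf,
            if (j > 1) cur[j - 1] else Inf,
            if (i > 1 && j > 1) prev[j - 1] else Inf)
      }
      cur[j] <- cost_row[j] + best_prev
    }
    prev <- cur
  }
  prev[m]
}

#' Compare a Moore fit and an integrative-model fit on the same envelope
#'
#' Assembles both models' goodness-of-fit metrics, the AICc difference
#' (Moore minus integrative), the DTW distance between the two fitted
#' curves on a common age grid, and the AICc-preferred model.
#'
#' @param fit_m A `perf_fit` from [fit_moore()].
#' @param fit_i A `perf_fit` from [fit_imap()].
#' @param grid Optional common age grid (years); defaults to the fitted
#'   ages.
#' @return A `model_comparison` object (list) with a tibble of per-model
#'   metrics, `delta_aicc`, `dtw_distance` and `preferred_model`.
#' @export
compare_models <- function(fit_m, fit_i, grid = NULL) {
  stopifnot(inherits(fit_m, "perf_fit"), inherits(fit_i, "perf_fit"))
  if (fit_m$model != "moore" || fit_i$model != "imap1") {
    stop("`fit_m` must be a Moore fit and `fit_i` an integrative-model fit.",
         call. = FALSE)
  }
  if (nrow(fit_m$data) != nrow(fit_i$data) ||
      any(abs(fit_m$data$age - fit_i$data$age) > 1e-12) ||
      any(abs(fit_m$data$value - fit_i$data$value) > 1e-12)) {
    stop("The two fits were not computed on the same envelope.", call. = FALSE)
  }
  grid <- grid %||% fit_m$data$age
  cm <- predict(fit_m, grid)
  ci <- predict(fit_i, grid)
  metrics <- dplyr::bind_rows(
    tibble::tibble(model = "moore", !!!fit_m$metrics),
    tibble::tibble(model = "imap1", !!!fit_i$metrics)
  )
  delta <- fit_m$metrics$aicc - fit_i$metrics$aicc
  structure(
    list(
      metrics = metrics,
      delta_aicc = delta,
      dtw_distance = dtw_distance(cm, ci),
      preferred_model = if (fit_i$metrics$aicc <= fit_m$metrics$aicc) "imap1" else "moore",
      grid = grid
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (top-performance envelope)\n")
  print(x$metrics)
  cat(sprintf("delta AICc (Moore - integrative): %.3f\n", x$delta_aicc))
  cat(sprintf("DTW distance between fitted curves: %.4g\n", x$dtw_distance))
  cat("Preferred model by AICc:", x$preferred_model, "\n")
  invisible(x)
}

#' Predict from a fitted performance curve
#'
#' @param object A `perf_fit` object.
#' @param newdata Ages (years) at which to evaluate the fitted curve;
#'   either a numeric vector or a data frame with an `age` column.
#'   Defaults to the fitted ages.
#' @param clamp Clamp negative predictions to 0? Default `TRUE`.
#' @param ... Unused.
#' @return Numeric vector of predicted performance values.
#' @export
predict.perf_fit <- function(object, newdata = NULL, clamp = TRUE, ...) {
  t <- if (is.null(newdata)) {
    object$data$age
  } else if (is.data.frame(newdata)) {
    newdata$age
  } else {
    newdata
  }
  out <- if (object$model == "imap1") {
    imap_performance(t, redimensionalize(object$estimates), clamp = clamp)
  } else {
    moore_performance(t, object$estimates, clamp = clamp)
  }
  as.numeric(out)
}

#' @export
print.perf_fit <- function(x, ...) {
  label <- if (x$model == "imap1") "integrative age-performance model" else "Moore curve"
  cat("Nonlinear least-squares fit:", label, "\n")
  cat("  n =", x$n_obs, "| converged:", x$converged, "\n")
  cat("  estimates:\n")
  print(x$par)
  cat(sprintf("  adj R2 = %.4f, RMSE = %.4g, AICc = %.2f\n",
              x$metrics$adj_r2, x$metrics$rmse, x$metrics$aicc))
  invisible(x)
}

#' Tidy a fitted performance curve
#'
#' @param x A `perf_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy perf_fit
#' @export
tidy.perf_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$covariance), 0))
  tibble::tibble(term = names(x$par), estimate = as.numeric(x$par),
                 std.error = as.numeric(se))
}

#' One-row summary of a fitted performance curve
#'
#' For integrative-model fits the derived quantities (peak age,
#' normalised peak, time constant) are included.
#'
#' @param x A `perf_fit` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance perf_fit
#' @export
glance.perf_fit <- function(x, ...) {
  out <- tibble::tibble(
    model = x$model,
    n_obs = x$n_obs,
    r2 = x$metrics$r2,
    adj_r2 = x$metrics$adj_r2,
    rmse = x$metrics$rmse,
    aicc = x$metrics$aicc,
    converged = x$converged
  )
  if (x$model == "imap1") {
    s <- x$estimates
    out$peak_age <- as.numeric(peak_age(s))
    out$normalized_peak <- as.numeric(normalized_peak(s))
    out$tau <- time_constant(s)
    out$td <- s$td
  }
  out
}

#' Plot a fitted performance curve over its envelope
#'
#' @param object A `perf_fit` object.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perf_fit
#' @export
autoplot.perf_fit <- function(object, n_grid = 400, ...) {
  grid <- seq(min(object$data$age), max(object$data$age), length.out = n_grid)
  curve <- tibble::tibble(age = grid, value = predict(object, grid))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "Age (years)", y = "Top performance",
                  title = paste("Fitted model:", object$model)) +
    ggplot2::theme_minimal()
}
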