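test_that("noise-free data generated from a known shape is recovered", {
  truth <- load_fixture("100 m")$shape
  env <- simulate_envelope(truth, ages = 1:100, noise_scale = 0, seed = 1)
  fit <- fit_imap(env)
  expect_true(fit$converged)
  est <- fit$estimates
  for (nm in c("alpha0_star", "alphar_star", "betar_star", "td", "scale_inf")) {
    expect_equal(est[[nm]], truth[[nm]], tolerance = 1e-3, label = nm)
  }
  expect_lt(fit$metrics$rmse, 1e-6)
})

test_that("noise-free Moore data is recovered by the Moore fit", {
  truth <- moore_params(a = 12, b = 0.25, c = 0.9, d = 0.035)
  t <- 1:80
  env <- tibble::tibble(age = t,
                        value = as.numeric(moore_performance(t, truth,
                                                             clamp = FALSE)))
  fit <- fit_moore(env, n_starts = 8, seed = 2)
  expect_true(fit$converged)
  for (nm in c("a", "b", "c", "d")) {
    expect_equal(fit$estimates[[nm]], truth[[nm]], tolerance = 1e-3,
                 label = nm)
  }
})

test_that("under-determined or degenerate envelopes are rejected", {
  expect_error(fit_imap(data.frame(age = c(1, 2), value = c(1, 2))),
               "Under-determined")
  expect_error(fit_moore(data.frame(age = 1:10, value = rep(2, 10))),
               "Degenerate")
})

test_that("goodness-of-fit metrics follow their formulas", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4), n_params = 1)
  expect_equal(g$r2, 0.5)
  expect_equal(g$rmse, sqrt(1 / 3), tolerance = 1e-10)

  perfect <- goodness_of_fit(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6), 2)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)

  # adjusted R2 never exceeds R2
  set.seed(8)
  for (i in 1:20) {
    y <- rnorm(15)
    f <- y + rnorm(15, sd = 0.3)
    g <- goodness_of_fit(y, f, n_params = sample(1:5, 1))
    expect_lte(g$adj_r2, g$r2)
  }
  expect_error(goodness_of_fit(rep(1, 5), rep(1, 5), 1), "variance")
})

test_that("dynamic time warping matches enumeration and its properties", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(5, 2), 3)
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2)), 1)

  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(2:15, 1))
    b <- rnorm(sample(2:15, 1))
    d_ab <- dtw_distance(a, b)
    expect_gte(d_ab, 0)
    expect_equal(d_ab, dtw_distance(b, a))
    if (length(a) == length(b)) {
      expect_lte(d_ab, sum(abs(a - b)) + 1e-12)
    }
  }
})

test_that("model comparison prefers the generating model on its own data", {
  truth <- load_fixture("100 m")$shape
  env <- simulate_envelope(truth, ages = 1:100, noise_scale = 0.01, seed = 4)
  fm <- fit_moore(env, n_starts = 4, seed = 4)
  fi <- fit_imap(env)
  cmp <- compare_models(fm, fi)
  expect_equal(cmp$preferred_model, "imap1")
  expect_gt(cmp$delta_aicc, 0)
  expect_gte(cmp$dtw_distance, 0)

  other <- simulate_envelope(truth, ages = 1:100, noise_scale = 0.01, seed = 5)
  fm2 <- fit_moore(other, n_starts = 4, seed = 4)
  expect_error(compare_models(fm2, fi), "same envelope")
})

test_that("fits are invariant to performance-unit rescaling", {
  truth <- load_fixture("Chess")$shape
  env <- simulate_envelope(truth, ages = 2:110, noise_scale = 0.02, seed = 6)
  f1 <- fit_imap(env)
  env_scaled <- env
  env_scaled$value <- env$value * 1000
  f2 <- fit_imap(env_scaled)
  for (nm in c("alpha0_star", "alphar_star", "betar_star", "td")) {
    expect_equal(f2$estimates[[nm]], f1$estimates[[nm]], tolerance = 1e-6,
                 label = nm)
  }
  expect_equal(f2$estimates$scale_inf, 1000 * f1$estimates$scale_inf,
               tolerance = 1e-6)
})

test_that("the optimum never exceeds the starting objective", {
  truth <- load_fixture("Marathon")$shape
  env <- simulate_envelope(truth, noise_scale = 0.03, seed = 7)
  init <- imap_shape(20, 15, 2, td = 1.3 * max(env$age), scale_inf = max(env$value))
  fit <- fit_imap(env, init = init)
  obj_init <- sum((env$value - init$scale_inf *
                     as.numeric(imap_reduced(env$age / init$td, init,
                                             clamp = FALSE)))^2)
  obj_opt <- sum(fit$residuals^2)
  expect_lte(obj_opt, obj_init + 1e-12)
})

test_that("parameter recovery bias shrinks as noise decreases", {
  truth <- load_fixture("100 m")$shape
  err_at <- function(noise) {
    errs <- vapply(1:8, function(k) {
      env <- simulate_envelope(truth, ages = 1:100, noise_scale = noise,
                               seed = 100 + k)
      fit <- fit_imap(env)
      mean(abs(c(fit$estimates$alphar_star / truth$alphar_star - 1,
                 fit$estimates$betar_star / truth$betar_star - 1,
                 fit$estimates$td / truth$td - 1)))
    }, numeric(1))
    stats::median(errs)
  }
  e <- vapply(c(0.002, 0.01, 0.05), err_at, numeric(1))
  expect_lt(e[1], e[3])
  expect_lt(e[1], 0.02)
})

test_that("tidy and glance expose estimates, uncertainty and derived peaks", {
  truth <- load_fixture("400 m")$shape
  env <- simulate_envelope(truth, noise_scale = 0.01, seed = 11)
  fit <- fit_imap(env)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(nrow(td), 5)
  expect_true(all(td$std.error >= 0))
  gl <- glance(fit)
  expect_equal(gl$model, "imap1")
  expect_equal(gl$peak_age, as.numeric(peak_age(fit$estimates)),
               tolerance = 1e-10)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
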