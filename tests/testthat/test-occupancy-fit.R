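test_that("incidence prediction: closed-form values, saturation, monotonicity", {
  expect_equal(predict_incidence(1, 0, 0, 5.47, 0.4), 0)
  expect_equal(predict_incidence(1, 0, 1, 5.47, 0.4), 1 / 6.47,
               tolerance = 1e-10)
  expect_equal(predict_incidence(1, 0, 1e12, 5.47, 0.4), 1, tolerance = 1e-9)

  base <- predict_incidence(2, 0.1, 3, 4, 0.5, 1.5)
  expect_gt(predict_incidence(2.5, 0.1, 3, 4, 0.5, 1.5), base)
  expect_gt(predict_incidence(2, 0.2, 3, 4, 0.5, 1.5), base)
  expect_gt(predict_incidence(2, 0.1, 4, 4, 0.5, 1.5), base)
  expect_lt(predict_incidence(2, 0.1, 3, 5, 0.5, 1.5), base)
})

test_that("stage-1 fit recovers noiseless model parameters to 1e-3", {
  gl <- generate_landscape(synth_config(n_patches = 150, n_networks = 2),
                           seed = 5)
  x <- gl$landscape
  p <- equilibrium_incidence(x, rep(0, 150), delta = 3.9, xexp = 0.5, y = 0)
  inc <- data.frame(patch_id = x$patches$id, p_bar = p,
                    n_observed_years = 22, defined = TRUE)
  f1 <- fit_stage1(inc, x, gl$assignment, networks = c(1, 2))
  expect_equal(unname(f1$estimate["delta"]), 3.9, tolerance = 1e-3)
  expect_equal(unname(f1$estimate["x"]), 0.5, tolerance = 1e-3)
  expect_equal(f1$stage, 1)
  expect_false(f1$boundary)
})

test_that("stage-2 frees the quality effect and nests stage 1", {
  gl <- generate_landscape(synth_config(n_patches = 150, n_networks = 2),
                           seed = 6)
  x <- gl$landscape
  q <- quality_index(x)
  p <- equilibrium_incidence(x, q, delta = 5.5, xexp = 0.43, y = 1.7)
  inc <- data.frame(patch_id = x$patches$id, p_bar = p,
                    n_observed_years = 22, defined = TRUE)
  f2 <- fit_stage2(inc, x, gl$assignment, q, networks = c(1, 2))
  expect_equal(unname(f2$estimate), c(5.5, 0.43, 1.7), tolerance = 1e-3)
  expect_true(all(f2$ci95[, "lower"] <= f2$estimate &
                    f2$estimate <= f2$ci95[, "upper"]))

  # data generated without a quality effect: stage 2 finds y ~ 0 and the
  # stage-1 parameters
  p0 <- equilibrium_incidence(x, q, delta = 3.9, xexp = 0.5, y = 0)
  inc0 <- data.frame(patch_id = x$patches$id, p_bar = p0,
                     n_observed_years = 22, defined = TRUE)
  f20 <- fit_stage2(inc0, x, gl$assignment, q, networks = c(1, 2))
  f10 <- fit_stage1(inc0, x, gl$assignment, networks = c(1, 2))
  expect_equal(unname(f20$estimate["y"]), 0, tolerance = 1e-3)
  expect_equal(f20$estimate[c("delta", "x")], f10$estimate[c("delta", "x")],
               tolerance = 1e-3)
})

test_that("network selection filter and degenerate inputs are handled", {
  gl <- generate_landscape(synth_config(n_patches = 60, n_networks = 3),
                           seed = 7)
  x <- gl$landscape
  inc <- data.frame(patch_id = x$patches$id, p_bar = 0.02,
                    n_observed_years = 22, defined = TRUE)
  # 20-patch networks never pass the default >50 patch filter
  expect_error(fit_stage1(inc, x, gl$assignment), "selection filter")

  # saturated occupancy drives delta to the boundary
  inc$p_bar <- 1
  expect_warning(
    fb <- fit_stage1(inc, x, gl$assignment, networks = 1:3), "boundary")
  expect_true(fb$boundary)
})

test_that("quality logistic regression recovers planted coefficients", {
  set.seed(42)
  n <- 2000
  df <- data.frame(id = sprintf("q%04d", 1:n), x_km = runif(n, 0, 30),
                   y_km = runif(n, 0, 30), area_ha = rlnorm(n, log(0.06), 1),
                   host_plantago = sample(0:3, n, TRUE),
                   host_veronica = sample(0:3, n, TRUE),
                   pct_dry = runif(n), pct_low = runif(n),
                   pct_grazed = runif(n))
  x <- landscape(df)
  pred <- runif(n, 0.05, 0.95)
  hostv <- pmax(df$host_plantago, df$host_veronica)
  truth <- c(-3, 4, 1.0, 3.0, -1.0, 0.5)   # int, pred, host, dry, grazed, low
  lp <- truth[1] + truth[2] * pred + truth[3] * hostv + truth[4] * df$pct_dry +
    truth[5] * df$pct_grazed + truth[6] * df$pct_low
  nyr <- 22
  inc <- data.frame(patch_id = df$id,
                    p_bar = rbinom(n, nyr, plogis(lp)) / nyr,
                    n_observed_years = nyr, defined = TRUE)
  fit <- fit_quality_logistic(inc, pred, x)
  co <- fit$coefficients
  expect_equal(rownames(co),
               c("(Intercept)", "pred", "host", "dry", "grazed", "low"))
  for (i in seq_along(truth))
    expect_lt(abs(co[i, "Estimate"] - truth[i]) / co[i, "Std. Error"], 2.5)
  expect_gt(fit$pseudo_r2, 0.5)
  expect_false(fit$separation)

  # constant quality columns collapse to intercept + prediction
  df0 <- df
  df0$pct_dry <- 0; df0$pct_low <- 0; df0$pct_grazed <- 0
  df0$host_plantago <- 1; df0$host_veronica <- 1
  expect_warning(
    f0 <- fit_quality_logistic(inc, pred, landscape(df0)), "zero-variance")
  expect_equal(rownames(f0$coefficients), c("(Intercept)", "pred"))
})

test_that("network fit statistics: perfect fit, degenerate variance, small n", {
  lam <- c(6, 7, 9, 12, 4, 3)
  delta <- 5.47
  nt <- data.frame(lambda_M = lam,
                   mean_p_lambda = pmax(0, 1 - delta / lam))
  st <- network_fit_statistics(nt, delta)
  expect_equal(st$r_viable, 1, tolerance = 1e-12)
  expect_equal(st$n_viable, 4L)
  expect_gt(st$R2_all, 0.5)

  nt$mean_p_lambda <- 0.3
  expect_warning(st0 <- network_fit_statistics(nt, delta), "variance")
  expect_true(is.na(st0$r_viable))

  nt2 <- data.frame(lambda_M = c(6, 7, 1), mean_p_lambda = c(0.1, 0.2, 0))
  expect_true(is.na(network_fit_statistics(nt2, delta)$r_viable))
})
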