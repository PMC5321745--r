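test_that("dispersal kernel matches direct evaluation", {
  expect_equal(dispersal_kernel(0, 1), 1)
  expect_equal(dispersal_kernel(1, 1), 0.367879, tolerance = 1e-5)
  expect_equal(dispersal_kernel(2, 0.93), 0.155673, tolerance = 1e-5)
  expect_error(dispersal_kernel(-1, 1), "negative")
})

test_that("patch connectivity: direct values, linearity, area-free term", {
  x2 <- mk_line(c(0, 1))
  pars <- spom_params(im = 0.7, em = 0.3, alpha = 1)
  cn <- patch_connectivity(x2, c(0, 1), pars)
  expect_equal(unname(cn$S["p01"]), exp(-1), tolerance = 1e-12)
  expect_equal(cn$R, cn$S)                    # unit areas neutralize exponents

  expect_equal(unname(patch_connectivity(x2, c(0, 0), pars)$S), c(0, 0))

  x3 <- mk_random_landscape(15, seed = 3)
  p <- runif(15, 0, 0.5)
  c1 <- patch_connectivity(x3, p, pars)
  c2 <- patch_connectivity(x3, 2 * p, pars)
  expect_equal(c2$S, 2 * c1$S)
  expect_equal(c1$R, c1$S / x3$patches$area_ha^pars$im)
})

test_that("landscape matrix M has the plug-in form and power-law area scaling", {
  p1 <- mk_line(0)
  cr1 <- metapop_capacity(build_M(p1, 0, incidence_params()))
  expect_equal(cr1$lambda_M, 0)

  x2 <- mk_line(c(0, 2))
  pars <- spom_params(alpha = 0.7, em = 0.2, x = 0.4, y = 1)
  M <- build_M(x2, c(0, 0), pars)
  expect_equal(unname(diag(M)), c(0, 0))
  expect_equal(M[1, 2], exp(-0.7 * 2), tolerance = 1e-12)
  expect_equal(M[2, 1], exp(-0.7 * 2), tolerance = 1e-12)

  xr <- mk_random_landscape(12, seed = 5)
  q <- quality_index(xr)
  Ma <- build_M(xr, q, pars)
  xr2 <- xr; xr2$patches$area_ha <- 3 * xr$patches$area_ha
  Mb <- build_M(landscape(xr2$patches), q, pars)
  expect_equal(Mb, Ma * 3^(pars$x + pars$em), tolerance = 1e-12)
  expect_equal(metapop_capacity(Mb)$lambda_M,
               metapop_capacity(Ma)$lambda_M * 3^(pars$x + pars$em),
               tolerance = 1e-10)
})

test_that("metapopulation capacity solves the hand-derived eigenproblems", {
  # symmetric 2x2 with off-diagonal a: lambda = a, weights equal
  M2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  cr <- metapop_capacity(M2)
  expect_equal(cr$lambda_M, 0.3, tolerance = 1e-12)
  expect_equal(unname(cr$weights), c(0.5, 0.5), tolerance = 1e-12)

  # equilateral triangle of identical unit patches: lambda = 2 e^{-alpha d}
  d <- 0.8; alpha <- 1
  tri <- mk_line(c(0, d, d / 2), ys = c(0, 0, d * sqrt(3) / 2))
  crt <- metapop_capacity(build_M(tri, rep(0, 3),
                                  spom_params(alpha = alpha, em = 0.2, x = 0.4)))
  expect_equal(crt$lambda_M, 2 * exp(-alpha * d), tolerance = 1e-10)

  # block-diagonal: capacity of the union = max of the blocks
  B <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  B[1, 2] <- B[2, 1] <- 0.9
  B[3, 4] <- B[4, 3] <- 0.2
  expect_warning(crb <- metapop_capacity(B), "component")
  expect_equal(crb$lambda_M, 0.9, tolerance = 1e-12)
  expect_equal(unname(crb$weights[3:4]), c(0, 0))

  expect_error(metapop_capacity(matrix(c(0, NA, 1, 0), 2, 2)), "finite")
})

test_that("eigen solution agrees with power iteration on random landscapes", {
  for (s in 1:10) {
    x <- mk_random_landscape(40, seed = 100 + s)
    M <- build_M(x, quality_index(x), incidence_params())
    lam <- metapop_capacity(M)$lambda_M
    expect_equal(lam, power_iteration_lambda(M), tolerance = 1e-10)
  }
})

test_that("capacity is monotone in areas and quality, antitone in distance", {
  x <- mk_random_landscape(25, seed = 44)
  q <- quality_index(x)
  pars <- incidence_params()
  lam0 <- metapop_capacity(build_M(x, q, pars))$lambda_M

  p_big <- x$patches; p_big$area_ha[7] <- p_big$area_ha[7] * 2
  expect_gt(metapop_capacity(build_M(landscape(p_big), q, pars))$lambda_M, lam0)

  q_up <- q; q_up[3] <- q_up[3] + 0.2
  expect_gt(metapop_capacity(build_M(x, q_up, pars))$lambda_M, lam0)

  p_far <- x$patches
  p_far$x_km <- p_far$x_km * 1.5; p_far$y_km <- p_far$y_km * 1.5
  expect_lt(metapop_capacity(build_M(landscape(p_far), q, pars))$lambda_M, lam0)
})

test_that("weighted occupancy renormalizes over surveyed patches", {
  occ <- rbind(a = c(1, 1, 0, NA), b = c(1, 0, 0, NA))
  colnames(occ) <- 1:4
  h <- occupancy_history(occ)
  w <- c(a = 0.8, b = 0.2)
  pl <- p_lambda_series(h, w)
  expect_equal(unname(pl), c(1, 0.8, 0, NA))
  expect_error(p_lambda_series(h, c(a = 0.8, b = 0.5)), "sum to 1")
})

test_that("equilibrium prediction and viability classification", {
  expect_equal(equilibrium_prediction(5.47, 5.47)$p_lambda_star, 0)
  expect_false(equilibrium_prediction(5.47, 5.47)$viable)
  expect_equal(equilibrium_prediction(6.1, 5.47)$p_lambda_star, 0.1033,
               tolerance = 1e-3)
  expect_equal(equilibrium_prediction(10, 5)$p_lambda_star, 0.5)
  e0 <- equilibrium_prediction(0, 5.47)
  expect_equal(e0$p_lambda_star, -Inf)
  expect_false(e0$viable)

  cl <- classify_networks(c(1, 6, 10), 5.47)
  expect_equal(cl$n_viable, 2L)
  expect_equal(cl$fraction_below, 1 / 3)
  expect_equal(classify_networks(rep(5.47, 4), 5.47)$n_viable, 0L)
})

test_that("mean-field fixed point matches the capacity identity", {
  ## deterministic p_i = C_i/(C_i + E_i) solved by damped iteration; the
  ## weighted average should sit near 1 - delta/lambda for homogeneous nets
  x <- mk_grid(4, 4, 0.5)
  pars0 <- spom_params(alpha = 1, em = 0.2, im = 0.2, ex = 0.2, y = 0,
                       e = 0.1, c = 0.1)
  cr <- metapop_capacity(build_M(x, NULL, pars0))
  for (ratio in c(1.5, 3, 5)) {
    cc <- 0.15; ee <- cc * cr$lambda_M / ratio
    pars <- spom_params(alpha = 1, em = 0.2, im = 0.2, ex = 0.2, y = 0,
                        e = ee, c = cc)
    E <- ee * x$patches$area_ha^(-pars$ex)
    p <- rep(0.5, n_patches(x))
    for (i in 1:2000) {
      C <- cc * patch_connectivity(x, p, pars)$S
      pn <- C / (C + E)
      if (max(abs(pn - p)) < 1e-12) break
      p <- 0.7 * p + 0.3 * pn
    }
    expect_lt(abs(sum(cr$weights * p) - (1 - 1 / ratio)), 0.05)
  }
})
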