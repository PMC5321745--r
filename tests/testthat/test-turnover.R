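test_that("event extraction enumerates opportunities by hand", {
  occ <- rbind(p1 = c(1, 0, 1), p2 = c(0, 0, 1))
  colnames(occ) <- 2000:2002
  ev <- extract_events(occupancy_history(occ))
  # p1: 1->0 (extinction event), 0->1 (colonization event)
  # p2: 0->0, 0->1
  expect_equal(nrow(ev), 4L)
  expect_equal(sum(ev$state_from == 1), 1L)              # 1 ext opportunity
  expect_equal(sum(ev$state_from == 1 & ev$event == 1), 1L)
  expect_equal(sum(ev$state_from == 0), 3L)              # 3 col opportunities
  expect_equal(sum(ev$state_from == 0 & ev$event == 1), 2L)
  expect_equal(turnover_rate(ev), 0.75)

  # occupied both years: opportunity, no event
  occ2 <- rbind(p = c(1, 1)); colnames(occ2) <- 1:2
  ev2 <- extract_events(occupancy_history(occ2))
  expect_equal(ev2$state_from, 1)
  expect_equal(ev2$event, 0L)

  # a missing middle year removes both adjacent transitions
  occ3 <- rbind(p = c(1, NA, 1)); colnames(occ3) <- 1:3
  expect_equal(nrow(extract_events(occupancy_history(occ3))), 0L)

  # non-consecutive survey years yield no transition records
  occ4 <- rbind(p = c(1, 0)); colnames(occ4) <- c(2000, 2005)
  expect_equal(nrow(extract_events(occupancy_history(occ4))), 0L)
})

test_that("turnover rate spans its extremes and respects opportunities", {
  occ_static <- matrix(1, 2, 5,
                       dimnames = list(c("a", "b"), 1:5))
  expect_equal(turnover_rate(extract_events(occupancy_history(occ_static))), 0)

  occ_alt <- rbind(a = rep(c(1, 0), 3), b = rep(c(0, 1), 3))
  colnames(occ_alt) <- 1:6
  expect_equal(turnover_rate(extract_events(occupancy_history(occ_alt))), 1)

  # event conservation: opportunities = observed consecutive transitions
  st <- generate_study(synth_config(n_patches = 80, n_networks = 2,
                                    years = 8), seed = 31)
  ev <- extract_events(st$history_observed, st$assignment)
  occ <- st$history_observed$occupied
  n_trans <- sum(!is.na(occ[, -ncol(occ)]) & !is.na(occ[, -1]))
  expect_equal(nrow(ev), n_trans)
})

test_that("transition probabilities match the printed-rate arithmetic", {
  x <- mk_line(c(0, 1))
  pars <- spom_params(e = 0.38, c = 0.11, ex = 0.23, im = 0.44, em = 0.22,
                      alpha = 0.93, y = 1.40)
  # no occupied sources: no colonization pressure
  tp0 <- transition_probabilities(x, NULL, pars, occupancy = c(0, 0))
  expect_equal(tp0$P_col, c(0, 0))

  # unit area neutralizes the exponents: P_ext = 1 - e^{-e}
  expect_equal(tp0$P_ext, rep(1 - exp(-0.38), 2), tolerance = 1e-6)
  expect_equal(tp0$P_ext[1], 0.3161, tolerance = 1e-3)

  # c = 0.11 at S = 1: P_col = 1 - e^{-0.11} = 0.10417
  expect_equal(1 - exp(-pars$c * 1), 0.10417, tolerance = 1e-4)

  # bounds and monotonicity
  xr <- mk_random_landscape(20, seed = 2)
  q <- quality_index(xr)
  tp <- transition_probabilities(xr, q, pars, occupancy = rep(1, 20))
  expect_true(all(tp$P_col >= 0 & tp$P_col < 1))
  expect_true(all(tp$P_ext > 0 & tp$P_ext < 1))
  ord <- order(xr$patches$area_ha)
  expect_lt(tp$P_ext[ord[20]], tp$P_ext[ord[1]])   # big patches die less
})

test_that("transition likelihood matches an R reference on a small history", {
  x <- mk_line(c(0, 0.5, 1.2), areas = c(0.5, 1, 2))
  q <- c(-0.3, 0, 0.4)
  occ <- rbind(p01 = c(1, 0, 1, NA), p02 = c(0, 1, 1, 1),
               p03 = c(1, 1, NA, 0))
  colnames(occ) <- 1:4
  pars <- c(e = 0.4, c = 0.2, ex = 0.3, im = 0.4, em = 0.25,
            alpha = 1.1, y = 0.8)
  Oint <- matrix(as.integer(ifelse(is.na(occ), -1L, occ)), 3, 4)
  ll_cpp <- metacap:::spom_transition_loglik(pars, x$patches$area_ha, q,
                                             x$dist, Oint)
  # independent R-side evaluation
  sp <- spom_params(e = pars["e"], c = pars["c"], ex = pars["ex"],
                    im = pars["im"], em = pars["em"], alpha = pars["alpha"],
                    y = pars["y"])
  ll_r <- 0
  for (t in 1:3) {
    cur <- occ[, t]; nxt <- occ[, t + 1]
    tp <- transition_probabilities(x, q, sp,
                                   occupancy = ifelse(is.na(cur), 0, cur))
    for (i in 1:3) {
      if (is.na(cur[i]) || is.na(nxt[i])) next
      pr <- if (cur[i] == 0) tp$P_col[i] else tp$P_ext[i]
      ev <- if (cur[i] == 0) nxt[i] == 1 else nxt[i] == 0
      ll_r <- ll_r + log(if (ev) pr else 1 - pr)
    }
  }
  expect_equal(ll_cpp, ll_r, tolerance = 1e-10)
})

test_that("rate posterior concentrates near truth on simulated data", {
  cfg <- synth_config(n_patches = 120, n_networks = 3, years = 25,
                      det_intercept = Inf, early_coverage = 1,
                      n_early_years = 0)
  st <- generate_study(cfg, seed = 13)
  fit <- suppressWarnings(
    estimate_rates(st$landscape, st$history_true, st$q_tilde,
                   chains = 2, iter = 800, warmup = 800))
  s <- fit$summary
  expect_setequal(s$parameter,
                  c("e", "c", "ex", "im", "em", "alpha", "y", "delta"))
  expect_true(all(s$q2.5 < s$q97.5))
  expect_true(all(s$mean > 0))
  # point estimates in the right region (loose: short chains)
  expect_lt(abs(s$mean[s$parameter == "e"] - 0.38), 0.25)
  expect_lt(abs(s$mean[s$parameter == "im"] - 0.44), 0.25)
  # delta summarized from joint draws, not the ratio of summaries
  expect_equal(s$mean[s$parameter == "delta"],
               mean(fit$draws[, "e"] / fit$draws[, "c"]), tolerance = 1e-12)
})

test_that("histories without colonization events flag an unidentified c", {
  occ <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 0))
  colnames(occ) <- 1:4
  x <- mk_line(c(0, 0.4))
  expect_warning(
    suppressMessages(estimate_rates(x, occupancy_history(occ), NULL,
                                    chains = 1, iter = 150, warmup = 150)),
    "no colonization")
})

test_that("hierarchical turnover model recovers planted effects", {
  d <- gen_glmm_events(5)
  fit <- fit_turnover_glmm(d, models = "colonization", chains = 2,
                           iter = 800, warmup = 400)
  s <- fit$colonization$summary
  truth <- c(a0 = -2, bA = 0.8, bS = 0.8, bf = 0.25, rho = 0.7, tau = 1.5)
  for (p in names(truth)) {
    row <- s[s$parameter == p, ]
    expect_true(truth[p] >= row$q2.5 - 0.3 && truth[p] <= row$q97.5 + 0.3,
                label = paste("parameter", p, "near its planted value"))
  }
  # odds-ratio column is exp of the median column
  bet <- s[s$parameter %in% c("bA", "bS", "bf"), ]
  expect_equal(bet$odds_ratio, exp(bet$median), tolerance = 1e-12)
  expect_true(all(is.na(s$odds_ratio[s$parameter %in% c("a0", "tau", "rho")])))
})

test_that("a constant genotype covariate centres its coefficient at zero", {
  d <- gen_glmm_events(6, n_net = 8, n_yr = 6, n_patch = 8,
                       beta = c(0.8, 0.8, 0))
  d$f_S <- 0.4
  expect_warning(
    fit <- fit_turnover_glmm(d, models = "colonization", chains = 1,
                             iter = 400, warmup = 200),
    "constant covariate")
  bf <- fit$colonization$summary
  bf <- bf[bf$parameter == "bf", ]
  expect_true(bf$q2.5 < 0 && bf$q97.5 > 0)
})

test_that("detection models recover known coefficients and rates", {
  set.seed(2)
  n <- 200
  area <- rlnorm(n, log(0.06), 1.5)
  tot <- pmax(1, rpois(n, 5))
  truth <- c(1.0, 0.3, 0.2)
  pg <- plogis(truth[1] + truth[2] * log(area) + truth[3] * tot)
  found <- rbinom(n, tot, pg)
  ctrl <- data.frame(patch_id = paste0("c", 1:n), area_ha = area,
                     groups_main = found, groups_total = tot,
                     detected = as.integer(found >= 1))
  fit <- fit_detection_models(ctrl, chains = 2, iter = 800, warmup = 400)
  s <- fit$group_detection$summary
  for (i in 1:3)
    expect_lt(abs(s$mean[i] - truth[i]) / s$sd[i], 2.5)
  expect_equal(fit$nondetection_rate, mean(1 - ctrl$detected))
  expect_named(fit, c("group_detection", "patch_nondetection",
                      "population_size", "nondetection_rate"))

  ctrl_all <- ctrl; ctrl_all$detected <- 1L
  expect_warning(fit_detection_models(ctrl_all, chains = 1, iter = 200,
                                      warmup = 200), "prior-regularized")
  expect_error(fit_detection_models(ctrl[0, ]), "empty")
})

test_that("Pearson chi-squared matches closed form, df = 1", {
  # closed form n(ad - bc)^2 / (r1 r2 c1 c2)
  tab <- matrix(c(20, 0, 0, 20), 2, 2)
  expect_equal(contingency_chi2(tab)$chi2, 40, tolerance = 1e-12)
  expect_equal(contingency_chi2(matrix(10, 2, 2))$chi2, 0)
  expect_equal(contingency_chi2(tab)$df, 1)
  # long-extinct by viability class, from the study's printed counts
  # 79/92 non-viable vs 5/33 viable
  per <- matrix(c(79, 5, 13, 28), 2, 2)
  expect_equal(contingency_chi2(per)$chi2, 55.1, tolerance = 0.01)
  expect_error(contingency_chi2(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})
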