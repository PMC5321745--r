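#' Extract annual colonization and extinction opportunities
#'
#' One record per patch transition between consecutive surveyed years: a
#' colonization opportunity where the patch was empty (event = 1 if it
#' became occupied), an extinction opportunity where it was occupied
#' (event = 1 if it went extinct). Transitions spanning a missing survey
#' are dropped, not imputed.
#'
#' @param history [occupancy_history].
#' @param assignment optional [network_assignment] to attach network ids.
#' @return data.frame of class `turnover_events` with columns `patch_id`,
#'   `network_id` (NA if no assignment), `year_from`, `year_to`,
#'   `state_from`, `event`.
#' @export
extract_events <- function(history, assignment = NULL) {
  occ <- history$occupied
  years <- history$years
  if (ncol(occ) < 2) stop("need at least 2 survey years")
  recs <- list()
  for (t in seq_len(ncol(occ) - 1)) {
    if (years[t + 1] != years[t] + 1) next   # non-consecutive years
    from <- occ[, t]; to <- occ[, t + 1]
    ok <- !is.na(from) & !is.na(to)
    if (!any(ok)) next
    recs[[length(recs) + 1]] <- data.frame(
      patch_id = rownames(occ)[ok],
      year_from = years[t], year_to = years[t + 1],
      state_from = from[ok], event = as.integer(to[ok] != from[ok]),
      stringsAsFactors = FALSE)
  }
  ev <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(patch_id = character(), year_from = integer(),
               year_to = integer(), state_from = numeric(), event = integer())
  ev$network_id <- if (is.null(assignment)) rep(NA_integer_, nrow(ev)) else
    assignment$network_id[match(ev$patch_id, assignment$patch_id)]
  rownames(ev) <- NULL
  class(ev) <- c("turnover_events", "data.frame")
  ev
}

#' Observed population turnover rate
#'
#' Extinction plus colonization events divided by the total number of
#' opportunities (observed consecutive-year patch transitions).
#'
#' @param events [extract_events] output.
#' @param per "overall" for a single rate or "network" for one per network.
#' @return numeric rate in \[0, 1\], or data.frame (`network_id`, `rate`,
#'   `n_opportunities`); NA where a network has no opportunities.
#' @export
turnover_rate <- function(events, per = c("overall", "network")) {
  per <- match.arg(per)
  if (per == "overall") {
    if (nrow(events) == 0) return(NA_real_)
    return(mean(events$event))
  }
  agg <- stats::aggregate(event ~ network_id, data = events,
                          FUN = function(v) c(rate = mean(v), n = length(v)))
  data.frame(network_id = agg$network_id, rate = agg$event[, "rate"],
             n_opportunities = agg$event[, "n"])
}

#' Annual colonization and extinction probabilities
#'
#' The discrete-time transition probabilities of the SPOM:
#' `P_col,i = 1 - exp(-c S_i)` with connectivity computed from the current
#' occupancy, and `P_ext,i = 1 - exp(-e A_i^-ex exp(-y Q_i))`.
#'
#' @param x landscape.
#' @param q_tilde quality index (0 if NULL).
#' @param params [spom_params].
#' @param occupancy current per-patch occupancy (0/1 or probabilities).
#' @return data.frame with `patch_id`, `S`, `P_col`, `P_ext`.
#' @export
transition_probabilities <- function(x, q_tilde = NULL, params = spom_params(),
                                     occupancy) {
  if (is.null(q_tilde)) q_tilde <- rep(0, n_patches(x))
  conn <- patch_connectivity(x, occupancy, params)
  A <- x$patches$area_ha
  data.frame(patch_id = x$patches$id, S = unname(conn$S),
             P_col = 1 - exp(-params$c * conn$S),
             P_ext = 1 - exp(-params$e * A^(-params$ex) *
                               exp(-params$y * q_tilde)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bayesian estimation of SPOM rate parameters from annual turnover
#'
#' Posterior over (e, c, ex, im, em, alpha, y) under the Bernoulli
#' likelihood of the observed annual transitions, with connectivity
#' recomputed each year from that year's occupancy. Priors are uniform on
#' the positive reals; sampling is adaptive random-walk Metropolis on the
#' log scale (the Jacobian is included so the prior remains flat on the
#' natural scale). The extinction threshold delta = e/c is summarized from
#' the joint posterior draws, not from the ratio of summaries.
#'
#' @param x landscape.
#' @param history [occupancy_history]; transitions with unsurveyed endpoints
#'   are dropped and unsurveyed sources contribute no immigrants.
#' @param q_tilde quality index (0 if NULL).
#' @param chains number of chains.
#' @param iter,warmup post-warmup and warmup iterations per chain.
#' @param init optional named initial values (natural scale).
#' @param strict if TRUE, stop (rather than warn) when split-Rhat >= 1.01.
#' @return list of class `rate_estimates`: `summary` data.frame (mean, sd,
#'   2.5%, 97.5%, Rhat, n_eff per parameter including delta), `draws`
#'   matrix, `accept_rate`.
#' @export
estimate_rates <- function(x, history, q_tilde = NULL, chains = 2,
                           iter = 1500, warmup = 1500, init = NULL,
                           strict = FALSE) {
  if (is.null(q_tilde)) q_tilde <- rep(0, n_patches(x))
  O <- history$occupied
  stopifnot(nrow(O) == n_patches(x))
  Oint <- matrix(as.integer(ifelse(is.na(O), -1L, O)), nrow(O), ncol(O))
  ev <- extract_events(history)
  if (sum(ev$state_from == 0 & ev$event == 1) == 0)
    warning("no colonization events: c is unidentified and will pile near 0")
  if (sum(ev$state_from == 1 & ev$event == 1) == 0)
    warning("no extinction events: e is unidentified and will pile near 0")

  pn <- c("e", "c", "ex", "im", "em", "alpha", "y")
  A <- x$patches$area_ha
  logpost <- function(theta) {
    if (any(theta > 12) || any(theta < -20)) return(-Inf)
    spom_transition_loglik(exp(theta), A, q_tilde, x$dist, Oint) + sum(theta)
  }
  th0 <- if (is.null(init)) {
    log(c(e = 0.3, c = 0.1, ex = 0.3, im = 0.4, em = 0.3, alpha = 1, y = 0.5))
  } else log(init[pn])

  runs <- lapply(seq_len(chains), function(ch) {
    start <- th0 + stats::rnorm(7, 0, 0.3)
    adaptive_metropolis(logpost, start, n_warmup = warmup, n_iter = iter)
  })
  draws <- exp(do.call(rbind, lapply(runs, `[[`, "draws")))
  colnames(draws) <- pn
  draws <- cbind(draws, delta = draws[, "e"] / draws[, "c"])

  rhat <- vapply(colnames(draws), function(v) {
    split_rhat(lapply(seq_len(chains), function(ch)
      log(draws[(ch - 1) * iter + seq_len(iter), v])))
  }, numeric(1))
  n_eff <- vapply(colnames(draws), function(v)
    unname(coda::effectiveSize(coda::mcmc(draws[, v]))), numeric(1))
  if (any(rhat >= 1.01, na.rm = TRUE)) {
    msg <- paste0("convergence not reached (max split-Rhat = ",
                  format(max(rhat), digits = 4), ")")
    if (strict) stop(msg) else warning(msg)
  }
  qs <- t(apply(draws, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  summ <- data.frame(parameter = colnames(draws),
                     mean = colMeans(draws), sd = apply(draws, 2, stats::sd),
                     q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3],
                     rhat = rhat, n_eff = n_eff, row.names = NULL)
  structure(list(summary = summ, draws = draws,
                 accept_rate = mean(vapply(runs, `[[`, numeric(1),
                                           "accept_rate"))),
            class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat("SPOM rate posterior (", nrow(x$draws), " draws, accept ",
      format(x$accept_rate, digits = 3), ")\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Hierarchical logistic regression of turnover events
#'
#' Varying-intercepts logistic regression of colonization (or extinction)
#' events on standardized `A^0.2`, connectivity S and the dispersive
#' immigrant genotype frequency f^S_disp, with annual network-level random
#' intercepts (scale tau) and network-specific patch random intercepts
#' (scale rho):
#' `logit p = a0 + a_{n,t} + a_{i,n} + bA A^0.2 + bS S + bf f^S`.
#' Fitted by Gibbs sampling (JAGS); weakly informative priors (normal sd 5
#' on fixed effects, half-t(3, 0, 2.5) on tau and rho).
#'
#' @param events data.frame with columns `event`, `state_from`, `patch_id`,
#'   `network_id`, `year_from`, `area_ha`, `S`, `f_S`. Covariates are
#'   standardized internally within each model's record set.
#' @param models which event models to fit.
#' @param chains,iter,warmup MCMC settings.
#' @param quiet suppress JAGS progress output.
#' @return list of class `turnover_glmm` with one element per model, each a
#'   list with `summary` (median, 95% Cr.I., odds ratio where applicable)
#'   and `draws`.
#' @export
fit_turnover_glmm <- function(events,
                              models = c("colonization", "extinction"),
                              chains = 2, iter = 1000, warmup = 500,
                              quiet = TRUE) {
  models <- match.arg(models, several.ok = TRUE)
  needed <- c("event", "state_from", "patch_id", "network_id", "year_from",
              "area_ha", "S", "f_S")
  stopifnot(all(needed %in% names(events)))
  model_str <- "
  model {
    for (r in 1:N) {
      y[r] ~ dbern(p[r])
      logit(p[r]) <- a0 + ant[ny[r]] + ain[pid[r]] +
        bA * xA[r] + bS * xS[r] + bf * xf[r]
    }
    for (j in 1:Nny) { ant[j] ~ dnorm(0, 1 / (tau * tau)) }
    for (j in 1:Np)  { ain[j] ~ dnorm(0, 1 / (rho * rho)) }
    a0 ~ dnorm(0, 0.04)
    bA ~ dnorm(0, 0.04)
    bS ~ dnorm(0, 0.04)
    bf ~ dnorm(0, 0.04)
    tau ~ dt(0, 0.16, 3) T(0,)
    rho ~ dt(0, 0.16, 3) T(0,)
  }"
  std <- function(v) {
    s <- stats::sd(v)
    if (s == 0) { warning("constant covariate; coefficient unidentified, ",
                          "posterior will centre at 0"); return(v * 0) }
    (v - mean(v)) / s
  }
  out <- list()
  for (m in models) {
    d <- events[events$state_from == (m == "extinction"), ]
    if (nrow(d) == 0) stop("no ", m, " opportunities in events")
    if (length(unique(d$network_id)) < 2 ||
        length(unique(d$year_from)) < 2)
      warning("single network or year: tau weakly identified")
    nyf <- factor(paste(d$network_id, d$year_from))
    pf <- factor(paste(d$network_id, d$patch_id))
    data <- list(y = d$event, N = nrow(d),
                 xA = std(d$area_ha^0.2), xS = std(d$S), xf = std(d$f_S),
                 ny = as.integer(nyf), Nny = nlevels(nyf),
                 pid = as.integer(pf), Np = nlevels(pf))
    jm <- rjags::jags.model(textConnection(model_str), data = data,
                            n.chains = chains, n.adapt = max(200, warmup),
                            quiet = quiet)
    update(jm, warmup, progress.bar = "none")
    sm <- rjags::coda.samples(jm, c("a0", "bA", "bS", "bf", "tau", "rho"),
                              n.iter = iter, progress.bar = "none")
    draws <- as.matrix(sm)
    qs <- t(apply(draws, 2, stats::quantile, c(0.025, 0.5, 0.975)))
    summ <- data.frame(parameter = rownames(qs), median = qs[, 2],
                       q2.5 = qs[, 1], q97.5 = qs[, 3], row.names = NULL)
    summ$odds_ratio <- ifelse(summ$parameter %in% c("bA", "bS", "bf"),
                              exp(summ$median), NA_real_)
    out[[m]] <- list(summary = summ, draws = draws)
  }
  structure(out, class = "turnover_glmm")
}

#' Detection GLMs for control-survey data
#'
#' Three Bayesian GLMs quantifying imperfect detection in the annual larval
#' census, fitted to repeat-visit control data on occupied patches:
#' (1) binomial (logit) model for the probability that a larval group is
#' found in the main survey, with log patch area and total group count as
#' predictors; (2) logistic model for whole-patch non-detection, same
#' predictors; (3) Poisson (log) model for population size (total groups)
#' with log area and the non-detection indicator. Priors are Student-t with
#' 4 degrees of freedom, scale 10 for intercepts and 2.5 for predictors.
#'
#' @param control data.frame with columns `patch_id`, `area_ha`,
#'   `groups_main` (groups found in the main survey), `groups_total`
#'   (including the control visit), `detected` (0/1, patch found occupied
#'   in main survey).
#' @param chains,iter,warmup MCMC settings.
#' @param quiet suppress JAGS progress output.
#' @return list of class `detection_fits` with elements `group_detection`,
#'   `patch_nondetection`, `population_size` (each: `summary`, `draws`),
#'   plus `nondetection_rate` (fraction of occupied patches missed).
#' @export
fit_detection_models <- function(control, chains = 2, iter = 1000,
                                 warmup = 500, quiet = TRUE) {
  needed <- c("area_ha", "groups_main", "groups_total", "detected")
  stopifnot(all(needed %in% names(control)))
  if (nrow(control) == 0) stop("empty control data")
  if (all(control$detected == 1))
    warning("all populations detected: non-detection intercept is ",
            "prior-regularized only")
  logA <- log(control$area_ha)

  run <- function(model_str, data, pars) {
    jm <- rjags::jags.model(textConnection(model_str), data = data,
                            n.chains = chains, n.adapt = max(200, warmup),
                            quiet = quiet)
    update(jm, warmup, progress.bar = "none")
    sm <- rjags::coda.samples(jm, pars, n.iter = iter, progress.bar = "none")
    draws <- as.matrix(sm)
    qs <- t(apply(draws, 2, stats::quantile, c(0.025, 0.5, 0.975)))
    rh <- try(coda::gelman.diag(sm, autoburnin = FALSE)$psrf[, 1],
              silent = TRUE)
    list(summary = data.frame(parameter = rownames(qs),
                              mean = colMeans(draws),
                              sd = apply(draws, 2, stats::sd),
                              q2.5 = qs[, 1], median = qs[, 2],
                              q97.5 = qs[, 3],
                              rhat = if (inherits(rh, "try-error"))
                                NA_real_ else unname(rh),
                              row.names = NULL),
         draws = draws)
  }
  prior <- "b0 ~ dt(0, 0.01, 4)\n b1 ~ dt(0, 0.16, 4)\n b2 ~ dt(0, 0.16, 4)"

  m1 <- run(paste0("model { for (r in 1:N) {
      k[r] ~ dbin(p[r], n[r])
      logit(p[r]) <- b0 + b1 * logA[r] + b2 * tot[r]
    }\n", prior, "}"),
    list(N = nrow(control), k = control$groups_main,
         n = control$groups_total, logA = logA, tot = control$groups_total),
    c("b0", "b1", "b2"))
  m2 <- run(paste0("model { for (r in 1:N) {
      y[r] ~ dbern(p[r])
      logit(p[r]) <- b0 + b1 * logA[r] + b2 * tot[r]
    }\n", prior, "}"),
    list(N = nrow(control), y = 1L - control$detected, logA = logA,
         tot = control$groups_total),
    c("b0", "b1", "b2"))
  m3 <- run(paste0("model { for (r in 1:N) {
      k[r] ~ dpois(mu[r])
      log(mu[r]) <- b0 + b1 * logA[r] + b2 * nd[r]
    }\n", prior, "}"),
    list(N = nrow(control), k = control$groups_total, logA = logA,
         nd = 1L - control$detected),
    c("b0", "b1", "b2"))

  structure(list(group_detection = m1, patch_nondetection = m2,
                 population_size = m3,
                 nondetection_rate = mean(1 - control$detected)),
            class = "detection_fits")
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Without continuity correction, df = 1.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
contingency_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
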