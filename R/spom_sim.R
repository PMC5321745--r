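#' Simulate the stochastic patch occupancy model
#'
#' Synchronous annual update: each occupied patch goes extinct with
#' probability `1 - exp(-e A^-ex exp(-y Q))`; each empty patch is colonized
#' with probability `1 - exp(-c S)` where connectivity S is computed from
#' the previous year's occupancy. A patch changes state at most once per
#' year and there is no within-year rescue. An optional constant
#' `external_connectivity` is added to every S to represent immigration from
#' outside the simulated network.
#'
#' An optional genotype layer propagates the dispersive-genotype frequency:
#' a newly colonized patch inherits the immigrant-pool frequency of its
#' sources ([immigrant_freq]), and occupied patches relax towards their
#' immigrant pool at rate `mix` per year. This layer is a simple
#' frequency-propagation model, not individual-based, and is off by default.
#'
#' @param x landscape.
#' @param q_tilde quality index (0 if NULL).
#' @param params [spom_params].
#' @param years number of annual steps simulated after the initial year.
#' @param init initial occupancy: numeric vector, or "all" (every patch
#'   occupied), "random" (each patch independently with probability
#'   `init_p`), "single" (only the first patch).
#' @param init_p occupancy probability for `init = "random"`.
#' @param seed RNG seed (required, for reproducibility).
#' @param external_connectivity constant added to every S_i.
#' @param track_genetics logical; simulate the genotype layer.
#' @param f_init initial per-patch dispersive frequency (genotype layer).
#' @param mix per-year relaxation rate of resident frequency towards the
#'   immigrant pool.
#' @param start_year calendar year of the initial state.
#' @return list of class `spom_sim`: `history` (an [occupancy_history] of
#'   the `years + 1` simulated years), `fraction_occupied` and `p_lambda`
#'   left NULL (compute via [p_lambda_series]), `events` (the
#'   [extract_events] log), `extinction_year` (first all-empty year or NA),
#'   `f_disp` (patch x year matrix when tracking genetics).
#' @export
simulate_spom <- function(x, q_tilde = NULL, params = spom_params(),
                          years = 20, init = "all", init_p = 0.5, seed,
                          external_connectivity = 0, track_genetics = FALSE,
                          f_init = NULL, mix = 0.1, start_year = 1L) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n <- n_patches(x)
  if (is.null(q_tilde)) q_tilde <- rep(0, n)
  A <- x$patches$area_ha
  occ0 <- if (is.character(init)) {
    switch(match.arg(init, c("all", "random", "single")),
           all = rep(1, n),
           random = stats::rbinom(n, 1, init_p),
           single = c(1, rep(0, n - 1)))
  } else as.numeric(init)
  stopifnot(length(occ0) == n, all(occ0 %in% 0:1), years >= 1)

  P_ext <- 1 - exp(-params$e * A^(-params$ex) * exp(-params$y * q_tilde))
  K <- exp(-params$alpha * x$dist)     # kernel; source area factor applied below
  diag(K) <- 0
  Aem <- A^params$em
  Aim <- A^params$im

  O <- matrix(NA_real_, n, years + 1,
              dimnames = list(x$patches$id, start_year + 0:years))
  O[, 1] <- occ0
  f <- NULL
  if (track_genetics) {
    if (is.null(f_init)) f_init <- rep(0.3, n)
    f <- matrix(NA_real_, n, years + 1, dimnames = dimnames(O))
    f[, 1] <- ifelse(occ0 == 1, f_init, NA_real_)
  }
  for (t in seq_len(years)) {
    cur <- O[, t]
    S <- Aim * as.vector(K %*% (cur * Aem)) + external_connectivity
    P_col <- 1 - exp(-params$c * S)
    u <- stats::runif(n)
    nxt <- ifelse(cur == 1, ifelse(u < P_ext, 0, 1),
                  ifelse(u < P_col, 1, 0))
    O[, t + 1] <- nxt
    if (track_genetics) {
      fS <- immigrant_freq(x, ifelse(is.na(f[, t]), 0, f[, t]), cur, params)
      fn <- f[, t]
      colonized <- cur == 0 & nxt == 1
      fn[colonized] <- fS[colonized]
      stay <- cur == 1 & nxt == 1
      fn[stay] <- ifelse(is.na(fS[stay]), fn[stay],
                         (1 - mix) * fn[stay] + mix * fS[stay])
      fn[nxt == 0] <- NA_real_
      f[, t + 1] <- fn
    }
  }
  hist <- occupancy_history(O)
  allempty <- which(colSums(O) == 0)
  structure(list(history = hist,
                 fraction_occupied = colMeans(O),
                 events = extract_events(hist),
                 extinction_year = if (length(allempty) > 0)
                   as.integer(colnames(O)[allempty[1]]) else NA_integer_,
                 f_disp = f, seed = seed),
            class = "spom_sim")
}

#' Persistence experiment over replicate simulations
#'
#' Repeatedly simulates a network and summarizes (i) the probability of
#' persisting to the horizon (not a single all-empty year at the end) and
#' (ii) the quasi-equilibrium weighted occupancy: the mean p_lambda over the
#' final third of the horizon, averaged over surviving replicates.
#'
#' @param x landscape (one network).
#' @param q_tilde quality index.
#' @param params [spom_params].
#' @param weights capacity weights for p_lambda (from [metapop_capacity]);
#'   computed internally when NULL.
#' @param replicates,years experiment size.
#' @param seed base seed; replicate r uses seed + r.
#' @param init initial occupancy passed to [simulate_spom].
#' @param external_connectivity see [simulate_spom].
#' @return list with `persistence_prob`, `mean_p_lambda` (NA when no
#'   replicate survives), `n_surviving`.
#' @export
persistence_experiment <- function(x, q_tilde = NULL, params = spom_params(),
                                   weights = NULL, replicates = 100,
                                   years = 100, seed = 1, init = "all",
                                   external_connectivity = 0) {
  stopifnot(replicates >= 1)
  if (is.null(weights))
    weights <- metapop_capacity(build_M(x, q_tilde, params))$weights
  surv <- logical(replicates)
  plam <- rep(NA_real_, replicates)
  tail_cols <- (floor(2 * years / 3) + 1):(years + 1)
  for (r in seq_len(replicates)) {
    sim <- simulate_spom(x, q_tilde, params, years = years, init = init,
                         seed = seed + r,
                         external_connectivity = external_connectivity)
    O <- sim$history$occupied
    surv[r] <- sum(O[, years + 1]) > 0
    if (surv[r]) {
      pl <- p_lambda_series(sim$history, weights)
      plam[r] <- mean(pl[tail_cols])
    }
  }
  list(persistence_prob = mean(surv),
       mean_p_lambda = if (any(surv)) mean(plam[surv]) else NA_real_,
       n_surviving = sum(surv))
}
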