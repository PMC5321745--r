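#' Configuration for synthetic study generation
#'
#' Defaults emulate the structure of a highly fragmented dry-meadow
#' landscape: patches arise in spatial clusters (the future networks), patch
#' areas are log-normal with median 0.06 ha and 1% exceeding 2 ha, the SPOM
#' runs at the posterior-mean rate parameters of the turnover analysis, and
#' surveys have partial early coverage plus imperfect group-level detection.
#' Group counts for occupied patches are zero-truncated negative binomial
#' with a log-area trend.
#'
#' @param n_patches number of patches.
#' @param n_networks number of spatial clusters / networks.
#' @param cluster_spread_km Gaussian spread of patches around their cluster
#'   centre.
#' @param domain_km landscape extent (width, height) in km.
#' @param area_median_ha,area_exceed_ha,area_p_exceed log-normal area
#'   calibration: median and the probability of exceeding
#'   `area_exceed_ha`.
#' @param params [spom_params] driving the occupancy dynamics.
#' @param years survey years (after a burn-in reaching quasi-equilibrium).
#' @param burnin_years burn-in years discarded before the survey window.
#' @param n_early_years,early_coverage the first `n_early_years` surveys
#'   cover only a random `early_coverage` fraction of patches (emulating
#'   partial early mapping).
#' @param group_intercept,group_logarea,group_dispersion zero-truncated
#'   negative binomial group-count model: log mean =
#'   `group_intercept + group_logarea * log(area)`.
#' @param det_intercept,det_logarea,det_groups per-group detection logistic
#'   model: logit p = `det_intercept + det_logarea * log(area) +
#'   det_groups * (total groups - 1)`; a patch is recorded occupied when at
#'   least one group is found. `det_intercept = Inf` means perfect
#'   detection.
#' @param gen_a0,gen_a1,gen_a2,gen_noise_sd planted network-level structural
#'   equation `f_disp = a0 + a1 * turnover - a2 * log10(pooled area) +
#'   noise`, clipped to \[0.02, 0.98\].
#' @param n_neutral_snps neutral SNPs in the panel besides the candidate.
#' @param families_per_network,larvae_per_family genotype sampling effort.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_patches = 400, n_networks = 6,
                         cluster_spread_km = 0.5, domain_km = c(50, 70),
                         area_median_ha = 0.06, area_exceed_ha = 2,
                         area_p_exceed = 0.01,
                         params = spom_params(), years = 22,
                         burnin_years = 20, n_early_years = 6,
                         early_coverage = 0.6,
                         group_intercept = 2.6, group_logarea = 0.4,
                         group_dispersion = 0.8,
                         det_intercept = 1.0, det_logarea = 0.15,
                         det_groups = 0.25,
                         gen_a0 = 0.35, gen_a1 = 1.5, gen_a2 = 0.15,
                         gen_noise_sd = 0.08, n_neutral_snps = 18,
                         families_per_network = 20, larvae_per_family = 3) {
  stopifnot(n_patches >= 1, n_networks >= 1, years >= 2,
            early_coverage > 0, early_coverage <= 1)
  if (area_p_exceed >= 0.5 && area_exceed_ha > area_median_ha)
    stop("infeasible area calibration: exceedance probability >= 0.5 ",
         "with threshold above the median")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a clustered synthetic landscape
#'
#' Patch coordinates follow a Thomas-type cluster process (cluster centres
#' uniform in the domain, patches Gaussian around their centre); areas are
#' log-normal solved from the (median, exceedance) calibration, i.e.
#' meanlog = log(median) and sdlog = (log(threshold) - log(median)) /
#' qnorm(1 - p_exceed); quality variables are drawn independently (ordinal
#' host scores, Beta-distributed fractions).
#'
#' @param config [synth_config].
#' @param seed RNG seed.
#' @return list: `landscape`, `assignment` (the generating clusters as a
#'   [network_assignment]).
#' @export
generate_landscape <- function(config = synth_config(), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n <- config$n_patches
  k <- config$n_networks
  centres <- cbind(stats::runif(k, 0, config$domain_km[1]),
                   stats::runif(k, 0, config$domain_km[2]))
  parent <- sort(rep_len(seq_len(k), n))    # balanced cluster sizes
  xy <- centres[parent, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, 0, config$cluster_spread_km), n, 2)
  sdlog <- (log(config$area_exceed_ha) - log(config$area_median_ha)) /
    stats::qnorm(1 - config$area_p_exceed)
  areas <- stats::rlnorm(n, log(config$area_median_ha), sdlog)
  df <- data.frame(
    id = sprintf("p%03d", seq_len(n)),
    x_km = xy[, 1], y_km = xy[, 2], area_ha = areas,
    host_plantago = sample(0:3, n, TRUE, prob = c(0.15, 0.35, 0.3, 0.2)),
    host_veronica = sample(0:3, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
    pct_dry = stats::rbeta(n, 1.5, 3), pct_low = stats::rbeta(n, 2, 2),
    pct_grazed = stats::rbeta(n, 1, 4))
  list(landscape = landscape(df),
       assignment = network_assignment(
         data.frame(patch_id = df$id, network_id = parent)))
}

## zero-truncated negative binomial via rejection-free inversion
rztnbinom <- function(n, mu, size) {
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, p0, 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' Generate a complete synthetic study
#'
#' End-to-end data generator: a clustered landscape, true multi-year
#' occupancy simulated from the SPOM, an observed history thinned by
#' partial early coverage and group-level imperfect detection, and a SNP
#' panel whose candidate locus follows the planted structural equation
#' linking network-level dispersive frequency to turnover and pooled
#' habitat area (neutral SNPs are independent of the dynamics). The truth
#' record stores every planted parameter for recovery reporting.
#'
#' @param config [synth_config].
#' @param seed RNG seed.
#' @return list of class `synth_study`: `landscape`, `assignment`,
#'   `q_tilde`, `history_true`, `history_observed`, `genotypes` (counts
#'   table as in [fdisp_from_counts]), `network_truth` (per-network planted
#'   f_disp and realized turnover), `truth` (named list of planted
#'   parameters).
#' @export
generate_study <- function(config = synth_config(), seed) {
  if (missing(seed)) stop("seed is required")
  gl <- generate_landscape(config, seed = seed)
  x <- gl$landscape
  set.seed(seed + 1)
  q <- quality_index(x)
  n <- n_patches(x)

  sim <- simulate_spom(x, q, config$params,
                       years = config$burnin_years + config$years - 1,
                       init = "random", init_p = 0.5, seed = seed + 2)
  keep <- (config$burnin_years + 1):(config$burnin_years + config$years)
  O_true <- sim$history$occupied[, keep, drop = FALSE]
  colnames(O_true) <- seq_len(config$years)

  set.seed(seed + 3)
  A <- x$patches$area_ha
  mu <- exp(config$group_intercept + config$group_logarea * log(A))
  G_true <- O_true * 0
  occ_idx <- which(O_true == 1)
  G_true[occ_idx] <- rztnbinom(length(occ_idx),
                               mu[(occ_idx - 1) %% n + 1],
                               config$group_dispersion)
  ## per-group detection; patch missed when every group is missed
  O_obs <- O_true; G_obs <- G_true
  if (is.finite(config$det_intercept)) {
    lp <- config$det_intercept + config$det_logarea * log(A)[(occ_idx - 1) %% n + 1] +
      config$det_groups * (G_true[occ_idx] - 1)
    found <- stats::rbinom(length(occ_idx), G_true[occ_idx], stats::plogis(lp))
    G_obs[occ_idx] <- found
    O_obs[occ_idx] <- as.numeric(found >= 1)
  }
  ## partial early coverage
  if (config$n_early_years > 0 && config$early_coverage < 1) {
    for (t in seq_len(min(config$n_early_years, config$years))) {
      masked <- stats::runif(n) > config$early_coverage
      O_obs[masked, t] <- NA; G_obs[masked, t] <- NA
    }
  }

  history_true <- occupancy_history(O_true, G_true)
  history_observed <- occupancy_history(O_obs, G_obs)

  ## planted genetics at network level
  ev <- extract_events(history_observed, gl$assignment)
  tr <- turnover_rate(ev, per = "network")
  summ <- network_summaries(gl$assignment, x)
  tr <- merge(summ[, c("network_id", "pooled_area_ha")], tr, all.x = TRUE)
  f_true <- pmin(pmax(
    config$gen_a0 + config$gen_a1 * ifelse(is.na(tr$rate), 0, tr$rate) -
      config$gen_a2 * log10(tr$pooled_area_ha) +
      stats::rnorm(nrow(tr), 0, config$gen_noise_sd), 0.02), 0.98)

  snps <- c("pgi_331", sprintf("neutral_%02d", seq_len(config$n_neutral_snps)))
  neutral_freq <- stats::runif(config$n_neutral_snps, 0.2, 0.8)
  geno <- list()
  for (i in seq_len(nrow(tr))) {
    for (s in seq_along(snps)) {
      if (s == 1) {
        qall <- 1 - sqrt(1 - f_true[i])   # C allele freq giving planted f_disp
      } else {
        qall <- stats::rbeta(1, neutral_freq[s - 1] * 30,
                             (1 - neutral_freq[s - 1]) * 30)
      }
      nind <- config$families_per_network * config$larvae_per_family
      cnt <- stats::rmultinom(1, nind,
                              c((1 - qall)^2, 2 * qall * (1 - qall), qall^2))
      geno[[length(geno) + 1]] <- data.frame(
        network_id = tr$network_id[i], snp_id = snps[s],
        n_AA = cnt[1], n_AC = cnt[2], n_CC = cnt[3],
        n_family_groups = config$families_per_network)
    }
  }
  structure(list(
    landscape = x, assignment = gl$assignment, q_tilde = q,
    history_true = history_true, history_observed = history_observed,
    genotypes = do.call(rbind, geno),
    network_truth = data.frame(network_id = tr$network_id,
                               f_disp_true = f_true,
                               turnover_rate = tr$rate,
                               pooled_area_ha = tr$pooled_area_ha),
    truth = list(params = config$params, gen_a0 = config$gen_a0,
                 gen_a1 = config$gen_a1, gen_a2 = config$gen_a2,
                 seed = seed)),
    class = "synth_study")
}

#' Parameter-recovery report
#'
#' Joins planted true values with fitted estimates and intervals and flags
#' whether each interval covers the truth.
#'
#' @param truth named numeric vector of planted parameter values.
#' @param fitted data.frame with columns `parameter`, `estimate`, `lower`,
#'   `upper`.
#' @return data.frame with `parameter`, `truth`, `estimate`, `lower`,
#'   `upper`, `covered`.
#' @export
truth_report <- function(truth, fitted) {
  stopifnot(all(c("parameter", "estimate", "lower", "upper") %in%
                  names(fitted)))
  miss <- setdiff(fitted$parameter, names(truth))
  if (length(miss) > 0)
    stop("no truth recorded for parameter(s): ", paste(miss, collapse = ", "))
  out <- fitted
  out$truth <- unname(truth[fitted$parameter])
  out$covered <- out$truth >= out$lower & out$truth <= out$upper
  out[, c("parameter", "truth", "estimate", "lower", "upper", "covered")]
}
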