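## Shared fixture builders: every data set is generated in code.

## landscape with given coordinates, unit areas and neutral quality
mk_line <- function(xs, ys = 0, areas = 1, ids = NULL) {
  n <- length(xs)
  landscape(data.frame(
    id = if (is.null(ids)) sprintf("p%02d", seq_len(n)) else ids,
    x_km = xs, y_km = rep_len(ys, n), area_ha = rep_len(areas, n),
    host_plantago = 1, host_veronica = 1,
    pct_dry = 0.5, pct_low = 0.5, pct_grazed = 0.5))
}

mk_grid <- function(nx, ny, d, areas = 1) {
  g <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1)) * d
  mk_line(g$x, g$y, areas = areas)
}

## random landscape for property tests
mk_random_landscape <- function(n, seed, box_km = 5) {
  set.seed(seed)
  landscape(data.frame(
    id = sprintf("r%03d", seq_len(n)),
    x_km = runif(n, 0, box_km), y_km = runif(n, 0, box_km),
    area_ha = rlnorm(n, log(0.06), 1.5),
    host_plantago = sample(0:3, n, TRUE), host_veronica = sample(0:3, n, TRUE),
    pct_dry = runif(n), pct_low = runif(n), pct_grazed = runif(n)))
}

## deterministic equilibrium incidence by damped fixed-point iteration:
## p = V / (V + delta) with V = A^x exp(y Q) R(p)
equilibrium_incidence <- function(x, q_tilde, delta, xexp, y,
                                  params = incidence_params()) {
  p <- rep(0.5, n_patches(x))
  for (it in 1:1000) {
    R <- patch_connectivity(x, p, params)$R
    pn <- predict_incidence(x$patches$area_ha, q_tilde, R, delta, xexp, y)
    if (max(abs(pn - p)) < 1e-12) break
    p <- 0.5 * p + 0.5 * pn
  }
  p
}

## independent eigenvalue oracle: plain power iteration on |M|
power_iteration_lambda <- function(M, tol = 1e-13, max_iter = 100000) {
  v <- rep(1, nrow(M))
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- as.vector(M %*% v)
    lam_new <- sqrt(sum(w^2))
    if (lam_new == 0) return(0)
    w <- w / lam_new
    if (abs(lam_new - lam) < tol * lam_new) return(lam_new)
    lam <- lam_new; v <- w
  }
  lam
}

## events generated directly from the hierarchical logistic turnover model
gen_glmm_events <- function(seed, n_net = 12, n_yr = 10, n_patch = 12,
                            a0 = -2, beta = c(0.8, 0.8, 0.25),
                            tau = 1.5, rho = 0.7) {
  set.seed(seed)
  d <- expand.grid(network_id = seq_len(n_net), year_from = seq_len(n_yr),
                   patch = seq_len(n_patch))
  d$patch_id <- paste0("n", d$network_id, "p", d$patch)
  ant <- rnorm(n_net * n_yr, 0, tau)
  names(ant) <- paste(rep(seq_len(n_net), n_yr), rep(seq_len(n_yr), each = n_net))
  ain <- rnorm(n_net * n_patch, 0, rho)
  names(ain) <- paste(rep(seq_len(n_net), n_patch),
                      rep(seq_len(n_patch), each = n_net))
  d$area_ha <- rlnorm(nrow(d), log(0.06), 1.5)
  d$S <- rlnorm(nrow(d), 0, 1)
  d$f_S <- runif(nrow(d))
  lp <- a0 + ant[paste(d$network_id, d$year_from)] +
    ain[paste(d$network_id, d$patch)] +
    beta[1] * as.vector(scale(d$area_ha^0.2)) +
    beta[2] * as.vector(scale(d$S)) +
    beta[3] * as.vector(scale(d$f_S))
  d$event <- rbinom(nrow(d), 1, plogis(lp))
  d$state_from <- 0
  d
}

## per-network table for the association analyses of a synthetic study
study_network_table <- function(st, capacity = FALSE) {
  gp <- fdisp_from_counts(st$genotypes)
  gp <- gp[gp$snp_id == "pgi_331", ]
  tr <- turnover_rate(extract_events(st$history_observed, st$assignment),
                      per = "network")
  summ <- network_summaries(st$assignment, st$landscape, st$history_observed)
  nt <- merge(merge(summ, tr), gp[, c("network_id", "f_disp")])
  nt$turnover_rate <- nt$rate
  nt$mean_p_lambda <- nt$mean_fraction_occupied
  if (capacity) {
    nid <- st$assignment$network_id[match(st$landscape$patches$id,
                                          st$assignment$patch_id)]
    nt$lambda_M <- vapply(nt$network_id, function(nn) {
      ix <- which(nid == nn)
      metapop_capacity(build_M(landscape(st$landscape$patches[ix, ]),
                               st$q_tilde[ix], incidence_params()))$lambda_M
    }, numeric(1))
  }
  nt
}
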