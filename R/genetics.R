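#' Dispersive-genotype frequency from genotype counts
#'
#' At the SNP pgi:c.331A>C the AC and CC genotypes have elevated flight
#' metabolic rate and dispersal rate. Under the dominance model the
#' dispersive frequency is the pooled frequency of AC and CC individuals,
#' `f_disp = (n_AC + n_CC) / n`; under the additive model it is the C allele
#' frequency `(n_AC + 2 n_CC) / (2 n)`. A network sample is flagged as
#' included when it covers more than `min_family_groups` larval family
#' groups.
#'
#' @param counts data.frame with columns `network_id`, `snp_id`, `n_AA`,
#'   `n_AC`, `n_CC`, `n_family_groups`.
#' @param model "dominance" (default) or "additive".
#' @param min_family_groups inclusion threshold (strictly more than).
#' @return data.frame with `network_id`, `snp_id`, `f_disp`,
#'   `allele_freq_C`, `n_total`, `included`.
#' @export
fdisp_from_counts <- function(counts, model = c("dominance", "additive"),
                              min_family_groups = 10) {
  model <- match.arg(model)
  stopifnot(all(c("network_id", "snp_id", "n_AA", "n_AC", "n_CC",
                  "n_family_groups") %in% names(counts)))
  n <- counts$n_AA + counts$n_AC + counts$n_CC
  if (any(n == 0)) stop("zero genotype total for network(s): ",
                        paste(counts$network_id[n == 0], collapse = ", "))
  if (any(counts$n_AA < 0 | counts$n_AC < 0 | counts$n_CC < 0))
    stop("negative genotype counts")
  dom <- (counts$n_AC + counts$n_CC) / n
  add <- (counts$n_AC + 2 * counts$n_CC) / (2 * n)
  data.frame(network_id = counts$network_id, snp_id = counts$snp_id,
             f_disp = if (model == "dominance") dom else add,
             allele_freq_C = add, n_total = n,
             included = counts$n_family_groups > min_family_groups,
             stringsAsFactors = FALSE)
}

#' Dispersive-genotype frequency among emigrants
#'
#' If dispersive genotypes emigrate Delta times as fast as the sedentary
#' homozygote, a source population with resident dispersive frequency f
#' sends out emigrants with frequency
#' `f~ = Delta f / (Delta f + (1 - f))`. Delta = 1 is the identity.
#'
#' @param f resident dispersive frequency in \[0, 1\].
#' @param Delta emigration-rate ratio (> 0), default 2.
#' @return emigrant frequency in \[0, 1\].
#' @export
emigrant_freq <- function(f, Delta = 2) {
  stopifnot(all(f >= 0 & f <= 1), Delta > 0)
  Delta * f / (Delta * f + (1 - f))
}

#' Dispersive-genotype frequency among immigrants
#'
#' The frequency of dispersive genotypes among immigrants arriving at each
#' patch: the connectivity-share weighted average of the source patches'
#' emigrant frequencies,
#' `f^S_i = sum_j w_ij f~_j` with
#' `w_ij = p_j A_j^em exp(-alpha d_ij) / sum_k p_k A_k^em exp(-alpha d_ik)`,
#' i.e. each source's share of the connectivity S_i. A patch with zero total
#' connectivity receives no immigrants and gets NA.
#'
#' @param x landscape.
#' @param f per-patch resident dispersive frequency (landscape order); in
#'   practice the network-level estimate of the patch's network.
#' @param occupancy per-patch source occupancy p_j in \[0, 1\].
#' @param params [spom_params] (uses em, alpha, Delta).
#' @return named vector of per-patch immigrant frequencies.
#' @export
immigrant_freq <- function(x, f, occupancy, params = spom_params()) {
  stopifnot(length(f) == n_patches(x), length(occupancy) == n_patches(x))
  occupancy <- ifelse(is.na(occupancy), 0, occupancy)
  ft <- emigrant_freq(ifelse(is.na(f), 0, f), params$Delta)
  w <- occupancy * x$patches$area_ha^params$em
  K <- exp(-params$alpha * x$dist)
  diag(K) <- 0
  tot <- as.vector(K %*% w)
  num <- as.vector(K %*% (w * ft))
  out <- ifelse(tot > 0, num / tot, NA_real_)
  stats::setNames(out, x$patches$id)
}

#' Network-level association regressions for dispersal genetics
#'
#' The headline network-level analyses relating the dispersive genotype
#' frequency to metapopulation dynamics, run over networks with included
#' genetic samples:
#' (a) OLS of f_disp on turnover rate and log10 pooled habitat area;
#' (b) OLS of mean weighted occupancy on lambda_M and f_disp;
#' (c) simple regressions of mean weighted occupancy on each predictor
#' alone;
#' (d) two-sample t-test of f_disp between networks persistent throughout
#' the study and those extinct for at least `extinct_years` years.
#'
#' @param network_table data.frame with columns `f_disp`, `turnover_rate`,
#'   `pooled_area_ha`, `mean_p_lambda`, `lambda_M` and (for d) logical
#'   `long_extinct`.
#' @return list of class `network_association` with elements `fdisp_model`,
#'   `size_model`, `size_simple` (list), `persistence_ttest` (NULL if
#'   `long_extinct` absent or degenerate), each carrying R2 / F / p.
#' @export
network_association <- function(network_table) {
  nt <- network_table[stats::complete.cases(
    network_table[, c("f_disp", "turnover_rate", "pooled_area_ha",
                      "mean_p_lambda", "lambda_M")]), ]
  if (nrow(nt) < 4) stop("fewer than 4 networks with complete data")
  nt$log_area <- log10(nt$pooled_area_ha)

  preds <- c("turnover_rate", "log_area")
  keep <- preds[vapply(preds, function(v) stats::sd(nt[[v]]) > 0, logical(1))]
  if (length(keep) < length(preds))
    warning("dropping zero-variance predictor(s): ",
            paste(setdiff(preds, keep), collapse = ", "))
  lm_summ <- function(fit) {
    sm <- suppressWarnings(summary(fit))
    f <- sm$fstatistic
    if (is.null(f)) f <- c(value = NA_real_, numdf = NA_real_, dendf = NA_real_)
    list(fit = fit, R2 = sm$r.squared, coefficients = sm$coefficients,
         F = unname(f["value"]), df = unname(f[c("numdf", "dendf")]),
         p_value = stats::pf(f["value"], f["numdf"], f["dendf"],
                             lower.tail = FALSE))
  }
  a <- lm_summ(stats::lm(stats::reformulate(keep, "f_disp"), data = nt))
  b <- lm_summ(stats::lm(mean_p_lambda ~ lambda_M + f_disp, data = nt))
  cc <- list(lambda_M = lm_summ(stats::lm(mean_p_lambda ~ lambda_M, nt)),
             f_disp = lm_summ(stats::lm(mean_p_lambda ~ f_disp, nt)))
  d <- NULL
  if ("long_extinct" %in% names(nt)) {
    le <- nt$long_extinct
    if (length(unique(le)) == 2 && min(table(le)) >= 2)
      d <- stats::t.test(nt$f_disp[!le], nt$f_disp[le], var.equal = TRUE)
  }
  structure(list(fdisp_model = a, size_model = b, size_simple = cc,
                 persistence_ttest = d, n_networks = nrow(nt)),
            class = "network_association")
}

#' SNP-panel specificity check (QQ comparison)
#'
#' Runs the network-level association tests for every SNP in a panel and
#' compares the sorted observed p-values with draws from Uniform(0, 1): for
#' a panel of SNPs unrelated to the dynamics the QQ regression slope should
#' be about 1, and a causal SNP stands out as a low-p outlier. Two test
#' modes mirror the two association analyses: `"turnover"` uses the F-test
#' p of the regression of allele frequency on turnover rate + log10 pooled
#' area; `"size"` uses the t-test p of the SNP effect on mean weighted
#' occupancy alongside lambda_M.
#'
#' @param per_snp data.frame with one row per network x SNP: columns
#'   `snp_id`, `network_id`, `freq` (allele frequency), plus per-network
#'   `turnover_rate`, `pooled_area_ha`, `mean_p_lambda`, `lambda_M`.
#' @param mode "turnover" or "size".
#' @param n_replicates uniform replicate draws (default 100).
#' @param expected "sampled" (mean of sorted uniform replicates, the
#'   default) or "analytic" (i / (n + 1) quantiles).
#' @param exclude SNP ids to exclude from the slope regression (declared
#'   outliers).
#' @param min_networks SNPs observed in fewer networks are dropped with a
#'   warning.
#' @return list of class `snp_panel_qq`: `p_values` (named, sorted),
#'   `slope` (observed QQ regression slope excluding `exclude`),
#'   `replicate_slope_mean`, `replicate_slope_sd`, `expected`, `mode`.
#' @export
snp_panel_qq <- function(per_snp, mode = c("turnover", "size"),
                         n_replicates = 100,
                         expected = c("sampled", "analytic"),
                         exclude = character(), min_networks = 8) {
  mode <- match.arg(mode); expected <- match.arg(expected)
  snps <- unique(per_snp$snp_id)
  if (length(snps) < 3) stop("need at least 3 SNPs")
  pv <- vapply(snps, function(s) {
    d <- per_snp[per_snp$snp_id == s, ]
    d <- d[stats::complete.cases(d[, c("freq", "turnover_rate",
                                       "pooled_area_ha", "mean_p_lambda",
                                       "lambda_M")]), ]
    if (nrow(d) < min_networks) return(NA_real_)
    if (mode == "turnover") {
      fit <- stats::lm(freq ~ turnover_rate + log10(pooled_area_ha), data = d)
      f <- summary(fit)$fstatistic
      stats::pf(f["value"], f["numdf"], f["dendf"], lower.tail = FALSE)
    } else {
      fit <- stats::lm(mean_p_lambda ~ lambda_M + freq, data = d)
      summary(fit)$coefficients["freq", "Pr(>|t|)"]
    }
  }, numeric(1))
  names(pv) <- snps
  if (anyNA(pv)) {
    warning("SNP(s) dropped for insufficient network coverage: ",
            paste(names(pv)[is.na(pv)], collapse = ", "))
    pv <- pv[!is.na(pv)]
  }
  n <- length(pv)
  reps <- matrix(stats::runif(n_replicates * n), n_replicates, n)
  reps <- t(apply(reps, 1, sort))
  exp_q <- if (expected == "sampled") colMeans(reps) else seq_len(n) / (n + 1)

  obs_sorted <- sort(pv)
  use <- !(names(obs_sorted) %in% exclude)
  slope <- unname(stats::coef(stats::lm(obs_sorted[use] ~ exp_q[use]))[2])
  rep_slopes <- apply(reps, 1, function(r)
    stats::coef(stats::lm(r[use] ~ exp_q[use]))[2])
  structure(list(p_values = obs_sorted, slope = slope,
                 replicate_slope_mean = mean(rep_slopes),
                 replicate_slope_sd = stats::sd(rep_slopes),
                 expected = exp_q, mode = mode),
            class = "snp_panel_qq")
}
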