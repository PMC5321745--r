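#' Equilibrium incidence of patch occupancy
#'
#' The probability that a patch is occupied at stochastic equilibrium,
#' `p = C / (C + E)`, written in fittable form as `p = V / (V + delta)` with
#' `V = A^x exp(y Q) R`, where A is patch area (ha), Q the composite quality
#' index, R the area-free connectivity (see [patch_connectivity]), delta the
#' extinction threshold and x the pooled area exponent. Setting `y = 0`
#' gives the quality-free first-stage model. A patch with R = 0 cannot be
#' colonized and has incidence 0.
#'
#' @param A area (ha), > 0.
#' @param q_tilde quality index.
#' @param R area-free connectivity, >= 0.
#' @param delta extinction threshold (> 0).
#' @param x area exponent.
#' @param y quality effect.
#' @return predicted incidence in \[0, 1\].
#' @export
predict_incidence <- function(A, q_tilde, R, delta, x, y = 0) {
  stopifnot(all(A > 0), all(R >= 0), delta > 0)
  V <- A^x * exp(y * q_tilde) * R
  V / (V + delta)
}

#' Two-stage nonlinear fit of the equilibrium incidence model
#'
#' Estimates the extinction threshold delta, the area exponent x and (stage
#' 2) the habitat-quality effect y by nonlinear least squares of observed
#' per-patch incidence on [predict_incidence]. Following the incidence
#' function fitting tradition, the connectivity term uses the observed
#' multi-year mean occupancies as the source terms p_j, held fixed
#' (no iteration), with alpha = 1 and em = 0.2 assumed. The fit is
#' restricted to networks likely to hold viable metapopulations: by default
#' those with more than `min_patches` patches and mean observed occupancy
#' above `min_occupancy`; connectivity is still computed over the whole
#' landscape so immigration from outside the selected networks is counted.
#'
#' Stage 1 fixes y = 0 (quality-free); stage 2 frees y. Confidence
#' intervals are asymptotic (estimate +/- 1.96 standard errors from the
#' least-squares covariance).
#'
#' @param incidence output of [incidence_from_history].
#' @param x landscape (same patch set and order).
#' @param assignment [network_assignment].
#' @param q_tilde quality index vector (stage 2; ignored in stage 1).
#' @param stage 1 or 2.
#' @param min_patches,min_occupancy network selection filter.
#' @param networks optional explicit vector of network ids to fit on,
#'   bypassing the filter.
#' @param params kernel/emigration assumptions; only `alpha` and `em` are
#'   used. Default [incidence_params] (alpha = 1, em = 0.2).
#' @return list of class `incidence_fit`: `estimate` (named vector),
#'   `se`, `ci95` (matrix), `stage`, `n_patches_used`, `n_networks_used`,
#'   `fit` (the nls object), `boundary` (TRUE when delta ran to the lower
#'   boundary, i.e. the data carry no signal of an extinction threshold).
#' @export
fit_incidence <- function(incidence, x, assignment, q_tilde = NULL,
                          stage = 2, min_patches = 50, min_occupancy = 0.05,
                          networks = NULL, params = incidence_params()) {
  stopifnot(stage %in% 1:2, nrow(incidence) == n_patches(x))
  if (stage == 2 && is.null(q_tilde))
    stop("stage 2 requires a quality index")
  if (is.null(q_tilde)) q_tilde <- rep(0, n_patches(x))

  nid <- assignment$network_id[match(x$patches$id, assignment$patch_id)]
  if (anyNA(nid)) stop("assignment does not cover the landscape")
  if (is.null(networks)) {
    npn <- tapply(rep(1, length(nid)), nid, sum)
    mocc <- tapply(incidence$p_bar, nid, mean, na.rm = TRUE)
    networks <- as.integer(names(npn))[npn > min_patches &
                                         !is.na(mocc) & mocc > min_occupancy]
    if (length(networks) == 0)
      stop("no network passes the selection filter (>", min_patches,
           " patches, mean occupancy > ", min_occupancy, ")")
  }

  conn <- patch_connectivity(x, incidence$p_bar, params)
  use <- nid %in% networks & incidence$defined
  df <- data.frame(p = incidence$p_bar[use], A = x$patches$area_ha[use],
                   Q = q_tilde[use], R = conn$R[use])

  if (all(df$p >= 1 - 1e-9)) {
    ## saturated occupancy: the least-squares solution diverges to delta = 0
    warning("all selected patches always occupied; ",
            "delta ran to the lower boundary")
    pn <- if (stage == 1) c("delta", "x") else c("delta", "x", "y")
    est <- stats::setNames(c(0, rep(NA_real_, length(pn) - 1)), pn)
    return(structure(list(estimate = est,
                          se = stats::setNames(rep(NA_real_, length(pn)), pn),
                          ci95 = cbind(lower = est * NA, upper = est * NA),
                          stage = stage, n_patches_used = nrow(df),
                          n_networks_used = length(networks),
                          networks = networks, fit = NULL, boundary = TRUE),
                     class = "incidence_fit"))
  }
  if (stage == 1) {
    fml <- p ~ predict_incidence(A, Q, R, delta, x, 0)
    start <- c(delta = 1, x = 0.5)
    lower <- c(delta = 1e-8, x = -5); upper <- c(delta = Inf, x = 5)
  } else {
    fml <- p ~ predict_incidence(A, Q, R, delta, x, y)
    start <- c(delta = 1, x = 0.5, y = 0)
    lower <- c(delta = 1e-8, x = -5, y = -50); upper <- c(delta = Inf, x = 5, y = 50)
  }
  fit <- minpack.lm::nlsLM(fml, data = df, start = start,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  boundary <- est["delta"] < 1e-6
  if (boundary)
    warning("delta ran to the lower boundary; occupancy data are saturated")
  structure(list(estimate = est, se = se, ci95 = ci, stage = stage,
                 n_patches_used = nrow(df),
                 n_networks_used = length(networks),
                 networks = networks, fit = fit, boundary = boundary),
            class = "incidence_fit")
}

#' @rdname fit_incidence
#' @param ... passed on to [fit_incidence].
#' @export
fit_stage1 <- function(incidence, x, assignment, ...)
  fit_incidence(incidence, x, assignment, stage = 1, ...)

#' @rdname fit_incidence
#' @export
fit_stage2 <- function(incidence, x, assignment, q_tilde, ...)
  fit_incidence(incidence, x, assignment, q_tilde = q_tilde, stage = 2, ...)

#' @export
print.incidence_fit <- function(x, ...) {
  cat("equilibrium incidence fit (stage ", x$stage, "), ",
      x$n_patches_used, " patches in ", x$n_networks_used, " networks\n",
      sep = "")
  print(cbind(estimate = x$estimate, se = x$se, x$ci95))
  invisible(x)
}

#' Logistic regression of observed incidence on model prediction and quality
#'
#' Tests whether the four raw habitat-quality variables explain occupancy
#' beyond the quality-free (stage 1) equilibrium prediction: a binomial GLM
#' (logit link, weights = years surveyed) of observed incidence on the
#' predicted incidence plus host-plant abundance and the dry / grazed / low
#' fractions. The pseudo-R-squared reported is the squared Pearson
#' correlation between observed and fitted values.
#'
#' @param incidence output of [incidence_from_history].
#' @param predicted_p per-patch stage-1 predicted incidence in \[0, 1\].
#' @param x landscape (source of the quality columns).
#' @param host how to combine host scores, as in [quality_index].
#' @return list of class `quality_logistic_fit` with `coefficients` table
#'   (estimate, se, z, p), `pseudo_r2`, `separation` flag, `fit`.
#' @export
fit_quality_logistic <- function(incidence, predicted_p, x,
                                 host = c("max", "sum")) {
  host <- match.arg(host)
  stopifnot(all(predicted_p >= 0 & predicted_p <= 1))
  p <- x$patches
  host_raw <- switch(host, max = pmax(p$host_plantago, p$host_veronica),
                     sum = p$host_plantago + p$host_veronica)
  df <- data.frame(p_bar = incidence$p_bar, w = incidence$n_observed_years,
                   pred = predicted_p, host = host_raw,
                   dry = p$pct_dry, grazed = p$pct_grazed, low = p$pct_low)
  df <- df[incidence$defined, ]
  ## drop zero-variance quality columns (nothing to estimate)
  terms <- c("pred", "host", "dry", "grazed", "low")
  keep <- terms[vapply(terms, function(v) stats::var(df[[v]]) > 0, logical(1))]
  if (length(keep) < length(terms))
    warning("dropping zero-variance predictor(s): ",
            paste(setdiff(terms, keep), collapse = ", "))
  fml <- stats::reformulate(keep, response = "p_bar")
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = df, weights = df$w))
  sm <- stats::summary.glm(fit)$coefficients
  separation <- any(abs(sm[, "Estimate"]) > 15)
  if (separation) warning("possible separation: extreme coefficient(s)")
  structure(list(
    coefficients = sm,
    pseudo_r2 = stats::cor(df$p_bar, stats::fitted(fit))^2,
    separation = separation, fit = fit),
    class = "quality_logistic_fit")
}

#' Network-level goodness of fit of the equilibrium prediction
#'
#' Two complementary statistics: (i) the Pearson correlation (with its
#' t-test) between observed mean weighted occupancy and the Eq-1 prediction
#' `1 - delta / lambda_M` over the viable networks, and (ii) the R-squared
#' of the linear regression of observed mean weighted occupancy on lambda_M
#' over all networks.
#'
#' @param network_table data.frame with columns `lambda_M`, `mean_p_lambda`.
#' @param delta extinction threshold.
#' @return list with `r_viable`, `t`, `df`, `p_value`, `n_viable`,
#'   `R2_all`, `F_all`.
#' @export
network_fit_statistics <- function(network_table, delta) {
  stopifnot(all(c("lambda_M", "mean_p_lambda") %in% names(network_table)))
  v <- network_table$lambda_M > delta
  out <- list(r_viable = NA_real_, t = NA_real_, df = NA_integer_,
              p_value = NA_real_, n_viable = sum(v))
  if (sum(v) >= 3) {
    pred <- 1 - delta / network_table$lambda_M[v]
    obs <- network_table$mean_p_lambda[v]
    if (stats::sd(obs) > 0 && stats::sd(pred) > 0) {
      ct <- stats::cor.test(obs, pred)
      out$r_viable <- unname(ct$estimate)
      out$t <- unname(ct$statistic)
      out$df <- unname(ct$parameter)
      out$p_value <- ct$p.value
    } else warning("zero variance; correlation undefined")
  }
  lmfit <- stats::lm(mean_p_lambda ~ lambda_M, data = network_table)
  sm <- summary(lmfit)
  out$R2_all <- sm$r.squared
  out$F_all <- unname(sm$fstatistic["value"])
  out
}
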