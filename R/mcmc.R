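## Adaptive random-walk Metropolis on an unconstrained parameter vector.
## Proposal covariance adapts towards 2.38^2/d * cov(history) during warmup
## (Haario-style), with a global scale tuned to ~25% acceptance; adaptation
## is frozen after warmup so the sampled chain is Markov.
adaptive_metropolis <- function(logpost, init, n_warmup = 1000, n_iter = 1000,
                                scale0 = 0.1) {
  d <- length(init)
  theta <- init
  lp <- logpost(theta)
  if (!is.finite(lp)) stop("initial value has non-finite posterior density")
  Sig <- diag(scale0^2, d)
  Lc <- chol(Sig)
  lsc <- 0
  total <- n_warmup + n_iter
  hist_all <- matrix(NA_real_, total, d)
  acc_window <- 0; win <- 0
  n_acc <- 0
  for (it in seq_len(total)) {
    prop <- theta + drop(crossprod(Lc, stats::rnorm(d))) * exp(lsc)
    lp_prop <- logpost(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop
      acc_window <- acc_window + 1
      if (it > n_warmup) n_acc <- n_acc + 1
    }
    hist_all[it, ] <- theta
    win <- win + 1
    if (it <= n_warmup && win == 50) {
      rate <- acc_window / win
      lsc <- lsc + (rate - 0.25) / sqrt(it / 50)
      if (it >= 200) {
        cv <- stats::cov(hist_all[max(1, it - 999):it, , drop = FALSE])
        Sig <- cv * 2.38^2 / d + diag(1e-8, d)
        Lc <- chol(Sig)
      }
      acc_window <- 0; win <- 0
    }
  }
  list(draws = hist_all[(n_warmup + 1):total, , drop = FALSE],
       accept_rate = n_acc / n_iter)
}

## Split-Rhat (Gelman-Rubin) over a list of equally long chains (vectors).
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    m <- length(ch) %/% 2
    list(ch[1:m], ch[(m + 1):(2 * m)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
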