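# metacap

Spatially realistic metapopulation analysis of highly fragmented
landscapes — for ecologists working with multi-year patch-occupancy
surveys of species living in networks of small habitat patches (the
motivating system is a checkerspot butterfly censused annually in ~4,000
dry meadows).

At the core is the **metapopulation capacity** framework. A landscape of
patches with areas `A_i`, qualities `Q_i` and pairwise distances `d_ij`
defines the matrix

    m_ii = 0,    m_ij = A_i^x * exp(y*Q_i) * A_j^em * exp(-alpha*d_ij)

whose leading eigenvalue `lambda_M` (the metapopulation capacity)
integrates the amount, quality and spatial configuration of habitat. A
patch network supports a viable metapopulation precisely when `lambda_M`
exceeds the species' **extinction threshold** `delta = e/c` (extinction
over colonization rate), and the equilibrium weighted occupancy is
`p_lambda* = 1 - delta/lambda_M`. The package provides both routes to
`delta`: a two-stage nonlinear fit of the equilibrium incidence
`p = V/(V + delta)`, `V = A^x exp(y*Q) R`, to multi-year occupancy
fractions, and Bayesian estimation of the annual colonization/extinction
rates `(e, c, ex, im, em, alpha, y)` from observed turnover events.
Around this sit connectivity-based clustering of patches into
semi-independent networks, hierarchical logistic turnover models with a
dispersive-genotype covariate (*Pgi*), network-level association
regressions and a SNP-panel specificity check, detection GLMs for control
surveys, a stochastic patch occupancy simulator, and a synthetic-study
generator that makes every stage testable without any field data.

## Worked example

A complete synthetic study — clustered landscape, 22 years of SPOM
dynamics, imperfect detection — analysed end to end:

```r
library(metacap)
study <- generate_study(synth_config(n_patches = 400, n_networks = 6), seed = 11)
x <- study$landscape
x
#> landscape: 400 patches, 91.19 ha pooled area

q <- quality_index(x)
nid <- study$assignment$network_id[match(x$patches$id, study$assignment$patch_id)]
lambda <- sapply(sort(unique(nid)), function(nn) {
  ix <- which(nid == nn)
  metapop_capacity(build_M(landscape(x$patches[ix, ]), q[ix],
                           incidence_params()))$lambda_M
})
round(lambda, 2)
#> [1]  9.88 10.12  9.60 12.93 11.23 12.47

inc <- fit_stage2(incidence_from_history(study$history_observed),
                  x, study$assignment, q)
inc
#> equilibrium incidence fit (stage 2), 400 patches in 6 networks
#>        estimate         se     lower     upper
#> delta 3.6653097 0.27877979 3.1189013 4.2117181
#> x     0.5960374 0.02939435 0.5384245 0.6536503
#> y     1.1823998 0.15756816 0.8735662 1.4912334

classify_networks(lambda, delta = inc$estimate["delta"])$n_viable
#> [1] 6
round(equilibrium_prediction(lambda, inc$estimate["delta"])$p_lambda_star, 3)
#> [1] 0.629 0.638 0.618 0.717 0.674 0.706
```

The study was simulated at `e = 0.38, c = 0.11` (`delta = 3.45`) with
`ex + im = 0.67`; the fitted threshold `3.67 (3.12–4.21)` and exponent
`0.60` recover them from the observed occupancy pattern alone. All six
synthetic networks sit above the threshold, with predicted equilibrium
weighted occupancies of 0.6–0.7 — matching the simulated time series these
networks actually produce. `estimate_rates()` gives the complementary
event-based posterior, `fit_turnover_glmm()` the covariate effects on
single colonization/extinction events, and `network_association()` /
`snp_panel_qq()` the dispersal-genetics layer.

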