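# focalecol

Taxon-centric ecology for 16S rRNA amplicon surveys.

Large gut-microbiome cohorts make it possible to study one organism of
interest — a *focal taxon* such as the oxalate-degrading gut bacterium
*Oxalobacter formigenes* — across thousands of hosts: who carries it, how
its marker OTUs co-occur, which host features predict carriage and
abundance, how the surrounding community differs when it is present, and
whether the ecological networks it belongs to are more robust. `focalecol`
implements that analysis as a tested, reusable R pipeline, together with a
synthetic-cohort generator with known ground truth so every stage can be
validated without any external data.

## The models at the core

**Zero-inflated negative binomial regression with read-depth offsets.**
Focal counts `y_i` in a survey are mostly zero and overdispersed when
positive. `zinb_fit()` maximises the joint likelihood of

    logit(pi_i) = x_i' gamma + log T_i        (structural absence)
    log(mu_i)   = x_i' beta  + log T_i        (NB mean, dispersion k)
    y_i = 0 with prob. pi_i, else y_i ~ NB(mu_i, k)

where `T_i` is the sample's total read count; the offset (coefficient
fixed at 1) enters both components, so the count model describes the
focal taxon's *proportion*. ZIP is the `k -> Inf` family for the
goodness-of-fit comparison (`compare_models()`), and covariate effects
are summarised as overall fitted mean proportions by the
average-predicted-value method (`apv_proportions()`).

**Compositional network inference.** `infer_network()` aggregates OTUs to
species, keeps species present in ≥ 20% of samples, applies the centered
log-ratio transform, runs Meinshausen–Bühlmann neighborhood selection
(per-species lasso) along a 100-point penalty path, selects the penalty by
StARS stability (20 subsamples, instability threshold 0.05), and signs
each edge by the averaged beta matrix.

**Network resilience.** Natural connectivity
`ln(mean(exp(lambda_i)))/(N - ln N)` over adjacency eigenvalues, targeted
and random attack simulations, and resampled connectivity distributions
for focal-positive vs focal-negative samples (`attack_simulation()`,
`connectivity_distribution()`), with prevalence/abundance-matched control
taxa (`select_controls()`).

Supporting stages: depth/site filtering with first-specimen
deduplication, hypergeometric co-occurrence tests, exact small-sample
Mann–Whitney tests, longitudinal colonization groups, rarefaction, Chao1 /
Shannon / Faith PD, unweighted UniFrac and Bray–Curtis, PCoA, PERMANOVA,
and V4 primer extraction / percent-identity utilities for marker
sequences. See the methods vignette
(`vignettes/focal-taxon-ecology.Rmd`) for assumptions, parameter
defaults, and numerical choices.

## Worked example

Simulate a cohort whose generating model is known, then run the screening
and modelling stages:

```r
library(focalecol)
spec <- cohort_spec(n_subjects = 400, seed = 1)
spec$covariates <- list(
  list(name = "age", type = "continuous", mean = 45, sd = 15, missing_rate = 0),
  list(name = "sex", type = "categorical", levels = c("Female", "Male"),
       missing_rate = 0))
ft <- focal_model_truth(
  gamma = matrix(c(qlogis(0.6) - log(2e4), 0.02, -0.5), ncol = 1,
                 dimnames = list(c("(Intercept)", "age", "sex_Male"), NULL)),
  beta  = matrix(c(-8.5, 0.01, 0.3), ncol = 1,
                 dimnames = list(c("(Intercept)", "age", "sex_Male"), NULL)),
  dispersion = 1, coupling = 1.5,
  covariates = c("age", "sex"), references = c(sex = "Female"))
ds <- assemble_dataset(spec, ft, community_truth(p = 30, graph = "chain"))

fl  <- filter_and_dedup(ds$counts, ds$meta, min_depth = 10000, site = "feces")
det <- detect_focal(fl$counts, ds$focal_ids)
summarize_focal(fl$counts, det)
#>     taxon prevalence_percent share_percent geo_mean_rel_abundance
#> 1 focal_1               23.9           100               0.000313

y <- rowSums(fl$counts[, ds$focal_ids, drop = FALSE])
d <- build_design(fl$meta, c("age", "sex"), references = c(sex = "Female"))
zinb_fit(y[d$keep], d)
#> Zero-inflated negative binomial regression with log-read-count offset
#> n = 352  df = 7  logLik = -447.0  AIC = 907.9
#>
#> Zero (logistic) component:
#> (Intercept)         age    sex_Male
#>     -9.2952      0.0134     -0.4461
#>
#> Count component:
#> (Intercept)         age    sex_Male
#>     -8.6907      0.0145      0.4632
#>
#> Dispersion k = 1.1024
```

The focal taxon is detected in 23.9% of retained subjects with a
geometric-mean relative abundance of 3.1e-4 in carriers, and the fitted
coefficients recover the generating values (gamma intercept
`qlogis(0.6) - log(2e4) = -9.50`, beta intercept `-8.5`, `k = 1`) within
sampling error. Continuing with the network stages:

```r
net <- infer_network(fl$counts, seed = 2)
net
#> Signed association network: 31 species, 33 edges (-: 4, +: 29); lambda = 0.152
natural_connectivity(net)
#> [1] 0.0324
```

which recovers the planted 29-edge chain (plus the focal taxon's
associations) with signed edges. `run_pipeline()` chains all five stages
and writes TSV/JSON artifacts plus a manifest;
`inst/scripts/run_pipeline.R` wraps it for the shell.

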