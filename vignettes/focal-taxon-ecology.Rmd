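---
title: "Methods: focal-taxon ecology in 16S microbiome surveys"
author: "focalecol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focal-taxon ecology in 16S microbiome surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalecol)
```

# Overview

`focalecol` analyses a 16S rRNA amplicon survey *around one organism of
interest* — a focal taxon such as *Oxalobacter formigenes* in human gut
cohorts. Rather than profiling a whole community symmetrically, it asks a
taxon-centric set of questions: where and how often is the focal taxon
detected, do its marker OTUs co-occur, which host features predict its
presence and abundance, does the surrounding community differ when it is
present, which species does it interact with, and are the communities it
inhabits more robust as ecological networks?

The package is organised as a sequence of stages (screening, zero-inflated
abundance modelling, diversity, compositional network inference, network
resilience), each usable on its own and chained by `run_pipeline()`. A
synthetic-cohort generator with fully known ground truth accompanies every
stage, so the whole analysis can be validated end to end without any
external download.

# Screening and co-occurrence

Samples are filtered by total read count (default at least 10,000
reads/sample, boundary inclusive) and body site, and subjects contributing
several specimens are represented by their earliest retained one, so the
analysis unit is the subject. Detection of a focal OTU uses a read-count
threshold of 1 by default: published studies of this kind rarely state a
higher presence rule, and the threshold is a parameter of
`detect_focal()` for users who want one.

Prevalence, per-OTU shares of the summed focal reads, and the geometric
mean relative abundance *over detected samples only* summarise the focal
OTUs (`summarize_focal()`); an undetected OTU reports `NA` rather than 0
for its geometric mean, since the quantity is undefined.

Co-occurrence of two focal OTUs is tested with the upper-tail
hypergeometric probability of an overlap at least as large as observed,
conditioning on both marginal detection counts in the filtered sample
universe (`overlap_test()`) — the classical overlap-statistics test.
Abundance elevation under co-detection (`codetection_shift()`) and the
longitudinal group II vs III comparison (`longitudinal_groups()`) use
one-sided Mann–Whitney tests. `rank_test()` switches from exact
enumeration of all group assignments to the tie-corrected normal
approximation at a combined sample size of 12; mid-ranks handle ties.
Longitudinal trajectories partition multi-sample subjects into never
(I), intermittently (II), and always (III) colonised; the comparison of
group II against group III abundances is accompanied by a two-sided
depth comparison of the same sample sets, to show that sequencing effort
does not explain the abundance difference.

# Zero-inflated abundance model

Focal-taxon read counts in population surveys are dominated by zeros
(most people do not carry the organism) and are overdispersed when
present. The core model is therefore a two-component mixture fitted by
`zinb_fit()`:

* a **logistic component** for structural absence,
  `logit(pi_i) = x_i' gamma + log T_i`;
* a **count component**, negative binomial with dispersion `k` (or
  Poisson in the `k -> Inf` limit),
  `log(mu_i) = x_i' beta + log T_i`,

where `T_i` is the total read count of sample `i`. The offset enters
*both* linear predictors with its coefficient fixed at 1, taken
literally: the count component thereby models the focal taxon's
proportion of the community, and deeper sequencing mechanically raises
the chance of detecting a fixed proportion. An observed zero can come
from either component; the likelihood mixes them exactly.

Fitting is direct joint maximum likelihood over `(gamma, beta, log k)`
with an analytic gradient, BFGS, and two starting points (a null model
and a two-stage logistic/count start), followed by a polishing pass; the
reported optimum has a scaled gradient norm below 1e-5 in routine use.
`log k` keeps the dispersion unconstrained. Standard errors come from a
central-difference Hessian of the analytic gradient; Wald z tests are
reported per dummy level with no multiplicity correction, which is the
convention for covariate tables of this kind. EM was not used: the joint
likelihood is smooth and low-dimensional, and a gradient method with
restarts is simpler to verify.

Categorical covariates are dummy-coded against stated reference levels
(`build_design()`); missing values of a categorical covariate form a
hidden `"(missing)"` category so those samples stay in the model, while
samples missing a *continuous* covariate (age) are excluded — the
hidden-category device has no continuous analogue. The univariate screen
(`univariate_screen()`) fits each candidate covariate alone in a
logistic and a negative binomial regression, both with the log-depth
offset, and passes covariates with any-level p below 0.1 in either;
age, sex, and race are retained regardless as baseline covariates. The
NB screen uses all samples (zeros included); a `positives_only` flag
provides the defensible alternative of screening detected samples only.

ZINB is compared with ZIP by AIC, BIC, and the likelihood-ratio test on
one degree of freedom (`compare_models()`); since the dispersion sits on
the boundary of its space under the null, the chi-square reference is
conservative, which is acceptable because the test is used
directionally. Covariate effects are summarised as **overall fitted
mean proportions** by the average-predicted-value method
(`apv_proportions()`): set every sample's covariate to a level, predict
the unconditional mean count `(1 - pi) mu`, average, and divide by the
mean total reads. For an offset-only Poisson fit this reduces exactly to
the ratio of total focal reads to total reads, which the tests verify to
1e-8.

# Diversity

Alpha diversity is computed on rarefied counts (subsampling without
replacement; samples shallower than the target are flagged and dropped,
not an error). Metrics: observed OTUs; Shannon entropy in log base 2
(the convention of the QIIME-1 lineage of pipelines); Chao1 in its
classical form `S + F1^2/(2 F2)` with the bias-corrected
`S + F1(F1-1)/(2(F2+1))` exactly when doubletons are absent; and Faith
phylogenetic diversity including the path to the root (via picante).
Group comparisons by the number of focal OTUs detected use both plain
Welch t tests (a pooled-variance flag is available) and Monte-Carlo
permutation t tests with 999 label permutations; with the add-one
correction the smallest attainable permutation p is 1/1000. Bonferroni
correction multiplies by the number of pairwise comparisons in a panel.

Beta diversity offers Bray–Curtis on raw counts and unweighted UniFrac —
the fraction of covered branch length unique to one sample — implemented
directly on the `ape` edge structure and verified in the tests against a
brute-force branch enumeration oracle. Ordination is classical PCoA on
the double-centred squared distances; negative eigenvalues of
non-Euclidean dissimilarities are reported, never silently dropped.
Group separation uses a one-factor PERMANOVA with pseudo-F and
`p = (#{F* >= F} + 1)/(n_perm + 1)` over 1000 permutations by default
(cross-checked against `vegan::adonis2`), and `group_distance_compare()`
partitions pairwise distances into intra- and intergroup sets with
means, SEMs, Bonferroni-corrected t tests, and an optional within-group
bootstrap of the mean intragroup distance.

# Compositional network inference

Amplicon counts are compositional: only relative information survives
sequencing. The network stage therefore aggregates OTUs to species,
keeps species detected in at least 20% of samples (inclusive), adds a
pseudocount of 1 (the convention of compositionally aware network
tools), and applies the centered log-ratio transform, whose rows sum to
zero. Conditional dependence is then estimated by
Meinshausen–Bühlmann neighborhood selection: an L1-penalised regression
of every species' CLR column on all others (via glmnet, columns
standardized internally, coefficients reported on the standardized
scale), with an edge wherever *either* directional coefficient is
nonzero (union rule, the MB default).

The penalty is chosen by StARS: over a grid of 100 penalties log-spaced
from the largest absolute CLR correlation down to a fifth of it, edge
selection frequencies are estimated from 20 random subsamples of size
`ceiling(10 sqrt(n))` (for n > 144, else 0.8 n), the graph instability
`D(lambda) = mean(2 theta (1 - theta))` is monotonized from the sparsest
end, and the densest penalty with monotonized instability at most
beta = 0.05 is selected. If no penalty qualifies — which happens for
small species panels, where the instability is averaged over few node
pairs and CLR collinearity keeps a handful of edges flickering even at
the top of the path — the sparsest penalty is returned with a warning,
which is the stability-selection notion of "no reliable edges". Plain
StARS is implemented; the early-stopping "bstars" variant selects the
same penalty and is an optimisation, not a different criterion.

Edge signs come from the averaged beta matrix: the sign of the mean of
the two directional coefficients, falling back to the larger-magnitude
coefficient when the mean is exactly zero. Each edge carries its StARS
selection frequency as a stability score.

# Network resilience

Topology is compared via degree centrality normalised by `N - 1` and
betweenness normalised by `(N - 1)(N - 2)/2`, on the unweighted selected
network (signs ignored). Robustness uses **natural connectivity**, a
closed-walk index based on the eigenvalues of the adjacency matrix. The
index ships in two modes because the defining expression is printed
ambiguously in parts of the literature: `"standard"` computes
`ln(mean(exp(lambda)))/(N - ln N)` (an edgeless graph scores exactly 0)
and `"literal"` computes `ln(sum(exp(lambda)))/(N - ln N)`; the two
differ by `ln(N)/(N - ln N)`, the mode is recorded in the output, and
any comparison uses one mode consistently. The eigenvalue sum is
numerically a log-sum-exp and is verified against the trace of the
matrix exponential.

`attack_simulation()` removes nodes sequentially — by highest degree or
betweenness (recomputed after each removal by default; an
initial-ranking variant sits behind a flag) or uniformly at random —
recording natural connectivity from the intact network down to a single
node, with lexicographic tie-breaking for determinism.
`connectivity_distribution()` repeats the full inference pipeline on
random subsamples of focal-positive and focal-negative samples and
compares the two natural-connectivity distributions with a one-sided
Mann–Whitney test; `select_controls()` finds comparison taxa matched on
detection rate (30–40%) and geometric-mean nonzero relative abundance
(1e-3 to 1e-2). The selection universe for controls is whatever table
the caller passes, so site restrictions are the caller's choice.

# Synthetic cohorts and what passing tests mean

The generator emulates the features of a large gut-survey cohort that
the analyses actually exercise:

* subjects with 1–5 samples (heavily skewed to 1), host covariates drawn
  at the subject level with configurable missingness;
* log-normal read depths with median 2e4 and sdlog 0.6 by default, so
  the 10,000-read inclusion filter removes a nontrivial fraction;
* focal counts drawn by inverting the fitted model itself — structural
  absence via the logistic component (log-depth offset included,
  coefficient 1), counts via the NB component — with co-detection of
  multiple focal OTUs induced by one shared, centred Bernoulli factor
  added to every focal logit (one parameter reproduces both excess
  co-occurrence and its symmetry);
* a background community whose latent log-abundances are multivariate
  normal with a known sparse precision matrix (chain, multi-hub, random,
  or user-supplied), observed as multinomial draws from the softmax of
  the latent vector — the standard logistic-normal-multinomial link
  between a conditional-dependence graph and compositional counts;
* a random rooted binary phylogeny with exponential branch lengths over
  all taxa.

Simulation sizes used by the validation suite (n = 5000 subjects for
model recovery, p = 30 species and n = 1000 samples over 20 seeds for
network recovery, 20 x 200-sample inference rounds for the resilience
contrast) were chosen as the smallest at which the corresponding
statistical claims are stable, and the "hub" benchmark uses groups of
five nodes around local hubs — a single 29-neighbour hub bounds every
partial correlation below 1/sqrt(29) and is not recoverable at unit
diagonals, which is a property of the graph, not of the estimator.

What the generator does *not* emulate: taxonomic structure, chimeras and
sequencing error, batch effects, covariate-dependent community
composition, or longitudinal autocorrelation beyond subject-constant
covariates. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to
real-data artefacts outside it.

# Numerical and design choices

* ZINB likelihood terms for observed zeros use log-sum-exp; dispersion
  is optimized as `log k`; separation in the logistic component is
  reported as a warning when coefficients exceed 20 in absolute value.
* The exact Mann–Whitney enumerates all `choose(m + n, m)` assignments
  (ties included naturally); the asymptotic branch applies the standard
  tie correction without continuity correction.
* The penalty grid's top is the largest absolute CLR correlation, so the
  sparsest model on the path is empty by construction; a near-zero grid
  top (uncorrelated data) is flagged.
* Permutation p-values use the add-one correction everywhere.
* All stochastic stages take explicit seeds; the pipeline derives one
  child seed per stage from the master seed, and generators restore the
  caller's RNG state.
* Degenerate inputs fail loudly and specifically: all-zero samples in
  beta diversity, missing tree tips (listing the taxa), empty
  co-detection strata (naming the stratum), single-sample subjects in
  longitudinal grouping, constant columns in the CLR matrix (naming the
  species), `rep_num < 2` in StARS, empty graphs in natural
  connectivity.

# Limitations

The multivariate model deduplicates to one specimen per subject rather
than modelling repeated measures; regularised or Bayesian zero-inflated
variants are out of scope, as are weighted UniFrac, covariate-adjusted
PERMANOVA, glasso-mode network inference, and edge-level significance
beyond StARS stability. The univariate NB screen's all-samples default
is an interpretation (a single NB p per level is reported in covariate
tables of this kind); the positives-only alternative is one flag away.
Small species panels (roughly p < 15) make StARS conservative, as
discussed above.

# A minimal worked run

```{r example, eval = FALSE}
spec <- cohort_spec(n_subjects = 300, seed = 1)
ft <- focal_model_truth(
  gamma = matrix(c(qlogis(0.6) - log(2e4), 0.02, -0.5), ncol = 1,
                 dimnames = list(c("(Intercept)", "age", "sex_Male"), NULL)),
  beta = matrix(c(-8.5, 0.01, 0.3), ncol = 1,
                dimnames = list(c("(Intercept)", "age", "sex_Male"), NULL)),
  dispersion = 1, coupling = 1.5,
  covariates = c("age", "sex"), references = c(sex = "Female"))
ct <- community_truth(p = 30, graph = "chain")
spec$covariates <- list(
  list(name = "age", type = "continuous", mean = 45, sd = 15, missing_rate = 0),
  list(name = "sex", type = "categorical", levels = c("Female", "Male"),
       missing_rate = 0))
ds <- assemble_dataset(spec, ft, ct)
cfg <- run_config(focal_ids = ds$focal_ids, seed = 1)
res <- run_pipeline(ds$counts, ds$meta, cfg, tree = ds$tree)
summary(res$zinb$fit)
```
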