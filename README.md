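# commNmix

Multispecies N-mixture models of correlated abundances for community
point-count surveys with individual capture histories.

## The problem

Community point-count surveys often record, for every individual bird
detected, a *capture history*: detected or not in each of J successive
observation intervals within a survey (e.g. four five-minute intervals
of a 20-minute count). Counts of different species at the same points
may covary — because species interact, or because they respond to
habitat features nobody measured. Disentangling habitat effects from
residual association, while correcting for imperfect detection, is the
problem this package addresses. Its users are quantitative ecologists
and biostatisticians analysing repeated point counts of whole
communities.

## The model

For survey *i* and species *k*, the latent abundance vector follows a
multivariate Poisson-lognormal distribution:

* N_ik | ε_ik ~ Poisson(exp(μ_ik + ε_ik)), with log-linear predictor
  μ_ik = β_k′ x_ik (habitat covariates, typically PCA scores);
* ε_i = (ε_i1, …, ε_iK)′ ~ MVN(0, Σ), with an **unrestricted** K × K
  covariance Σ — variances σ_k² and correlations ρ_kl of either sign.

Detection is multinomial on the frequency summary Y_ikj (number of
individuals of species k detected exactly j times in survey i):

* Y_ik | N_ik ~ Multinomial(N_ik; π_ik0, …, π_ikJ),
  π_ikj = C(J, j) p_ik^j (1 − p_ik)^(J−j),
  logit(p_ik) = α_k′ w_ik (day of year, time-of-day block).

Marginally E(N_ik) = τ_ik = exp(μ_ik + σ_k²/2),
Var(N_ik) = τ_ik + τ_ik²{exp(σ_k²) − 1}, and
Cov(N_ik, N_il) = τ_ik τ_il {exp(ρ_kl σ_k σ_l) − 1}. A species with
σ_k = 0 is pure Poisson and contributes nothing estimable to Σ — hence
the package's two-step workflow:

1. per species, fit single-species Poisson N-mixture models by maximum
   likelihood, select covariates by exhaustive best-subset BIC, and
   screen for overdispersion with a parametric-bootstrap Pearson test;
2. fit the species that show extra-Poisson variation (and are not too
   sparse to support it) jointly by MCMC, reporting posterior means,
   Monte Carlo standard errors, credible intervals and significance
   flags for all pairwise abundance correlations.

A generative simulator (`simulateCommunity()`) draws the full chain —
correlated residuals, Poisson abundances, per-individual Bernoulli
capture histories — and backs every statistical claim in the test
suite.

## Worked example

Simulate a four-species community where species 1–2 share lognormal
overdispersion with correlation 0.85 and species 3–4 are pure Poisson,
then run the two-step pipeline:

```r
library(commNmix)
Sig <- diag(1e-6, 4)
Sig[1:2, 1:2] <- matrix(c(1, 0.85, 0.85, 1), 2)
ds <- simulateCommunity(I = 250, K = 4, J = 4,
                        beta = list(1.2, 1.2, 1.0, 1.0),
                        alpha = list(0), Sigma = Sig, seed = 21)
cfg <- pipelineConfig(dataset = ds, gofNBoot = 150,
                      mcmc = mcmcControl(nChains = 2, nIter = 2500,
                                         burnin = 1000, thin = 3,
                                         seed = 4),
                      seed = 7)
report <- runPipeline(cfg)
dispositions(report)[, c("species", "disposition", "gof_p")]
#>   species     disposition       gof_p
#> 1    SP01    multispecies 0.006622517
#> 2    SP02    multispecies 0.006622517
#> 3    SP03 single_adequate 0.377483444
#> 4    SP04 single_adequate 0.165562914
correlationTable(report)
#>   species_k species_l     mean        mcse     lower    upper significant
#> 1      SP01      SP02 0.822425 0.001950542 0.7424551 0.881909        TRUE
```

Reading the output: the bootstrap goodness-of-fit p-values flag the two
overdispersed species (p ≈ 0.007) and clear the Poisson ones; only the
flagged pair enters the joint model, whose posterior mean correlation
0.82 (Monte Carlo SE 0.002, 95% credible interval 0.74–0.88) recovers
the generating value 0.85 and is flagged significant because the
interval excludes zero. `formatCorrelationTable()` renders the
publication-style lower triangle; `writePipelineReport()` writes the
CSV/JSON bundle.

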