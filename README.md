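# mcarmap

Joint Bayesian multivariate disease mapping of cardiovascular conditions at
health-district level.

## The problem

National examination surveys measure cardiovascular conditions —
hypertension, ischaemic heart disease (IHD), stroke, dyslipidaemia — on a
few hundred people per health district, far too few for stable
district-level prevalence maps, especially for rare outcomes. Because the
four conditions share risk factors and aetiology, mapping them *jointly*
borrows strength both across neighbouring districts and across conditions,
producing smoothed, covariate-adjusted district risk surfaces from data
that are individually too thin to map. `mcarmap` implements that pipeline
for epidemiologists and health-systems analysts: clinical outcome
derivation, design-weighted prevalence estimation, a district
multidimensional poverty index, and the joint spatial model itself, plus a
synthetic-data generator so the whole pipeline can be validated with known
ground truth.

## The model

For participant *i* in district *j(i)* and condition *k = 1..K*,
*Y<sub>ik</sub>* ~ Bernoulli(*π<sub>ik</sub>*) with

&nbsp;&nbsp;&nbsp;&nbsp;logit(*π<sub>ik</sub>*) = *α<sub>k</sub>* + **x**<sub>*i*</sub>′**β**<sub>*k*</sub> + *S<sub>j(i),k</sub>* + *V<sub>j(i),k</sub>*

a convolution of two district random effects: **S**, a multivariate
*intrinsic CAR* field (each district's K-vector is conditionally Gaussian
around the mean of its neighbours with covariance Σ<sub>s</sub>/m<sub>j</sub>,
identified by sum-to-zero constraints), and **V** ~ MVN(0, Σ<sub>v</sub>),
exchangeable across districts. Priors: flat on the intercepts
*α<sub>k</sub>*, Normal(0, 10³) on fixed effects, Wishart(*K*, I) on both
precision matrices Σ<sub>s</sub>⁻¹ and Σ<sub>v</sub>⁻¹. The quantity mapped
is the *spatial odds* exp(*S<sub>jk</sub>* + *V<sub>jk</sub>*) — the
multiplicative excess odds of condition *k* from residing in district *j*
after covariate adjustment — with its exceedance probability P(odds > 1).

Inference is exact Gibbs sampling via Pólya–Gamma augmentation: every
observed Bernoulli-logit cell gets a latent ω ~ PG(1, η), after which all
full conditionals are Gaussian or Wishart. The PG(1, z) sampler
(alternating-series rejection) is implemented in C++ and uses R's RNG, so
runs are exactly reproducible from a seed.

## Worked example

Simulate a 20-district geography with two conditions, derive outcomes from
the raw clinical fields, estimate weighted prevalence, and fit the joint
model:

```r
library(mcarmap)
g <- lattice_graph(4, 5)
cfg <- generator_config(graph = g, diseases = c("hbp", "ihd"),
                        formula = ~ sex + diabetes,
                        size_meanlog = log(150), size_sdlog = 0.3,
                        size_range = c(60, 400))
pop <- generate_population(cfg, seed = 2026)
out <- derive_outcomes(pop$records)
weighted_prevalence(out$hbp, pop$records$weight)
#>   p_hat ci_low ci_high    n n_eff degenerate
#> 1 0.286  0.269   0.304 2764  2524      FALSE

spec <- mcar_spec(pop$outcomes, pop$records$district, g,
                  pop$records, ~ sex + diabetes)
fit <- run_mcmc(spec, chains = 2, iterations = 1500, burnin = 750,
                thin = 3, seed = 1)
fit
#> mcar_samples: 500 draws (2 chain(s) x 250), 2 conditions, 20 districts
#> max split R-hat 1.034 (converged)

tab <- posterior_or_table(fit)
tab[tab$disease == "hbp", ]
#>  disease     term  level    or ci_low ci_high reference
#>      hbp      sex female 1.000  1.000    1.00      TRUE
#>      hbp      sex   male 0.932  0.785    1.12     FALSE
#>      hbp diabetes     no 1.000  1.000    1.00      TRUE
#>      hbp diabetes    yes 2.443  2.007    3.01     FALSE

head(spatial_odds(fit)[spatial_odds(fit)$disease == "hbp", ], 3)
#>  district code disease  odds ci_low ci_high exceedance
#>         1    1     hbp 0.938  0.648    1.36      0.354
#>         2    2     hbp 1.244  0.780    1.91      0.864
#>         3    3     hbp 1.306  0.929    1.85      0.922
```

The weighted hypertension prevalence (28.6%, CI 26.9–30.4%) recovers the
generator's calibration target of 0.286; the diabetes odds ratio 2.44
(2.01–3.01) covers the generator's true value exp(1) ≈ 2.72; the spatial
odds say, e.g., that district 3 carries about 31% excess hypertension odds
with posterior probability 0.92 of genuine excess. `run_pipeline()` drives
the same stages end to end (simulate → derive → estimate → fit without and
with the district deprivation quintile → summarise) and writes CSV/GeoJSON
outputs plus a JSON manifest with seeds and convergence diagnostics.

The district deprivation covariate is the South African Multidimensional
Poverty Index: `compute_sampi(H, A)` with headcount `H` and intensity `A`
(e.g. `compute_sampi(0.20, 0.44)` → 0.088, i.e. 0.09 at two decimals),
categorised into rank quintiles by `sampi_quintiles()`.

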