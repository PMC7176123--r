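---
title: "Joint multivariate CAR disease mapping: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint multivariate CAR disease mapping: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcarmap)
```

## The scientific problem

District-level prevalence of cardiovascular conditions estimated directly
from a national examination survey is unstable: a survey powered for
national and provincial estimates leaves many districts with only a few
dozen participants, and for rare outcomes (stroke, IHD) the raw district
rates are dominated by sampling noise. Because hypertension, IHD, stroke
and dyslipidaemia share behavioural and metabolic risk factors, a *joint*
spatial model can pool information in two directions at once — across
adjacent districts and across correlated conditions — and return smoothed,
covariate-adjusted district risk surfaces with honest uncertainty.

`mcarmap` implements that analysis as a reusable pipeline: outcome
derivation from clinical cut-offs and self-reports, survey-weighted
prevalence estimation, a district deprivation index used as an area-level
covariate, the joint Bayesian spatial model, and a synthetic-data generator
that is the exact dual of the model so that every stage can be validated
against known ground truth.

## Model

For participant $i$ in district $j(i)$, condition $k = 1,\dots,K$:

$$Y_{ik} \sim \mathrm{Bernoulli}(\pi_{ik}), \qquad
\mathrm{logit}(\pi_{ik}) = \alpha_k + \beta_k' x_i + S_{j(i),k} + V_{j(i),k}.$$

The district effect $U_{jk} = S_{jk} + V_{jk}$ is a convolution of:

* **Structured effects $S$** — a multivariate intrinsic CAR field on the
  district adjacency graph. Row $S_j$ given the rest is
  $\mathrm{MVN}\!\left(\frac{1}{m_j}\sum_{l \sim j} S_l,\ \Sigma_s / m_j\right)$
  where $m_j$ is the neighbour count. The joint density is improper with
  precision $Q \otimes \Sigma_s^{-1}$ ($Q$ the graph Laplacian-style
  structure matrix); sum-to-zero constraints per condition identify it.
* **Unstructured effects $V$** — $V_j \sim \mathrm{MVN}(0, \Sigma_v)$,
  exchangeable over districts, absorbing non-spatial heterogeneity.

Priors: flat (improper uniform) on each intercept $\alpha_k$; independent
$\mathrm{Normal}(0, 10^3)$ on fixed effects; $\mathrm{Wishart}(K, I)$ on
both $\Sigma_s^{-1}$ and $\Sigma_v^{-1}$ — $K$ degrees of freedom is the
smallest value giving a proper Wishart, expressing vague prior knowledge,
and the identity scale is the conventional neutral choice (both are
configurable through `mcar_prior()`). Propriety of the posterior under the
flat intercept prior is ensured by the data together with the sum-to-zero
constraint.

The mapped quantity is the **spatial odds** $\exp(U_{jk})$ — the
multiplicative excess odds of condition $k$ attributable to residing in
district $j$ after covariate adjustment — summarised by posterior median,
95% credible interval and the exceedance probability
$P(\exp(U_{jk}) > 1 \mid \text{data})$.

## Sampler

The sampler is a Gibbs sweep made exactly conjugate by Pólya–Gamma
augmentation: each observed cell receives $\omega_{ik} \sim
\mathrm{PG}(1, \eta_{ik})$, turning the Bernoulli-logit likelihood into a
Gaussian one in $\eta$ with precision $\omega$ and pseudo-response
$(y - \tfrac12)/\omega$. One sweep is:

1. $\omega_{ik} \sim \mathrm{PG}(1, \eta_{ik})$ for observed cells (missing
   cells drop their latent draw and likelihood term — complete-cell
   analysis, mirroring the no-imputation stance of the estimation modules);
2. per condition, a joint Gaussian block draw of $(\alpha_k, \beta_k)$;
3. a systematic single-site scan of the $S_j$ rows, each combining the
   multivariate ICAR conditional with the Gaussianised likelihood of that
   district's participants;
4. the same for $V_j$ with its $\mathrm{MVN}(0, \Sigma_v)$ prior;
5. recentering: each column of $S$ is centred (over non-island districts)
   and the mean folded into $\alpha_k$, leaving the linear predictor
   unchanged — this invariance is asserted numerically at every sweep;
6. Wishart draws of $\Sigma_s^{-1}$ (data cross-product $S'QS$, degrees of
   freedom increment $\mathrm{rank}(Q) = J - c$ with $c$ the number of
   connected components) and $\Sigma_v^{-1}$ (cross-product $V'V$,
   increment $J$).

The PG(1, z) sampler is the exact alternating-series rejection method,
implemented in C++ on R's RNG stream: no tuning parameters, no
approximation, bit-reproducible under `set.seed()`. Chains differ by seed
only (chain $c$ uses `seed + (c-1) * 100003`). A purposeful consequence of
exact conjugacy is testability: the Wishart full conditionals are checked
against their closed-form moments by Monte Carlo, and the one-condition
non-spatial reduction against deterministic grid quadrature of the exact
posterior.

Defaults are 2 chains of 10,000 sweeps, 5,000 burn-in, thinning 5;
convergence is flagged by split-chain potential scale reduction
($\hat R < 1.1$ for all monitored parameters: intercepts, fixed effects and
the unique elements of both covariance matrices).

## Identifiability and degenerate-input conventions

* **Islands** (districts with no neighbours) have an undefined ICAR
  conditional; their structured effect is fixed at zero and a warning is
  emitted when the graph is built — the GeoBUGS-compatible convention. Any
  district-specific signal for an island is carried by its unstructured
  effect.
* **Recentering** is global over non-island districts. For a disconnected
  graph the per-component intercept offsets are not separately identified;
  the 52-district application graph is connected, where
  $\mathrm{rank}(Q) = J - 1$.
* **Ties in the deprivation quintiles** are broken by stable input order,
  making the $n = 52$ partition reproducible: the rule
  $\lceil 5r/n \rceil$ on ascending ranks gives sizes (10, 10, 11, 10, 11).
* **Degenerate prevalence estimates** ($\hat p \in \{0, 1\}$) cannot carry a
  logit-scale interval; a one-sided exact-style bound based on the
  effective sample size is substituted and flagged.
* **Numerical tolerances**: recentering invariance is asserted at
  $10^{-10}$ on the linear predictor; column sums of retained $S$ draws are
  checked to $10^{-8}$; Cholesky failure of any full-conditional precision
  aborts with context rather than silently regularising.

## Outcome derivation

The four outcomes are OR-rules over printed cut-offs: hypertension
(SBP ≥ 140 or DBP ≥ 90 mmHg, self-report, or medication), IHD and stroke
(self-report pass-through), dyslipidaemia (lipid drugs, diagnosis,
TC ≥ 6.22, TG ≥ 1.69, LDL ≥ 4.14 mmol/L, or HDL < 1.04 for men / < 1.29
for women); diabetes is HbA1c ≥ 6.5% or history/treatment; BMI classes are
underweight < 18.5, normal [18.5, 25), overweight ≥ 25 kg/m².
"Impaired glucose metabolism" is treated as identical to the diabetes
definition since both rest on the same HbA1c rule. Missingness follows the
only monotone completion of an OR-rule: any positive evidence gives 1;
all-observed-negative gives 0; no observed evidence gives missing. A record
with observed HDL but missing sex cannot use its HDL evidence and is
flagged rather than guessed.

## Survey estimation

Weighted prevalence is the ratio estimator $\sum w_i y_i / \sum w_i$ with
Taylor-linearised variance and a logit-scale Wald interval (so intervals
respect $[0,1]$); PSU-grouped linearisation is available. The interval
method is a design decision — the common survey default — since the source
analyses do not name theirs. Weights are consumed as given; the generator
emits two weight columns (interview and biomarker) so the
differential-weighting workflow between biomarker consenters and
self-report-only participants is exercised without inventing a particular
weighting scheme. Survey weights are deliberately *not* used in the
Bayesian likelihood, which is an unweighted Bernoulli model; weights live
entirely in the estimation module.

## Deprivation index

The district deprivation covariate is an Alkire–Foster-type index: the
product of the headcount ratio $H$ (share of households whose weighted
deprivation share reaches the poverty cutoff) and the intensity $A$ (mean
weighted deprivation share among the poor). The cutoff defaults to $1/3$
(the global-MPI convention the index is modelled on) and indicator weights
to nested equal weighting across the four dimensions (education, health,
living standards, economic activity) — both configurable, because the
source material lists the dimensions and worked examples but neither its
cutoff nor its weights. (It also once refers to "five dimensions"; the
definitional paragraph says four, which is what is implemented.)

## Synthetic-data generator

The generator draws from the fitting model itself — same linear predictor,
same effect decomposition — so that generator and sampler are exact duals
and parameter-recovery tests are meaningful:

* **Geography**: any adjacency graph; default a 4 × 13 rook lattice
  standing in for the 52-district map.
* **District sample sizes**: lognormal calibrated to the reported median
  277 (log-mean) and mean 346 (log-sd $\sqrt{2\log(346/277)} \approx
  0.67$), truncated by rejection to the reported range [22, 1625]. The
  distribution family is a package choice; only the three summaries are
  reported facts.
* **Structured effects**: simulated spectrally on the sum-to-zero subspace
  (coefficients on positive-eigenvalue eigenvectors of $Q$ with covariance
  $\Sigma_s/\lambda$) — the only construction consistent with the improper
  intrinsic prior used in fitting.
* **Intercept calibration**: $\alpha_k$ is found by root-finding on the
  realised population so the expected marginal prevalence equals its target
  (defaults 0.286, 0.054, 0.018, 0.531 for hypertension, IHD, stroke,
  dyslipidaemia).
* **Covariates**: categorical draws with the survey table's category
  frequencies; default true effects follow the reported qualitative
  gradients (steep age gradient for hypertension, diabetes raising all four
  conditions, adiposity raising hypertension and dyslipidaemia). A
  district-level deprivation quintile can be attached as a covariate.
* **Raw-field back-fill**: positive outcomes receive one sufficient
  positive field (e.g. SBP 150), negative outcomes all-negative observed
  fields, so `derive_outcomes()` round-trips the generated outcome matrix
  exactly. Self-report flags for hypertension and dyslipidaemia are drawn
  only among the truly positive (at rates emulating the low self-report
  sensitivity of those conditions), which keeps the round-trip exact while
  making the validity-statistics workflow non-trivial.

What the generator does **not** emulate: joint physiology of the lipid
panel and blood pressure (fields are back-filled, not co-simulated),
multi-stage cluster sampling mechanics beyond the two weight columns, and
item non-response patterns. Passing recovery tests therefore demonstrates
correctness of the inferential machinery under the model's own assumptions,
not robustness to real-data features outside them.

## Validation studies and problem sizes

The test suite validates each stage and then the whole, at sizes chosen to
keep the default run desk-sized:

* dense-oracle equivalence of the log-likelihood and the MICAR full
  conditional on graphs with $J \le 6$, $K \le 3$, at $10^{-10}$;
* Wishart-conjugacy Monte Carlo ($10^5$ draws) and quadrature match of the
  one-condition, no-spatial posterior;
* fixed-effect recovery on a scaled replica of the mapping exercise: 52
  districts, $K = 2$, ~3,000 participants, an exposure with true odds
  ratio 2.0 and a 5-level deprivation quintile, 5 replicates of 2 × 2,000
  sweeps — checking the posterior median OR lies in (1.6, 2.5), credible
  intervals cover truth at rate ≥ 0.85, and all $\hat R < 1.1$;
* spatial-effect recovery: a district with true spatial odds 2 must rank
  top in ≥ 90% of 10 replicate fits on a 20-district lattice;
* survey CI coverage 93–97% over 500 simulations at $n = 500$, $p = 0.3$;
* round-trip, recentering-invariance and retained-draw (SPD, sum-to-zero)
  invariants.

## Known limitations

* The intrinsic CAR is improper and its variance parameters are only
  interpretable conditionally; cross-condition correlations in $\Sigma_s$
  are on the conditional, not marginal, scale.
* Single-site updates of $S$ mix more slowly than block updates would on
  large, strongly-coupled graphs; at $J = 52$ this is immaterial.
* Complete-cell analysis assumes outcome missingness is ignorable given
  covariates; no imputation is offered by design.
* Binary contiguity only; no distance- or covariate-weighted adjacency.
* Shared-component joint models — an alternative multivariate mapping
  family — are out of scope; only the multivariate CAR convolution model is
  implemented.
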