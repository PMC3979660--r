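---
title: "Small-area estimation of water and sanitation coverage: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of water and sanitation coverage: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

National household cluster-sample surveys (DHS, MICS, LSMS and similar)
record, per sampled cluster of ~25 households, how many households use an
improved drinking-water source, improved sanitation, or practise open
defecation.  Surveys are powered for provinces ("admin1"), yet access varies
at the district ("admin2") scale.  This package estimates district-level
coverage by pooling all surveys in a single Bayesian hierarchical spatial
model, predicts coverage for a target year — including for districts no
survey ever visited — aggregates with urban/rural district populations, and
summarizes sub-national inequality with population-weighted Lorenz curves,
geographical GINI coefficients and a relative geographic inequality (RGI)
score.

# The model

For survey site $i$ in district $j$, province $k$, country $c$, stratum
$r \in \{\text{rural}, \text{urban}\}$ and year $t_i$, the number of
positive households is binomial,

$$y_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
\mathrm{logit}(p_i) = \alpha_{c,r} + \beta_{c,r}\,(t_i - t_0) + u_j + v_k,$$

with country intercepts and linear time slopes drawn from common means,

$$\alpha_{c,r} \sim N(\mu_\alpha^{(r)}, \sigma_\alpha^{(r)2}), \qquad
\beta_{c,r} \sim N(\mu_\beta^{(r)}, \sigma_\beta^{(r)2}),$$

an intrinsic conditional autoregressive (ICAR) prior on the district
effects within each country's adjacency graph,

$$\pi(u \mid \sigma_u^{(c)}) \propto
\exp\Big\{-\tfrac{1}{2\sigma_u^{(c)2}}
\sum_{i \sim j} (u_i - u_j)^2\Big\},$$

and unstructured province effects $v_k \sim N(0, \sigma_v^2)$.  Each
indicator is fitted independently.  Records arising from province-only
located sites are replicated over the province's $m$ districts with weight
$1/m$; weights enter as powers on the binomial likelihood contributions, so
splitting a record into two half-weight copies leaves the posterior exactly
unchanged (this is asserted to $10^{-10}$ in the tests).

Modelling choices where the design was genuinely open:

* **Spatial effects are shared across strata.**  Intercepts and slopes are
  stratum-specific, but $u$ and $v$ are common to urban and rural
  households of an area — the parsimonious choice given that a district's
  infrastructure deficit affects both populations.
* **$\sigma_u$ is country-specific** (with a common half-normal
  hyper-scale), since the degree of spatial clustering differs between
  countries; $\sigma_v$ is global.
* **$t_0 = 2012$**, the prediction year, so intercepts are directly the
  2012 logit-coverage; this also improves interpretability of
  $\mu_\alpha$.
* **Weight $1/m$ for allocated records** conserves total information mass:
  the sum of weights after allocation equals the number of input records
  exactly.

## Priors

Weakly informative on the logit scale, exposed via `hyperpriors()`:
$\mu_\alpha, \mu_\beta \sim N(0, 5^2)$ and all standard deviations
half-normal with scale 1.  On the probability scale an SD of 1 in a logit
already moves coverage from 0.5 to 0.73, so half-normal(1) comfortably
covers the plausible range while discouraging degenerate fits.

# Sampling

`run_mcmc()` runs an adaptive Metropolis-within-Gibbs sampler (compiled,
single-threaded):

* scalar random-walk updates for every $\alpha_{c,r}$, $\beta_{c,r}$,
  $u_j$ and $v_k$, with proposal scales adapted during warmup toward an
  acceptance rate of 0.38 (Robbins–Monro, step $\propto s^{-0.6}$ in sweep
  $s$, frozen after warmup);
* conjugate Gibbs draws for $\mu_\alpha^{(r)}$ and $\mu_\beta^{(r)}$;
* log-scale random-walk updates for all SDs (half-normal prior plus
  Jacobian), so $\sigma > 0$ always holds;
* an exact auxiliary Gibbs move that shifts a country's two intercepts by
  $d$ and its province effects by $-d$.  The likelihood is invariant along
  this direction, and the Gaussian priors give $d$ a closed-form normal
  conditional; without it the intercept/province-effect confounding mixes
  very slowly;
* after every sweep over $u$, the per-component sum-to-zero constraint of
  the intrinsic CAR is re-imposed by centring each connected component
  (islands are fixed at 0 and excluded from the ICAR sum).

Initial values use the empirical logit of the pooled counts per stratum
with seed-controlled jitter; a non-finite posterior at initialization stops
with advice to re-seed.  Chains are seeded `seed`, `seed + 1`, ...; given a
seed, all output is bit-reproducible.  `diagnostics()` reports split R-hat
and a Geyer initial-monotone-sequence effective sample size per stored
scalar, flagging anything above 1.05.  The compiled posterior kernel is
asserted equal to an independent pure-R implementation of the full
unnormalized posterior (`log_unnormalized_posterior()`) to $10^{-10}$ on
random parameter sets.

# Prediction, imputation and aggregation

For 2012 (or any requested year) the linear predictor is evaluated per
posterior draw.  Districts without data get $u$ drawn, per draw, from the
joint Gaussian conditional of the ICAR given the sampled districts: with
the graph Laplacian $Q = D - W$ partitioned into missing/observed blocks,
$u_m \mid u_o \sim N(-Q_{mm}^{-1} Q_{mo} u_o,\ \sigma_u^2 Q_{mm}^{-1})$;
for a single missing node this is the familiar
$N(\bar u_{\partial j}, \sigma_u^2/m_j)$.  The block solve is exact per
iteration, unlike single-site Gibbs sweeps.  The conditional is proper
whenever the missing node's component contains an observed node; fully
unobserved components fall back to $u = 0$ with a warning, and countries
with no directly-located district data fall back to province-level
prediction (`basis = "admin1-level"`).  A deliberate subtlety: literally
conditioning the *sum-to-zero constrained* representative of the ICAR would
make a single missing node's value deterministic (the constraint fixes it),
which contradicts the neighbour-mean/$\sigma^2/m$ full conditional used
throughout the disease-mapping literature; the package therefore uses the
unconstrained Markov-blanket conditional above, and its tests check it
against dense partitioned-precision conditioning on every connected graph
of up to five nodes.

District overall coverage is the urban/rural population-weighted mean per
draw; national coverage is the district-population-weighted mean, so
conservation (national = weighted mean of districts) holds to machine
precision per draw.  A district is flagged `low`/`high` when the 95%
interval of the per-draw *difference* from its national mean excludes 0 —
the coherent Bayesian reading of interval-based significance (not
non-overlap of two marginal intervals).

# Inequality

`lorenz_curve()` ranks districts ascending by per-capita coverage (ties
broken by id for determinism) and accumulates population and "use"
(population × coverage) shares; ranking by per-capita value — rather than
by raw share of national use, which is ambiguous when populations differ —
guarantees a convex curve below the diagonal, and the raw-share ranking
remains available behind `rank_by = "share"` for sensitivity analysis.
`gini()` is twice the area between diagonal and curve by the trapezoid
rule, which the tests verify against a brute-force population-weighted
pairwise mean-absolute-difference oracle to $10^{-12}$.  All-zero coverage
makes the curve undefined and raises an error rather than defining a
convention.  For open defecation, inequality is computed on the complement
(any-sanitation coverage).

Because coverage is bounded, GINI necessarily falls as coverage rises, so
raw GINIs are not comparable across coverage levels.  The RGI score is the
observed GINI minus the GINI expected from a cross-country OLS of GINI on
national coverage.  The regression is fitted once on posterior medians;
uncertainty is propagated through the per-draw GINIs only (RGI per draw =
GINI(draw) − expected at the median coverage), and significance is read
from the 95% interval of RGI with a $10^{-12}$ numerical guard around zero
so exact-fit residuals report `none`.  GINI is computed per posterior draw
by default; point-estimate mode simply passes a named vector of medians.

# What the synthetic data emulate — and what they do not

The generator inverts the model: nested hierarchy (sites ⊂ districts ⊂
provinces ⊂ countries, provinces as rook-contiguity lattices of districts),
urban/rural strata with distinct country intercepts and trends, ICAR
district effects sampled from the proper representative
$N(0, \sigma_u^2 L^{+})$ via the spectral decomposition of each component's
Laplacian, binomial cluster sampling with 25 households per site (the
typical DHS cluster take), survey years across 1990–2012, and configurable
fractions of never-sampled districts and province-only located sites.
District populations are log-normal around 200,000 people (a typical
sub-Saharan district) with Beta(2, 4) urban shares.

It does **not** emulate: survey design effects (PSU/strata weighting,
non-response), spatially varying cluster sizes, measurement error in
category coding, non-linear time trends, or real boundary geometry.
Passing tests therefore demonstrate the estimator's correctness under its
own assumptions, not robustness to their violation.

# Study-design scales used in the tests

The parameter-recovery study uses 3 countries × 2 provinces × a 3×3
district lattice, two strata, survey years 1998/2005/2011, two 25-household
clusters per district/stratum/year, truth
$\mu_\beta^{(\text{rural})} = 0.05$/yr and $\sigma_u = 0.5$, fitted with
2 chains × 4,000 iterations (2,000 warmup), replicated 20 times; the
bundled analysis scripts use 6 countries at the same lattice size with 10%
unsampled districts and 10% province-only sites.  These sizes keep a full
replicate around a second while leaving all parameters comfortably
identified.  The null design for the false-flagging check zeroes both $u$
and $v$ *and* fixes the urban population share, because with heterogeneous
urban shares districts genuinely differ from the national mean through
stratum composition and flagging them is correct behaviour, not error.

# Known limitations

* No covariates beyond time and stratum; trends are strictly linear on the
  logit scale.
* The ICAR recentring device trades a small amount of posterior exactness
  for identifiability, as in standard WinBUGS-style CAR implementations.
* Province effects for provinces absent from the data are drawn from their
  prior when predicting, which assumes exchangeability.
* The GINI/RGI machinery conditions on the fitted regression line; no
  uncertainty in the line itself is propagated.
* Indicator classification relies on an exact-match vocabulary (packaged
  CSV, extensible per survey); unknown categories are conservatively
  treated as unimproved.
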