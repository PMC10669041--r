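---
title: "Copula Bayesian networks for wetland bird diversity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copula Bayesian networks for wetland bird diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetlandbn)
```

## The problem and the model

A coastal-wetland survey yields, for each of a few dozen wetlands, three
spatial traits (size in hectares, isolation and distance to the coastline
in metres), six anthropic/hydrological pressures scored on short ordinal
scales (tourism pressure, anthropization, water salinity, water
diversions, water discharges, and an 11-class mean water level), and the
number of bird species observed. The question is predictive: how does the
cross-wetland distribution of species richness shift when one or several
pressures are fixed at a hypothetical level?

`wetlandbn` answers this with a *non-parametric Bayesian network*: a
directed acyclic graph whose nodes keep their raw empirical margins and
whose dependence is a Gaussian copula. Nothing is assumed about marginal
shapes — essential here, because the pressures are ordinal scores and the
continuous traits are strongly right-skewed — while the dependence
structure stays analytically tractable in z-space.

Calibration (`fit_network()`):

1. each column is mapped to normal scores
   $z_i = \Phi^{-1}(r_i/(n+1))$ using midranks $r_i$;
2. the z-space correlation matrix is the product-moment correlation of
   those scores (the *normal rank correlation matrix*), repaired to
   positive definiteness if a small sample makes it indefinite;
3. in the default `bn_constrained` mode the matrix is restricted to the
   DAG: in topological order, each node's dependence on its predecessors
   is the least-squares projection onto its parents' scores, which forces
   the partial correlation with every non-parent predecessor (given the
   parents) to zero; each arc is then labelled with the partial
   correlation of its endpoints given the destination's earlier-ordered
   parents.

The `saturated` mode skips step 3 and is used for diagnostics and for the
determinant identity tests.

## Conditionalization

Evidence is a map from driver nodes to data-scale values. Each value is
converted to a uniform via the node's empirical CDF under the *midrank
convention* — $u = \bar r(v)/(n+1)$, where $\bar r(v)$ is the midrank the
value would take in the observed column. Evidence values that were never
observed are linearly interpolated between the neighbouring observed
levels; values beyond the observed range map to the half-rank positions
$0.5/(n+1)$ and $(n+0.5)/(n+1)$. This keeps $\Phi^{-1}(u)$ finite for any
admissible evidence, including extreme management levels.

Given evidence z-values, the free nodes follow the exact conditional
multivariate normal: mean from the cross-covariance times the inverse
evidence covariance, covariance from the Schur complement. Sampling is
analytic — no iterative assimilation — and samples are mapped back to the
data scale through piecewise-linear empirical quantile functions clamped
to the observed range. Consequently a scenario can never predict richness
outside the span of the calibration data; this is a deliberate
conservatism of empirical margins, not a bug.

## The scenario catalog

`scenario_catalog()` ships 18 scenarios: the baseline (no evidence); six
worst-case single drivers (tourism = 3, salinity = 3, discharges = 2,
anthropization = 2, water level = 11, diversions = 0) and their union,
the *worst possible* scenario; the six mirror-image management levels
(tourism = 0, salinity = 0, discharges = 0, anthropization = 0, water
level = 3, diversions = 3) and their union, the *best possible* scenario;
and three mixed scenarios, equal to the worst-possible evidence with one
driver neutralized at its management level. A raised water level counts
as deterioration and active diversions as beneficial because in these
shallow coastal systems high regulated water levels exclude small waders
and other shoreline foragers.

Results report the conditional mean $\mu$ (alpha diversity), SD
$\sigma$, and a histogram over 10 equal-width bins of the fixed species
range $[2, 32]$ (all scenarios share one axis), plus integer per-bin
wetland counts obtained by largest-remainder rounding so the counts
always sum to the number of wetlands.

## Validation

`validate_model()` implements the determinant test: $D_{ER}$ is the
determinant of the data's Spearman rank correlation matrix, and the
reference distribution is the determinant of the normal rank correlation
matrix of datasets simulated from the fitted copula at the same $n$
(default $10^4$ simulations). The copula assumption is retained when
$D_{ER}$ lies inside the equal-tailed 90% band — two-sided, because the
10% significance level splits into 5% in each tail. Simulated datasets
are passed back through the fitted margins before re-ranking, so they
carry the same ordinal ties as real data; a simulated ordinal column that
collapses onto a single level is treated as independent of the rest.

The naming of the *empirical* matrix is ambiguous in parts of the
literature (Spearman vs normal scores); both conventions are one flag
apart (`d_er_from`), differ only in the third decimal for rank-typed
data, and the choice used is recorded in the report.

Two identities anchor the tests: for a complete partial-correlation
ordering, $\prod (1-\rho^2)$ equals the matrix determinant to $10^{-10}$;
and under the model's own null the band test passes at very nearly its
nominal rate (checked at 200 replicates of 500 inner simulations).

## The synthetic generator

`default_synthetic_spec()` emulates the survey conditions: 22 wetlands,
the documented variable ranges and ordinal scales, and z-space
correlations to richness that are negative for salinity (−0.40), tourism
(−0.35), discharges (−0.30), anthropization (−0.25), water level (−0.25)
and isolation (−0.20), positive for size (+0.35), diversions (+0.25) and
distance to the coastline (+0.20), with mild tourism–anthropization
(+0.30) and salinity–water-level (+0.20) driver correlations. The
magnitudes were chosen once, at the lower-middle of the plausible
0.2–0.6 band, because nine near-independent drivers cannot all correlate
strongly with one target: the squared correlations must sum well below 1
for the joint matrix to be positive definite (its smallest eigenvalue
here is 0.18). Size and isolation get log-uniform margins (both span two
orders of magnitude), distance a uniform margin, and the ordinal scores
interior cut-points so every level occurs with positive probability.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring wetlands, year-to-year turnover, observation error in the
point counts, and any nonlinear (non-monotone) driver effect. Passing
tests on synthetic data therefore demonstrate that the estimator and the
conditioning machinery are correct under the model's own assumptions, not
that those assumptions hold in any particular field system — that is
exactly what the determinant validation is for on real data.

## Numerical choices

* **Plotting positions** $r/(n+1)$ everywhere (ranks, margins, evidence),
  keeping $\Phi^{-1}$ finite at the extremes; the convention is uniform
  across calibration and conditioning so transforms cancel exactly.
* **Ties**: Spearman correlation is the product-moment correlation of
  midranks, which reduces to the classical $1 - 6\sum d_i^2/(n^3-n)$ for
  distinct values; the textbook formula alone is undefined under ties,
  which are pervasive in ordinal traits.
* **PD repair** by eigenvalue clipping at $10^{-8}$ followed by
  renormalization to unit diagonal, iterated until the floor holds; the
  repair returns PD inputs unchanged, hence is idempotent.
* **Conditional covariance** receives a $10^{-10}$ ridge only if the
  Schur complement is numerically semi-definite (near-deterministic
  evidence sets).
* **Tie-breaking**: topological ordering ties are broken by the canonical
  trait-table column order, making fits and arc labels deterministic.
* **Seeding**: every sampling function takes an explicit integer seed;
  multi-stage runs derive stage seeds by fixed small offsets from the
  master seed, recorded in each artifact.

## Design decisions taken where the design was open

* The exact inter-driver arc set of the conceptual model is expert
  knowledge, so the shipped default DAG contains only the nine
  driver-to-richness arcs and any inter-driver arcs are supplied through
  the structure file. All outputs are reported against the configured
  structure.
* The water-level node is treated on its 1–11 ordinal class scale; a
  survey storing centimetres instead can override the schema at load
  time.
* `bn_constrained` is the default fit mode because the model assigns
  correlations only to arcs; with the default single-target DAG the two
  modes coincide on the target row, and they diverge once inter-driver
  arcs are constrained away.

## Known limitations

* **Ordinal attenuation.** Normal scores of a 3–4 level ordinal variable
  under-estimate the latent z-space correlation, and the bias compounds
  through large conditioning sets: on the default 10-node DAG the most
  heavily conditioned arc carries a systematic recovery bias of about
  0.1 even at $10^4$ rows. The package reports the attenuated estimate
  rather than inverting the attenuation (a polychoric-style correction
  would impose exactly the latent-normality assumption the validation is
  supposed to test).
* Small surveys ($n \approx 22$) give noisy arc partials; signs of strong
  arcs are usually recovered, magnitudes are not. The recovery experiment
  quantifies this honestly.
* Scenario histograms are Monte Carlo summaries (default $10^5$ draws,
  giving a mean standard error of roughly 0.03 species); the test suite
  and the acceptance script use between $2\times 10^4$ and $10^5$ draws
  and $500$–$10^4$ validation simulations depending on the check, sizes
  chosen so each property is resolved well inside its tolerance.
* Predictions are cross-wetland distributions; the package deliberately
  offers no per-wetland site prediction and no species-composition
  modelling.
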