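# wetlandbn

Non-parametric Bayesian networks with a normal copula for predicting how
management and counterfactual scenarios change **alpha avian diversity**
(the mean number of bird species per wetland) across a set of coastal
wetlands.

The package is aimed at conservation ecologists and quantitative wetland
managers who have (i) a small survey table of wetland traits — spatial
variables (size, isolation, distance to the coastline), semi-quantitative
anthropic and hydrological pressures (tourism, anthropization, salinity,
water diversions and discharges, mean water level) — plus per-wetland
species richness, and (ii) an expert-specified directed acyclic graph of
how those drivers influence richness. It answers questions of the form
*"what happens to the expected number of species per wetland if water
salinity becomes widespread everywhere?"* or *"can a tourism ban alone
compensate for all other pressures deteriorating?"*.

## The model

Each variable `X_i` keeps its own **empirical margin** `F_i`; dependence is
carried entirely by a normal (Gaussian) copula. By Sklar's theorem the
joint CDF factorizes as

    F(x_1, ..., x_n) = C(F_1(x_1), ..., F_n(x_n))

and the copula is

    C_R(u_1, ..., u_n) = Phi_R(Phi^-1(u_1), ..., Phi^-1(u_n)),

where `Phi` is the standard normal CDF and `R` a correlation matrix in
z-space. Calibration is rank-based: observations are mapped to normal
scores `z_i = Phi^-1(r_i / (n + 1))` with midranks `r_i`, and `R` is the
product-moment correlation matrix of those scores, restricted to the DAG by
assigning a **partial correlation to every arc** (each node's z-scores are
the least-squares projection onto its parents' scores; the partial
correlation with any non-parent predecessor given the parents is zero).

Three operations follow from the fitted model:

* **Validation** — the determinant `D = prod(1 - rho_ij^2)` of the
  empirical rank correlation matrix (`D_ER`) is compared against the
  sampling distribution of the same determinant on datasets simulated from
  the fitted copula (`D_NR`, 10^4 simulations); the copula assumption is
  retained when `D_ER` falls inside the 90% confidence band.
* **Conditionalization** — evidence (e.g. `water salinity = 3`) is mapped
  through the empirical CDF and `Phi^-1` into z-space, the remaining nodes
  follow the exact conditional multivariate normal (Schur complement), and
  samples are mapped back through the empirical quantile functions.
* **Scenario simulation** — a built-in catalog of 18 scenarios (baseline,
  six worst-case drivers and their union, six management measures and
  their union, three mixed scenarios) summarizes the conditional richness
  distribution as a mean, an SD and a 10-bin histogram with per-bin
  wetland counts.

A seeded synthetic-data generator reproduces the survey's variable ranges,
ordinal scales and hypothesized effect signs, so the whole pipeline is
testable without any field data.

## Worked example

```r
library(wetlandbn)

tab   <- generate_wetlands(seed = 1)          # 22 synthetic wetlands
model <- fit_network(tab)                     # margins + arc partials
round(model$arc_partials[c(5, 8)], 3)
#>  Water salinity -> Number of species  Tourism pressure -> Number of species
#>                              -0.481                                -0.860

validate_model(model, tab, n_sims = 10000, seed = 2)
#> <validation_report> D_ER = 0.0399; 90% band of D_NR = [0.0047, 0.0445]
#>   quantile position 0.927; normal-copula assumption not rejected

res <- run_catalog(model, n_samples = 1e5, seed = 3)
res$a$mu; res$a$sigma                          # baseline alpha diversity
#> 19.15   8.58
res$h$mu                                       # worst possible scenario
#> 3.68
res$o$mu                                       # best possible scenario
#> 30.30
delta_vs_baseline(res$c, res$a)                # widespread salinity
#> -3.99
res$h$wetland_counts                           # wetlands per richness bin
#> 19 1 2 0 0 0 0 0 0 0
```

Read that as: on this synthetic survey the fitted network expects 19.2
species per wetland at baseline; if every pressure deteriorates at once
the expectation collapses to 3.7 species, with 19 of the 22 wetlands in
the lowest richness class (2–5 species); widespread salinization alone
costs about 4 species per wetland; the full management package raises the
expectation to 30.3.

For file-based workflows, `run_config()` + `cmd_fit()` / `cmd_validate()`
/ `cmd_simulate()` run the same stages against a trait CSV, a structure
JSON/YAML and a scenario file, writing CSV/JSON artifacts and figures with
the seed and a config hash embedded.

## Package layout

* `R/trait_table.R` — schema, validation and CSV IO for the survey table
* `R/copula.R` — ranks, normal scores, correlation matrices, PD repair,
  copula sampling, empirical margins
* `R/network.R` — DAG structure, fitting, partial correlations
* `R/scenario.R` — scenario catalog, conditionalization, result summaries
* `R/validation.R` — determinant-based copula validation
* `R/synthetic.R` — ground-truth generator and recovery experiments
* `R/pipeline.R` — config, stage runners, serialization, figures
* `vignettes/wetland-diversity-scenarios.Rmd` — methods and design notes
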