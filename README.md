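# sizestab

Body size is a master trait of soil organisms: it sets growth rate,
dispersal, niche width and, this package's subject, how hard a
community is hit by environmental disturbance. `sizestab` is an R
toolkit for microbial ecologists analysing paired control/treatment
designs — field soils incubated under warming or nutrient addition,
profiled by 16S/18S amplicon sequencing — who want to ask, per organism
group along the body-size axis: how resistant is the community, why
(diversity, niche breadth, generalist content, assembly stochasticity),
and what does that mean for ecosystem functioning?

## What it computes

For each of a configurable set of organism groups (default 24: 12
bacterial, 7 fungal, 5 protistan, each with a characteristic body size
in µm), from a samples × taxa count table:

* **Resistance** per field pair, with the bounded Orwin–Wardle index
  `RS = 1 − 2|D₀|/(C₀ + |D₀|)`, `D₀ = C₀ − P₀` (control vs disturbed
  group abundance); plus abundance-weighted **tolerance width** and
  **nonsynchronization** `1 − Var(Σᵢxᵢ)/(ΣᵢSD(xᵢ))²` of member
  responses.
* **Diversity and niche**: Shannon `H = −Σ p ln p`; Levins breadth
  `B = 1/Σⱼ P²ᵢⱼ` across samples; **generalist/specialist** labels per
  taxon against a depth-preserving multinomial permutation null.
* **Assembly**: the Sloan neutral community model
  `F̂(p) = 1 − BetaCDF(d; Nm·p, Nm·(1−p))` fitted per group, and a
  normalized stochasticity ratio (NST) against a richness- and
  depth-preserving occupancy null.
* **Function linkage**: an averaged-z multifunctionality index over 11
  soil functions, Spearman **R values** per group × treatment stratum,
  and **D values** (R treated − R control).
* **Size regressions**: every per-group metric regressed on log₁₀ body
  size by OLS, the statistic behind each headline pattern.

A synthetic-study generator (`generate_bundle()`) with planted,
recoverable structure and a compiled neutral-assembly simulator
(`simulate_neutral()`) make the whole pipeline testable end to end
without field data.

## Worked example

```r
library(sizestab)

# a complete synthetic study: 2 crops x 25 fields x 4 treatments
bundle <- generate_bundle(synth_config(seed = 1))
rel    <- to_relative(bundle$community)
groups <- aggregate_groups(rel, bundle$annotation,
                           domain_of = bundle$domain_map)

# community resistance of every group under warming, per crop
res <- group_resistance(groups, bundle$meta, treatment = "warming")
head(res[, c("group", "crop", "rs_mean", "rs_sd", "n_pairs")], 3)
#>                 group  crop   rs_mean     rs_sd n_pairs
#> 1      Actinobacteria maize 0.8307866 0.1199914      25
#> 2 Alphaproteobacteria maize 0.7992280 0.1247828      25
#> 3  Betaproteobacteria maize 0.8386131 0.1149180      25

# does resistance decline with body size?
rs <- tapply(res$rs_mean, res$group, mean)
size_regression(setNames(as.vector(rs), names(rs)),
                default_group_sizes())
#>         slope intercept        r2      p_value  n
#> 1 -0.08724386 0.8069031 0.8235392 9.490354e-10 24
```

The slope is the change in mean resistance per decade of body size:
here small bacteria sit near RS ≈ 0.83 and the largest protists lose
roughly 0.09 of resistance per tenfold size increase (r² = 0.82,
p ≈ 1e-9) — the planted pattern, recovered.

`run_pipeline(pipeline_config(...))` executes every stage (validation,
coverage filter, resistance/stability, niche/generalists, NCM + NST,
function linkage, size regressions) and writes one TSV per stage plus a
JSON manifest; `inst/scripts/sizestab.R` is a small command-line
wrapper (`synth`, `run-all`). The methods vignette
(`vignettes/body-size-stability.Rmd`) documents every model,
parameter, and numerical choice.

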