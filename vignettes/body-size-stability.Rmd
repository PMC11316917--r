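---
title: "Body size and the stability of soil microbial communities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Body size and the stability of soil microbial communities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sizestab asks how the body size of soil organisms — from sub-micrometre
bacteria through fungi to protists hundreds of micrometres across —
relates to the stability of their communities under disturbances such as
warming and nutrient addition, and to their coupling with ecosystem
functions. It operates on paired control/treatment community tables from
incubated field soils and reduces them to a small set of per-group
statistics: resistance, diversity, niche breadth, generalist content,
assembly stochasticity, and function linkage, each finally regressed on
log10 body size.

This vignette documents the statistical machinery, the tunable
parameters, the synthetic-data generator used for validation, and the
numerical choices that were genuinely open.

## Data model

Four tables describe a study. The **community table** is a samples x
taxa count matrix. A **taxon annotation** maps each analysed taxon to a
domain (bacteria, fungi, protist), one of 24 organism groups, and a
characteristic body size in micrometres; taxa without a group are legal
and simply sit outside the analysed set (they still count toward domain
totals when a full taxon-to-domain map is supplied). **Sample metadata**
records field, crop, treatment and environmental covariates, and must
satisfy the pairing requirement: every disturbed sample's field also has
a control sample in the same crop. The **function table** holds the
measured ecosystem functions (11 by default).

Group abundance is, by default, the group's share of its *domain's*
reads in a sample (`aggregate_groups(relative_to = "domain")`). This
mirrors how marker-gene data are produced — bacterial (16S) and
eukaryotic (18S) reads come from separate amplifications, so
cross-domain read ratios are not biologically meaningful — and it keeps
the resistance contrast within the normalization unit where it is
measurable. Shares of the whole community are available via
`relative_to = "total"`.

The package ships a 24-group body-size lookup
(`default_group_sizes()`). Its sizes are synthetic, literature-plausible
fixture values spanning roughly 0.5-300 um; real analyses should supply
their own table, and the lookup file is named accordingly
(`group_sizes_synthetic.tsv`).

## Resistance and stability

Resistance uses the bounded Orwin-Wardle index per field pair,

$$RS = 1 - \frac{2\,|D_0|}{C_0 + |D_0|}, \qquad D_0 = C_0 - P_0,$$

with \(C_0\) the control and \(P_0\) the disturbed group abundance in
the same field. \(RS = 1\) means no change; total loss gives 0;
unbounded increase approaches -1. The index is scale-invariant, so it
does not matter that domain shares are used rather than absolute
abundances. Pairs with \(C_0 = 0\) carry no information and are skipped;
groups with fewer than three valid pairs are flagged.

Two supporting statistics summarize *why* an aggregate is stable.
Tolerance width is the abundance-weighted standard deviation of an
environmental covariate — wide means the group maintains abundance
across conditions. Nonsynchronization is one minus the
variance-ratio synchrony statistic
\(\varphi = \mathrm{Var}(\sum_i x_i)/(\sum_i \mathrm{SD}(x_i))^2\)
computed over member taxa across the ordered disturbance conditions
within a field, then averaged over fields; it is 0 when members move in
proportion and 1 when they cancel.

## Diversity, niche breadth, generalists

Shannon diversity \(H = -\sum p_i \ln p_i\) is computed per sample on a
group's member counts and averaged. Levins niche breadth
\(B = 1/\sum_j P_{ij}^2\) treats each sample as a habitat;
\(P_{ij}\) is the fraction of taxon *i*'s reads found in sample *j*, so
\(B\) runs from 1 (all reads in one sample) to the number of samples
(perfectly even occupancy). The group-level breadth is the
abundance-weighted mean over member taxa.

Generalists and specialists are called per taxon against a permutation
null that redistributes the taxon's total count across samples by a
multinomial draw with probabilities proportional to sample depths. This
null preserves uneven sequencing effort — the dominant artifact — and
represents a taxon with no environmental association at all. A taxon
whose observed breadth exceeds the upper 97.5% empirical quantile of
its null distribution is a generalist (flatter across fields than
sampling noise allows); below the 2.5% quantile, a specialist. Taxa
with fewer than 20 reads total are labeled neutral and flagged
`low_power` rather than tested. Defaults: 999 permutations, 95%
two-sided interval.

Classification in the pipeline uses the *control* samples within each
crop. The species-environment association of interest is the spatial
one across fields; including disturbed samples adds treatment-response
variance that overdisperses every taxon and drowns that signal.

## Assembly: neutral model and stochasticity ratio

The Sloan neutral community model predicts a taxon's occurrence
frequency from its mean relative abundance \(p\):

$$\hat F(p) = 1 - \mathrm{BetaCDF}(d;\; N\!m\,p,\; N\!m\,(1-p)),$$

with one free parameter \(Nm\) (community size times immigration rate)
and a detection limit \(d\). `fit_ncm()` estimates \(Nm\) by least
squares over a log-spaced grid refined by golden-section search — the
problem is one-dimensional, so this is deterministic and cannot get
stuck. Taxa observed in every sample or in none carry no information
about the curve and are excluded; at least 10 interior taxa are
required. The 95% band uses Wilson binomial intervals around the fitted
curve.

The detection limit defaults to **half** a read at the mean depth,
\(d = 0.5/\bar N\), a midpoint continuity correction: a zero count in a
discrete sample corresponds to a continuous abundance below half an
individual's worth. In Moran-model simulations the naive \(d = 1/\bar
N\) inflates the fitted immigration rate by 30-45%, while the midpoint
rule recovers it within about 10%; `d` remains overridable.

The normalized stochasticity ratio compares each observed pairwise
dissimilarity \(D_{ij}\) (Bray-Curtis on row proportions, or binary
Jaccard) with its mean \(\bar E_{ij}\) over null communities:

$$ST_{ij} = \begin{cases} D_{ij}/\bar E_{ij} & D_{ij} \le \bar E_{ij}\\
(1-D_{ij})/(1-\bar E_{ij}) & D_{ij} > \bar E_{ij}\end{cases}$$

averaged over pairs. This ratio form is bounded in [0, 1] and symmetric
about the null: 1 when observation matches the null, falling toward 0
as assembly becomes more deterministic than the null in either
direction (convergence or divergence). The null model preserves each
sample's richness and depth exactly; taxa are drawn without replacement
proportional to occupancy frequency and reads allocated multinomially
by regional mean abundance. Alternative nulls and both dissimilarity
metrics are exposed as arguments. The default 200 randomizations is a
desk-scale choice, lower than the 1000 often used in publications;
calibration (below) shows it suffices for the bounded ratio.

A Moran-type neutral simulator (`simulate_neutral()`, compiled) and a
gradient-filtering simulator (`simulate_filtered()`) provide matched
stochastic and deterministic references: death of a random resident,
replacement by immigration with probability *m* or local birth
otherwise, versus Gaussian environmental filtering around taxon optima.

## Function linkage

Multifunctionality is the averaging index: z-score each function across
the samples of a stratum, then average per sample. The **R value** of a
group in a (crop, treatment) stratum is the Spearman correlation
between the group's abundance and multifunctionality across that
stratum's samples; the **D value** is the treated-stratum R minus the
control-stratum R, so positive D means disturbance strengthened the
group's coupling to function. Per-function correlations are also
emitted (the heat-map view, with an optional Benjamini-Hochberg flag;
no adjustment is applied by default because the map is descriptive).

The Spearman implementation is the Pearson correlation of mid-ranks
with a t-approximation p-value, switching to an exact full-enumeration
permutation p-value for n <= 9.

All body-size trends use ordinary least squares of a per-group metric
on log10 size with the two-sided t-test on the slope. Any positive log
base would only rescale the slope. R- and D-value regressions pool the
two crops (doubling the stratum sample size); resistance, diversity
and breadth are strong enough per crop that pooling is a convenience.

## The synthetic study and what it validates

`generate_bundle()` builds a complete study with planted,
downstream-recoverable structure; its defaults are the package's
reference conditions: 2 crops x 25 fields x 4 treatments (control,
warming, N, P at unit doses 1, 0.8, 0.6), 24 groups spanning ~2.8
decades of size, 20-80 member taxa per group with richness decreasing
in size, a mean depth of 50,000 reads (negative-binomially dispersed),
and ~35% of each domain's reads in ungrouped background taxa so that
the groups cover about 65% of sequences — comfortably above the 60%
coverage rule that the coverage filter checks.

Planted effects, each switched by one parameter:

* **Disturbance sensitivity** `s_g = max(0, sensitivity_slope *
  log10(size_g))`: disturbed expected proportions are multiplied by
  `exp(-s_g * dose + eps)`. The noise `eps` has standard deviation
  `eps_sigma * (1 + 2 s_g)` — larger organisms respond more variably as
  well as more negatively. This variance component matters: under
  compositional normalization any suppression shared by a whole domain
  cancels, so a purely directional effect cannot produce the monotone
  resistance decline; response variance can. Setting
  `sensitivity_slope = 0` switches both off, which is the package's
  type-I control.
* **Niche differentiation**: per-taxon field effects (a small shared
  gradient response plus idiosyncratic field preferences) with standard
  deviation growing in size from 0.02 to 0.9 log units. This single
  mechanism drives the breadth decline, the specialist excess of large
  groups, and their lower assembly stochasticity.
* **Function links**: within each stratum all 11 functions share a
  latent activity axis built from standardized group abundances with
  strengths that rise with size in the control stratum and fall with
  size under treatment, plus a per-function own-group term and noise.
  Soil functions are strongly mutually correlated in reality, which the
  shared axis emulates; it is also what makes the multifunctionality
  correlation recoverable against inter-group correlation noise.

Two numerical choices deserve record. First, the disturbance noise is
split 60/40 between a group-coherent draw and taxon-idiosyncratic
scatter. The coherent part is self-damped by domain renormalization in
proportion to a group's domain weight (domains hold 12, 7 and 5 groups,
so this is size-correlated); the idiosyncratic part shrinks with group
richness (also size-correlated, oppositely). The split is set so the
two residual biases approximately cancel and the null planting is
clean: with `sensitivity_slope = 0`, resistance-size regressions are
non-significant in 19-20 of 20 seeds. Second, structure (baseline
compositions, field landscape) and sampling noise use separate seed
streams, so the same landscape can be resampled.

What passing tests show — and what they do not. The generator emulates
compositional count data with realistic depth variation, uneven taxon
abundances, field-level selection and correlated functions. It does not
simulate sequencing error, chimeras, copy-number variation,
compositional extraction bias, or phylogenetic correlation among taxa;
recovery of the planted patterns here demonstrates that the estimators
measure what they claim under the stated noise model, not that real
soils behave this way.

## Problem sizes and determinism

The validation suite runs the full pipeline on the default ~200-sample
bundle with 999 permutations for the generalist null and, for the
slower assembly stage, per-group NST at 200 randomizations; neutral
recovery uses S = 200 taxa, N = 1000 individuals, 60 samples and 50 N
update steps of burn-in (several relaxation times of the
drift-immigration balance). All randomness flows through named seed
arguments; rerunning any stage with the same configuration and seed is
byte-identical, and the pipeline manifest records the configuration
hash and every derived seed stream.

## Known limitations

* Body sizes enter as a single characteristic dimension per group;
  within-group size variation is ignored, and per-domain subgroup
  regressions (supported via subsetting the annotation) are the only
  robustness check offered.
* The resistance index is computed on relative (domain-share) data, so
  a change in a group's share can reflect other groups' responses; the
  background compartment softens but does not remove this.
* The NST variant implemented is the bounded ratio form above with an
  occupancy-proportional null; other published variants (incidence- vs
  abundance-weighted, different nulls) can give different absolute
  values, which is why the metric and null are swappable arguments and
  comparisons should be within one configuration.
* Tolerance width depends on the covariate supplied; with several
  covariates it is reported per covariate, never combined.
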