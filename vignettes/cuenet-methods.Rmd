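---
title: "Methods: carbon use efficiency, stoichiometry and co-occurrence networks in cuenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon use efficiency, stoichiometry and co-occurrence networks in cuenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuenet)
```

`cuenet` implements the full desk-side computation for a replicated
mycorrhizal field design: soil microbial growth, respiration and carbon use
efficiency (CUE) from ¹⁸O-H₂O quantitative stable isotope probing,
microbial biomass and stoichiometric imbalance from fumigation-extraction,
OTU-table diversity, SparCC co-occurrence networks per experimental group,
and the factorial statistics comparing them. This vignette explains the
models, the defaults and the numerical choices, and states what the
synthetic-data tests do and do not demonstrate.

## The qSIP rate model

During incubation with ¹⁸O-enriched water, oxygen in newly replicated DNA
derives from soil water. The amount of new DNA is

$$\mathrm{DNA_{produced}} = O_{total}\cdot\frac{at\%_{excess}}{100}\cdot
\frac{100}{at\%_{final}}\cdot\frac{100}{31.21},$$

where $O_{total}$ (μg) is the oxygen content of the dried DNA extract,
$at\%_{excess}$ the ¹⁸O atom-percent of labeled minus control DNA,
$at\%_{final}$ the soil-water enrichment at the start of incubation (20 at%
under the standard protocol) and 31.21 the average mass percentage of O in
DNA (monomer composition C₃₉H₄₄O₂₄N₁₅P₄). Two assumptions are inherited
from the labeling model: all O in new DNA comes from water, and mortality of
newly labeled cells during the short (24 h) incubation is negligible —
which is also why a negative measured $at\%_{excess}$ (possible under
instrument noise) is clipped to zero and flagged rather than propagated as
negative growth.

Growth in carbon units uses $f_{DNA}$, the ratio of microbial biomass C to
extractable DNA, computed per sample from that sample's own MBC and DNA
content (not as a group mean, so between-sample variation in extraction
efficiency is not averaged away):

$$\mathrm{Growth} = \frac{f_{DNA}\cdot \mathrm{DNA_{produced}}\cdot 1000}
{DW\cdot t}\quad[\mathrm{ng\,C\,g^{-1}\,h^{-1}}].$$

Respiration converts the blank-corrected headspace CO₂ mixing ratio $R_S$
(ppm) through the ideal gas law,

$$\mathrm{Respiration} = \frac{R_S}{DW\cdot t}\cdot\frac{p\,n}{R\,T}\cdot
V\cdot 1000,$$

with defaults $p = 101.325$ kPa, $T = 288.15$ K (15 °C), $V = 0.018$ L (a
20 ml headspace vial minus the 2 ml sample bottle), $n = 12.01$ g mol⁻¹ and
$R = 8.314$ J mol⁻¹ K⁻¹; all are configurable through
`incubation_config()`. The implementation is tested against an independent
mole-counting oracle (ppm → moles of gas → grams of C) to below 10⁻⁹
relative error. CO₂ is taken from the labeled vial; which vial the reading
comes from is a data-layout choice, and the record schema carries a single
`co2_ppm` column so either convention can be fed in. Finally

$$\mathrm{CUE} = \frac{\mathrm{Growth}}{\mathrm{Growth}+\mathrm{Respiration}}
\in [0, 1],$$

undefined (missing) only when both rates are zero. Mass-specific rates
divide by MBC; *turnover* is reported as growth/MBC. The literature uses
"turnover rate" loosely; the definition adopted here is surfaced in the run
manifest (`turnover_definition`) so downstream users are never guessing.

Rows that violate a precondition (e.g. soil-water enrichment not above the
control DNA reading) are carried through `process_incubation_table()` with
missing rates and a reason code — the output always has one row per input
sample, and `|input| = |rows with values| + |flagged rows|` is a tested
invariant.

## Fumigation chemistry

MBC and MBN are the fumigated-minus-unfumigated extract differences divided
by the conventional extraction efficiencies 0.45 (C) and 0.54 (N). Negative
flushes are clipped to zero with an audit flag: noise should not produce
negative biomass. The stoichiometric imbalance is
$(\mathrm{DOC}/\mathrm{TDN}) / (\mathrm{MBC}/\mathrm{MBN})$, with DOC and
TDN read from the *unfumigated* extract — the plain soil solution a microbe
experiences. All concentrations must share one mass basis (μg g⁻¹ dry
soil); the imbalance is then unit-scale invariant, which is tested.

## Community tables

Rarefaction subsamples each sample without replacement to an even depth
(seeded, via `vegan::rrarefy`); published rarefaction targets are read as
reads per sample and exposed as configuration. Richness and Shannon
diversity (natural log, `vegan::diversity`) are computed on rarefied
tables. Prevalence filtering keeps taxa present in at least the given
fraction of samples — inclusively, so a bacterial taxon in exactly 80 % of
samples survives the 80 % filter; the defaults are 0.8 for bacteria and 0.5
for fungi, reflecting the sparser fungal tables.

## SparCC correlation inference

Counts carry only relative information, and correlations of relative
abundances are distorted by the closure (every column sums to one). SparCC
instead uses log-ratio variances $t_{ij} = \mathrm{var}\,\log(x_i/x_j)$,
which are invariant to per-sample scaling, and the identity

$$t_{ij} = \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j$$

linking them to the basis (absolute-abundance) variances $\omega_i^2$ and
correlations $\rho_{ij}$. Under the sparsity approximation (average
correlation per taxon near zero) the basis variances solve the linear
system with matrix $(D-2)I + \mathbf{1}\mathbf{1}^\top$ and right-hand side
the row sums of $T$; for three uncorrelated taxa this reduces to the closed
form $\omega_i^2 = (t_{ij}+t_{ik}-t_{jk})/2$, which the implementation
matches to 10⁻⁶ and uses as its unit oracle. Pairs whose estimated
$|\rho|$ exceeds 0.1 are excluded from the system one at a time (strongest
first, at most 10 rounds) and the variances re-solved; these two internals
are not published for the original workflow, so the reference algorithm's
conventional values are adopted and exposed as arguments. A taxon cannot be
excluded into ill-posedness: exclusion stops when a diagonal entry would
drop to 2, which also means the 3-taxon closed form is never perturbed.

Zeros are handled with a +1 pseudocount; the full estimate is the
element-wise median of 20 estimates, each computed on per-sample fractions
drawn from Dirichlet(counts + 1) — the posterior under a uniform prior —
which damps low-count noise. Pseudo *P*-values come from a permutation
null: each taxon's counts are shuffled independently across samples
(destroying association, preserving marginals), the estimator re-run on
each of 100 such datasets, and $\hat p_{ij} = (1 + \#\{|r_b| \ge
|r_{obs}|\})/(B+1)$ — the add-one rule keeps $p \ge 1/(B+1)$, so 100
bootstraps can attain at best $p = 1/101 < 0.05$. The exact null used by
the original Gephi/SpiecEasi workflow is not documented; the permutation
null is stated here and in the output metadata.

Two behaviours of the estimator are worth knowing. First, with very few
taxa the sparsity assumption and the permutation null both degrade: when
two taxa dominate the composition, the closure couples them even after
permutation, so their null $|r|$ is not small. Networks should be inferred
on prevalence-filtered tables of a few dozen taxa or more. Second, the null
level of any correlation estimate is bounded below by sampling noise,
$E|r| \approx \sqrt{2/\pi}/\sqrt{n-1}$ (≈ 0.057 at $n = 200$); recovery
tests therefore measure RMSE against planted truth and the ranking of
planted pairs, not the literal vanishing of null estimates.

## Networks and topology

An edge requires $|r| > 0.65$ **and** $p < 0.05$, both strict, so boundary
values are excluded; isolated taxa are dropped (node counts in
co-occurrence studies conventionally mean connected OTUs). Bacterial and
fungal tables are filtered separately (80 %/50 %), then concatenated and
renormalised jointly per sample before correlation, giving one
cross-domain network per mycorrhizal type × position group.

Topology metrics follow the standard definitions: density $2L/(n(n-1))$,
average connectivity $2L/n$, weighted degree with $|r|$ weights, mean local
clustering coefficient (zero for degree < 2), mean eigenvector centrality,
and Freeman degree centralization $\sum_i(k_{max}-k_i)/((n-1)(n-2))$
(undefined below 3 nodes). Diameter and average path length are computed
unweighted on the largest connected component — the whole-graph versions
are infinite on disconnected graphs, and the choice is recorded in the run
manifest. Communities come from greedy modularity maximisation
(`igraph::cluster_fast_greedy`, deterministic and seeded); layout-coupled
detectors are not bit-reproducible, which is why a seeded detector is used
and named. Module composition reports the three largest modules (ties by
module id) with their bacterial/fungal shares. All formulas are verified
against hand-computed values on complete, star, path, cycle and
disjoint-clique graphs — e.g. two disjoint triangles give modularity
exactly $2(1/2 - 1/4) = 0.5$. Degree distributions of two networks are
compared with the two-sample Kolmogorov–Smirnov statistic (degrees are
discrete, so the asymptotic statistic is reported and tie warnings are
expected); note the hand-computable example that a 10-node star against a
10-node complete graph gives $D = 0.9$, not 1 — the hub's degree equals the
complete graph's.

## Group statistics

The species design is unbalanced (8 AM vs 7 ECM species), so factorial sums
of squares are type II (`car::Anova`): each main effect adjusted for the
other, which does not depend on term order. Responses are routed by a
Shapiro–Wilk gate on the residuals of the factorial fit (α = 0.05): pass →
two-way ANOVA; fail → retry after log transform (positive responses); still
fail → Scheirer–Ray–Hare. The SRH statistic is the factorial ANOVA on
mid-ranks with $H = SS_{effect}/MS_{total}$ referred to χ² — using the
observed rank variance as $MS_{total}$ applies the tie correction
automatically and makes the single-factor case collapse *exactly* to
tie-corrected Kruskal–Wallis, which is tested. Wilcoxon position contrasts
are unpaired by default (whether rhizosphere and non-rhizosphere samples
were paired by tree is not generally knowable from the tables; a paired
mode exists), exact for ≤ 25 per group without ties, and verified against
exhaustive enumeration of rank assignments for small n. The Spearman screen
reports raw p-values by default, as co-occurrence studies conventionally
do; Benjamini–Hochberg adjustment is available (`adjust = "BH"`) but off.
Both factorial tests are calibration-tested: empirical type-I error over
1000 seeded null simulations must stay within [0.03, 0.07] at nominal 0.05.

## The synthetic-data generator

`simulate_study()` emulates the field design: 8 AM + 7 ECM species × 2
positions × 5 replicates = 150 samples. Each design cell carries true mean
growth, respiration, MBC, MBN, DOC and TDN; the generator *inverts* the
measurement equations, so the emitted instrument readings (O content, at%
values, CO₂ ppm, extract concentrations) reproduce the truths exactly at
zero noise — the round-trip recovery test demands < 10⁻⁹ relative error.
Default truths are chosen to be realistic for temperate forest soils
(growth 90–150, respiration 150–350 ng C g⁻¹ h⁻¹, MBC 300–400 μg g⁻¹) and
to encode the contrast of scientific interest: equal growth but higher
rhizosphere respiration under ECM, hence ECM non-rhizosphere CUE 0.5
against 0.3 elsewhere — an absolute CUE difference of 0.2 whose detection
power is itself an acceptance property (> 80 % over 200 seeded runs at
noise CV 0.15).

Measurement noise is multiplicative log-normal with a configurable
coefficient of variation (default 0.15); field studies rarely report their
instrument error, so the default is editorial and exposed. The log-normal
choice keeps every generated concentration and isotope ratio positive. The
control-vial DNA is set at the ¹⁸O natural abundance, 0.2 at%. One
propagation effect deserves emphasis: growth depends on the *difference* of
two at% readings, so when enrichment is weak the relative error of growth
is several times the per-reading CV. The noise tests therefore distinguish
the strong-labeling regime (where growth CV ≈ reading CV) from the default
weak-enrichment regime, and verify the exact error-propagation prediction
in both.

OTU tables are multivariate log-normal basis abundances (given correlation
matrix, log-mean ramp over ~4 natural-log units, log-sd 1) closed to
fractions and sampled multinomially at fixed depth — the generative model
under which SparCC is consistent. The default study plants two 6-taxon
bacterial guilds and one 4-taxon fungal guild at basis correlation 0.85 so
that the network stage has structure to recover. What the generator does
*not* emulate: sequencing error and chimeras, taxon-specific DNA extraction
efficiency, isotope fractionation, overdispersion beyond multinomial,
spatial or temporal autocorrelation, and any coupling between community
composition and the rate truths. Passing recovery tests therefore
demonstrates the correctness of the computations and the detectability of
planted effects under idealised noise — not that field data meet these
assumptions.

## Problem sizes and reproducibility

Test and acceptance runs use: 150-sample studies for round trips and power
(200 simulated studies), 50 taxa × 200 samples × 50 000 reads for SparCC
recovery, 1000 null simulations for calibration, and reduced SparCC
iteration/bootstrap counts (3–10) inside the orchestration tests; the
pipeline defaults remain 20 iterations and 100 bootstraps. Every random
step takes a seed; the pipeline derives per-stage seeds from one master
seed by hashing the stage name (`stage_seed()`), so adding a stage never
shifts another stage's stream, and a run manifest (seed, thresholds,
versions, definitional choices) is written alongside the results.

## Known limitations

- The sparsity assumption fails for tiny or strongly block-correlated
  communities; estimates for dominant-taxon pairs are then untrustworthy
  (and their permutation-null p-values conservative in the wrong
  direction).
- Pseudo p-values inherit the granularity $1/(B+1)$; with the default
  B = 100 the smallest attainable p is ≈ 0.0099.
- The Scheirer–Ray–Hare test is approximate in unbalanced designs (type-II
  rank SS is one defensible convention among several).
- CUE is a ratio of noisy rates; its uncertainty is strongly asymmetric at
  weak labeling, and no delta-method correction is applied.
- Diameter/path length on the largest component understate disconnection;
  consult `n_communities` and component sizes together.
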