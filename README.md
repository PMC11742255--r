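# cuenet

Soil microbial **carbon use efficiency (CUE)** and **bacterial–fungal
co-occurrence networks**, from raw incubation measurements to group-level
statistics, in one tested R pipeline.

Forest soils under arbuscular mycorrhizal (AM) and ectomycorrhizal (ECM)
trees host free-living microbial communities whose carbon metabolism is
commonly characterised by three linked quantities: how fast microbes grow,
how fast they respire, and what fraction of the carbon they take up ends up
in biomass. `cuenet` is for soil ecologists and microbiome researchers who
collect ¹⁸O-H₂O labeling data, chloroform-fumigation extracts and
bacterial/fungal OTU tables for such designs (mycorrhizal type × rhizosphere
position, replicated per tree species) and want the whole downstream
computation — rates, stoichiometry, diversity, networks, statistics — to be
reproducible and verifiable against synthetic ground truth.

## What it computes

**¹⁸O-qSIP rates.** During a 24 h incubation with ¹⁸O-enriched water, oxygen
from soil water is built into newly synthesised DNA:

    DNA_produced = O_total · (at%_excess / 100) · (100 / at%_final) · (100 / 31.21)
    Growth       = f_DNA · DNA_produced · 1000 / (DW · t)
    Respiration  = R_S / (DW · t) · (p · n) / (R · T) · V · 1000
    CUE          = Growth / (Growth + Respiration)

with `O_total` the O content (μg) of the DNA extract, `at%_excess` the ¹⁸O
enrichment of labeled over control DNA, `at%_final` the soil-water labeling
(20 at%), 31.21 the mass % of O in DNA, `f_DNA = MBC / DNA content`,
`R_S` the blank-corrected headspace CO₂ (ppm) converted through the ideal
gas law. Mass-specific rates (qGrowth, qCO₂, qUptake) and turnover divide by
microbial biomass C.

**Soil chemistry.** MBC and MBN from fumigation-minus-control extract
differences divided by the extraction efficiencies 0.45 and 0.54, and the
stoichiometric imbalance `(DOC/TDN) / (MBC/MBN)` between resource and
biomass C:N.

**Community tables.** Rarefaction (without replacement, seeded), species
richness, Shannon diversity, and prevalence filtering (keep bacterial OTUs
present in ≥ 80 % of samples, fungal in ≥ 50 %).

**SparCC networks.** Compositionality-robust correlations from log-ratio
variances `t_ij = var(log x_i/x_j)` under a sparsity assumption, with
iterative exclusion of strongly correlated pairs, the element-wise median of
20 Dirichlet-resampled estimates, and permutation pseudo *P*-values from 100
bootstraps. Edges require `|r| > 0.65` and `P < 0.05` (both strict); one
network per AM/ECM × rhizosphere/non-rhizosphere group, summarised by nodes,
links, avgK, weighted degree, diameter, path length, density, modularity,
communities, clustering coefficient, eigenvector centrality and Freeman
degree centralization, plus module composition and Kolmogorov–Smirnov
comparison of degree distributions.

**Group statistics.** Shapiro–Wilk-gated routing between type-II two-way
ANOVA and the Scheirer–Ray–Hare rank test, Wilcoxon position contrasts, and
a Spearman screen of CUE predictors.

**Synthetic studies.** `simulate_study()` inverts all measurement equations
for a known truth (8 AM + 7 ECM species × 2 positions × 5 replicates = 150
samples; multivariate log-normal → multinomial OTU counts with planted basis
correlations), so every stage has an exact recovery test.

## Worked example

```r
library(cuenet)

# one vial pair, measured by hand
dna_produced(10, 5.2, 0.2, 20)$dna_produced   # 8.010253 ug new DNA
respiration_rate(1000, DW = 1, t = 24)        # 380.9713 ng C/g/h
cue(100, 300)                                 # 0.25

# a full synthetic study with known truth, then the whole pipeline
study  <- simulate_study(study_design(), seed = 3)
bundle <- run_study(study, run_config(seed = 3))
bundle$topology[, c("group", "n_nodes", "n_links", "avgK", "modularity")]
```

```
                group n_nodes n_links     avgK modularity
1  AM.non_rhizosphere      16      35 4.375000  0.5875939
2      AM.rhizosphere      14      31 4.428571  0.5266811
3 ECM.non_rhizosphere      16      36 4.500000  0.6231787
4     ECM.rhizosphere      16      32 4.000000  0.5693118
```

The four group networks recover the guilds planted in the generator (two
6-taxon bacterial blocks and one 4-taxon fungal block at basis correlation
0.85) as their top modules, and `bundle$stats` flags the planted mycorrhizal
CUE contrast (ECM non-rhizosphere CUE 0.5 vs AM 0.3). `write_bundle(bundle,
"out/")` exports every table plus GraphML/CSV networks; a command-line
wrapper with `simulate | cue | chem | diversity | network | stats | all`
subcommands lives in `inst/cli/cuenet.R`.

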