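# gutMetacom

Core–satellite metacommunity analysis of host-associated gut
microbiota, for ecologists studying how parasite burden and host traits
shape 16S phylotype communities sampled along the gastrointestinal
tract of a wild host population.

Given a taxa × sample count table and per-sample host covariates
(site, sex, mass, age, phenology, helminth count), the package runs the
full analysis chain such a study requires:

* **Core/satellite partitioning.** Each taxon's index of dispersion
  *I* = s²/x̄ over all samples of a metacommunity is tested against the
  χ² dispersion limit — under Poisson placement (n−1)·I ~ χ²ₙ₋₁ — so
  over-dispersed, aggregated taxa are labelled *core* and randomly
  dispersed or single-sample taxa *satellite*, alongside the occupancy
  vs log₁₀ mean-abundance coherence regression.
* **Raup–Crick stochasticity.** Pairwise S_RC under an
  occupancy-weighted Monte Carlo null (ties half-weighted): S_RC > 0.95
  is deterministic similarity, < 0.05 deterministic dissimilarity, the
  middle stochastic assembly.
* **Diversity and between-microbiome tests.** Fisher's log-series α
  (the root of S = α·ln(1 + N/α)) per local community, two-sample
  *t* contrasts, ANOSIM (R = (r̄_B − r̄_W)/(n(n−1)/4) on ranked
  Bray–Curtis dissimilarities, permutation or exact P) and SIMPER
  decomposition of between-group dissimilarity.
* **CCA with forward selection.** Chi-square-standardised table
  projected onto host variables; candidates admitted by Monte Carlo
  permutation P < 0.05 of their additional inertia, reported as
  percent of total variation plus an undetermined remainder.
* **Burden dysbiosis.** Median split of hosts by helminth count
  (high = strictly above the median), volcano log₂ fold changes with
  per-taxon *t*-tests on relative abundances, and gained/lost
  accounting of taxa detected in only one burden group.
* **Synthetic data.** A generator (`simulateMetacommunity`) emulating
  the statistical structure of a three-microbiome wild-bird study —
  overdispersed core vs Poisson satellite taxa, sex-linked mass and
  burden, per-site determinism and burden-effect gradients — with
  ground-truth labels for parameter-recovery testing.

Everything is seed-reproducible end to end; `runPipeline()` +
`writePipelineOutputs()` produce a machine-readable TSV bundle with the
seed and parameters recorded in `#` header lines.

## Worked example

```r
library(gutMetacom)

cfg <- metacomConfig(seed = 1)        # 40 hosts; 38/39/10 samples per site
sim <- simulateMetacommunity(cfg)
sim$experiment
#> MetacomExperiment: 455 taxa x 87 samples
#>   sites: cloaca (n=39), faeces (n=10), proventriculus (n=38)
#>   reads/sample: median 67273

partitionCoreSatellite(sim$experiment, site = "proventriculus")
#> PartitionResult: 299 taxa over 38 samples
#>   core 105, satellite 194 (single-sample 72); chi2 limit 1.505 (tail 0.025)
#>   core relative-abundance share: 99.9%
#>   occupancy ~ log10(abundance): slope 8.64, r2 0.94, P 1.77e-183
```

Of the 299 taxa detected in the stomach-site metacommunity, 105 are
over-dispersed core members carrying 99.9% of the reads; 72 satellites
occurred in a single sample and the rest were Poisson-consistent. The
strong positive occupancy–abundance regression is the expected
signature of a coherent metacommunity.

```r
raupCrick(sim$experiment, site = "faeces", nRand = 1000, seed = 1)
#> RaupCrickResult: 10 samples, 45 pairs (occupancy_weighted null, 1000 randomisations, seed 1)
#>   S_RC > 0.95: 100.0%; < 0.05: 0.0%; stochastic: 0.0%

md <- as.data.frame(SummarizedExperiment::colData(
  siteExperiment(sim$experiment, "faeces")))
split <- splitByMedian(setNames(md$nematode_count, md$sample_id))
part <- partitionCoreSatellite(sim$experiment, site = "faeces")
burdenDysbiosis(counts(siteExperiment(sim$experiment, "faeces")), split, part)
#> DysbiosisReport: 179 taxa in volcano (3 significant), 49 gained, 53 lost
#>   significant by fraction: core 2, satellite 1
```

The whole-community faecal pairs are all more similar than the
occupancy-weighted null expects (deterministic assembly); the
median-burden split then flags burden-responsive taxa in the volcano
table (`volcanoTable()`), with taxa detected in only one burden group
listed by `gainedTaxa()`/`lostTaxa()` instead of receiving infinite
fold changes.

`runPipeline(sim$experiment, seed = 1)` chains all of the above per
site and fraction (whole/core/satellite), adds between-microbiome
ANOSIM/SIMPER and CCA forward selection of host variables, and
`writePipelineOutputs()` exports every table. A thin command-line
wrapper for the two shell-level entry points (`simulate`, `run-all`)
ships in `inst/scripts/metacom-pipeline.R`.

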