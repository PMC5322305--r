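---
title: "Core-satellite metacommunity analysis of gastrointestinal microbiota: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-satellite metacommunity analysis of gastrointestinal microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutMetacom)
```

## The scientific setting

gutMetacom analyses 16S phylotype count tables from linked
gastrointestinal microbiomes of a wild host population — the motivating
system is a seabird colony of about 40 hosts sampled at the
proventriculus (the glandular stomach and site of nematode infection),
the cloaca and faeces, with per-host covariates (sex, mass, age, brood
phenology, chicks fledged) and an endoscopic helminth count per host.
Each site's set of local communities (samples) is treated as a
metacommunity, and the package asks three questions about it: which
taxa are structural "core" members and which are transient
"satellites"; how much of pairwise community similarity is forced
(deterministic) rather than expected under random draws from the
regional pool; and how host variables — helminth burden above all —
co-vary with composition, both globally (ordination) and per taxon
(volcano fold changes, gained/lost accounting).

## Core/satellite partitioning by the index of dispersion

For each taxon, counts across all $n$ samples of one metacommunity
(zeros included) give the index of dispersion $I = s^2/\bar{x}$, with
the unbiased $n-1$ variance. Under Poisson (random) placement,
$(n-1)\,I \sim \chi^2_{n-1}$, the classical dispersion test. A taxon is
called **core** when $(n-1)I$ exceeds the $\chi^2_{n-1}$ quantile at
$1-\text{tail}$ (default tail 0.025, i.e. the upper bound of the
central 95% interval): its distribution across samples is aggregated
beyond what randomness allows. Taxa at or below the limit are
**satellite** (reason `random_dispersion`), and taxa found in exactly
one sample are satellite outright (reason `single_sample`) — spatial
dispersion of a single occurrence has no usable variance. Taxa with
zero reads everywhere are dropped as not being members of the
metacommunity.

Two conventions deserve mention because published descriptions of this
procedure are often ambiguous about them:

* **Which tail.** Verbal descriptions of "falling below the 2.5%
  confidence limit" can mean either $\chi^2$ quantile. We use the upper
  quantile — non-random means *over*-dispersed — which is the only
  reading under which "no taxa fell below the other limit" is the
  typical outcome for sequence count data. The tail is a user-facing
  parameter, not an assertion about any particular study's intent.
* **Zeros count.** Mean and variance are over *all* samples of the
  metacommunity, so occupancy and abundance are coupled; this is what
  makes the occupancy vs $\log_{10}$ mean-abundance regression
  (`occupancyAbundanceRegression`) a meaningful coherence check.

`partitionBookkeeping()` exposes the accounting identity
(core = total − random − single-sample) so that published summary
totals can be checked for internal consistency without the raw data.

## Raup–Crick stochasticity classification

For a pair of communities with richnesses $r_a, r_b$ over a pool of $G$
taxa, the null model draws $r_a$ and $r_b$ taxa without replacement,
with selection probability proportional to each taxon's observed
occupancy in the metacommunity (or uniform under `equal_weight`), and
records the shared count. With ties split,
$$S_{RC} = \frac{\#\{\text{null} < \text{obs}\} + \tfrac12\#\{\text{null} = \text{obs}\}}{n_{\text{rand}}},$$
so $S_{RC} > 0.95$ marks pairs significantly *more* similar than chance
(deterministic assembly), $S_{RC} < 0.05$ significantly less, and the
middle stochastic. The half-weight tie rule is what makes $S_{RC}$
approximately uniform when both communities really are null draws — the
property the acceptance suite verifies at 500 pairs.

Two numerical notes. First, the matrix routine (`raupCrick`) simulates
each sample's null community once per randomisation and scores every
pair against that one set of draws; each pair's marginal null
distribution is identical to independent pairwise simulation
(`srcPair`), but the cost is linear rather than quadratic in samples.
Second, when the observed shared count is zero no null draw can fall
below it, so fully disjoint communities score $\tfrac12 P(\text{null
shared}=0)$ — near 0.5 over a large sparse pool — rather than a small
tail value. Deterministic *dissimilarity* therefore requires communities
that avoid each other relative to a null that would usually make them
overlap.

## Diversity, ANOSIM and SIMPER

Per-sample diversity is Fisher's log-series $\alpha$, the positive root
of $S = \alpha \ln(1 + N/\alpha)$, solved by bracketed root finding to
a residual below $10^{-8}$ ($S$ = richness, $N$ = reads; undefined and
flagged when $S = 0$ or $N \le S$). Alpha's relative insensitivity to
$N$ is the reason no rarefaction step is included. Group contrasts
(between sites; between sexes within a site; separately for the whole,
core and satellite fractions) use classic two-sample $t$-tests, pooled
variance and two-sided by default, with Welch and one-sided variants
emitted because published $t$/$P$ pairs do not always say which was
used.

ANOSIM ranks all pairwise Bray–Curtis dissimilarities (ties
mid-ranked) and computes
$R = (\bar{r}_B - \bar{r}_W) / \left(n(n-1)/4\right)$, which is exactly
1 when every between-group pair is more dissimilar than every
within-group pair. The permutation $P$ uses the add-one rule with ties
counted as extreme; for small designs `exact = TRUE` enumerates all
distinct relabellings instead. SIMPER decomposes the mean between-group
Bray–Curtis dissimilarity into per-taxon contributions
($|x_{ik}-x_{jk}|/\sum_l (x_{il}+x_{jl})$ averaged over between-group
pairs), on per-sample relative abundances by default so the reported
mean abundances are percentages; the contributions sum to the overall
mean dissimilarity by construction, and the tests assert that identity
to $10^{-10}$.

## CCA with permutation forward selection

The community table is $\chi^2$-standardised
($\bar{Q} = (P - rc^\top)/\sqrt{rc^\top}$ for the proportion table $P$
with row and column sums $r, c$), giving total inertia
$\sum \bar{Q}^2$ — identically the table's chi-square statistic over
its grand total. Explanatory variables are weighted-centred, scaled by
$\sqrt{r}$, and $\bar{Q}$ is projected onto their span; the projected
matrix's singular values squared are the canonical eigenvalues and its
squared norm the constrained inertia. Two-level factors are coded 0/1;
more levels must be coded explicitly.

Forward selection repeatedly takes the candidate adding the most
constrained inertia given the already-selected set and admits it only
if a Monte Carlo permutation test (candidate's values permuted across
samples; default 1000 permutations, add-one $P$) gives $P < \alpha$
(default 0.05); candidates that are collinear with the selected set are
never admitted. Each admitted variable is reported as its *additional*
inertia as a percentage of total inertia, with the remainder as
"undetermined", so the column sums to 100 exactly. Because published
percent-variation tables do not always say whether entries are
conditional (selection-step) or marginal (variable-alone) values, both
modes are implemented (`mode = "conditional"` / `"marginal"`) and
labelled; conditional is the default.

## Burden dysbiosis

Hosts are split at the median helminth count — strictly greater than
the median is "high" — mirroring the convention in which a median of
21 worms puts counts of 22 and above in the high group. For each taxon
detected in both groups the report gives the $\log_2$ fold change of
mean relative abundance (positive = higher under high burden) and a
two-sample $t$-test on per-sample relative abundances, with the
volcano significance line at $P = 0.05$ and *no* multiplicity
correction for the headline flag (a Benjamini–Hochberg column is
emitted alongside, for readers who want it). Taxa detected in exactly
one group would have infinite fold change; they are routed instead to
the gained/lost accounting, tagged core/satellite and ranked by mean
relative abundance where present. Every taxon of the metacommunity is
thus exactly one of: volcano-analysed, gained, lost, or absent from
both groups.

## The synthetic-data generator

Because the motivating study's raw reads live in a sequence archive and
its headline numbers derive from that specific dataset, validation here
is against a generator that reproduces the *statistical structure* the
analysis assumes, with known truth labels:

* **Hosts** (default 40): male mass $\mathcal{N}(1896.2, 121.9)$ g,
  female $\mathcal{N}(1614.0, 103.1)$ g; nematode burdens
  $\mathcal{N}(28, 14.8)$ (males) and $\mathcal{N}(20, 8.1)$ (females),
  rounded and clamped to the observed 3–45 range (clamping was chosen
  over truncated-normal resampling for simplicity and testability; it
  censors the male upper tail, so the realised sex difference is ~7.3
  worms rather than the nominal 8, and the tests check against the
  censored-normal integral); ages 3–17 (gamma-shaped, mean ≈ 7.8);
  1–3 chicks fledged (mean 2.25); early phenology with probability
  23/40.
* **Sites** default to 38/39/10 samples (proventriculus, cloaca,
  faeces), each sampling a random host subset, with per-site taxon sets
  (default 300) drawn from a shared pool 1.6× larger so neighbouring
  microbiomes overlap without coinciding.
* **Core taxa** (default a third of each site's taxa) get log-normal
  template means — no abundance family is dictated by the motivating
  analysis, and log-normal reproduces the straight-line occupancy vs
  log-abundance pattern — scaled so a sample's expected reads match
  `librarySizeMean` (default 70 000, with log-normal per-sample factors
  of sd log 0.6 emulating the large read-depth spread of real runs),
  and negative-binomial counts (size 0.7), i.e. dispersion indices far
  above 1 and occupancy near 100%.
* **Satellite taxa** are low-mean Poisson (λ log-normal around 0.3),
  deliberately *not* scaled by library size so their dispersion index
  stays at the Poisson value of 1 — the property the partition's
  satellite rule tests; a configurable fraction (default 0.35, the
  order observed in real partitions) is seeded into exactly one sample.
* **Determinism** $d \in [0,1]$ mixes, on the log scale, the shared
  site template with sample-specific random composition. Note what this
  does and does not control: deterministic ($S_{RC} > 0.95$) pairs in
  the generator arise chiefly from the core/satellite occupancy
  contrast (every sample carries the full core block, while the
  occupancy-weighted null also draws satellites); low $d$ adds presence
  turnover and abundance decorrelation, which shows up strongly in
  ANOSIM/CCA noise and only weakly in the Raup–Crick percentages. The
  per-site defaults (0.9, 0.6, 0.3) encode the
  stomach-to-faeces gradient.
* **Responder taxa** (default 8 core taxa per site, ~60% negative)
  have expected counts multiplied by $\exp(\text{effect} \times z)$
  where $z$ is the host's standardised burden; the multiplicative
  pre-sampling action makes log fold-change recovery clean. Per-site
  effects default to (0.3, 0.7, 1.2) — increasing away from the
  infection site, the gradient the ordination analysis should detect.

What passing tests on this generator do **not** show: robustness to
compositional artefacts of real sequencing (the generator's responders
shift absolute expectations), to phylogenetically correlated taxa, to
contaminant structure, or to OTU-clustering noise — all upstream of
this package's scope.

## Numerical choices and degenerate inputs

Reproducibility is end-to-end: every randomised stage takes a seed, the
pipeline derives per-stage seeds deterministically from one master
seed, and each output file records it in `#` header lines. Degenerate
inputs are flagged rather than silently absorbed: zero-mean taxa have
undefined dispersion, Fisher's alpha is `NA` outside $0 < S < N$,
zero-variance diversity comparisons return $t = 0, P = 1$ only when the
groups are genuinely identical, an all-equal burden vector (empty high
group) is an error, and rank-deficient CCA designs are warned about or,
in forward selection, simply never admitted. Test problem sizes (≤ 40
hosts, ≤ 300 taxa, permutation counts 199–1000, with 10⁵ randomisations
only where Monte Carlo exactness itself is under test) were chosen so
the full suite exercises every calibration property at 3-standard-error
tolerances while remaining comfortably interactive.

## Known limitations

Only two-level factors are auto-coded in CCA; multi-level factors need
explicit indicators. The Raup–Crick null conditions on observed
richness and occupancy, the standard choice, but other conditioning
schemes (fixed frequency, abundance-weighted) are out of scope, as are
PERMANOVA, ordination plotting, alternative core definitions and
compositional differential-abundance models — the volcano analysis
deliberately mirrors the simple relative-abundance $t$-test procedure
it reimplements, and should be read with that procedure's known
caveats.
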