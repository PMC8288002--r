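---
title: "Models and methods behind invadepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind invadepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invadepop)
```

`invadepop` reconstructs the history and selective environment of a recent
biological invasion from reduced-representation SNP genotypes. The package
was designed around a concrete study system — guppy (*Poecilia reticulata*)
populations introduced to Hawaiian stream watersheds roughly a century ago
from an unknown native-range source — but every stage is generic: genotypes
in, population structure, admixture tests, demographic reconstruction and
genotype–environment association out. This vignette explains the models,
the numerical choices, and what the built-in synthetic data can and cannot
tell you about real data.

## The synthetic-data generator

Every estimator in the package can be exercised against data with a known
answer. `scenario_config()` + `simulate_invasion()` draw unlinked biallelic
SNP genotypes under a backward-in-time structured coalescent (implemented
in C++) with demes, population joins (forward-time splits), admixture
pulses (translocations), piecewise-constant sizes and optional continuous
migration.

The default scenario mirrors the study design: 18 watershed demes on 4
islands (3 + 8 + 4 + 3), four native-range populations, 282 diploid
individuals with per-watershed sample sizes between 3 and 29, and 12,254
SNPs carrying 23 chromosome labels. The invasion story is single-source:
all Hawaiian ancestry passes through one founding bottleneck
(N~e~ = 100 diploids) 350 generations before present — 100 years at the
guppy's 3.5 generations per year — with islands splitting from the
introduction hub at 300 generations and watersheds within islands at 250.
Established watersheds have N~e~ = 1000 (matching the scale of the study's
stairway point estimates, median ≈ 1087), native populations N~e~ = 5000
with deep splits (5,000–12,000 generations). The mutation rate default is
4.89 × 10⁻⁸ per site per generation. Missing genotype calls are injected
completely at random at 10% to exercise the filter/imputation chain.

Two mutation modes matter:

* **`"snp"`** places exactly one mutation per genealogy on a branch chosen
  proportionally to its length. This fixes the SNP count, but the
  resulting frequency spectrum follows E[L~c~/L~tot~], the *conditioned*
  spectrum — appropriate for structure, F~ST~ and D statistics, which are
  frequency ratios.
* **`"poisson"`** drops a Poisson number of infinite-sites mutations with
  an explicit per-site rate, so expected SFS counts equal
  μL·E[branch length] — the quantity the demographic likelihoods model.
  SFS-based fitting should always use this mode; fitting branch-length
  expectations to one-SNP-per-locus data biases split-time estimates
  upward by tens of percent (we measured ≈ +80% at T = 0.01 before
  switching).

Loci are unlinked across genealogies; in `"poisson"` mode SNPs within one
genealogy are perfectly linked, which gives the chromosome-block bootstrap
and jackknife genuine linkage structure to correct for. Within-block
recombination is not modelled. Selection is injected after the fact by
`inject_environmental_selection()`, which resamples genotypes at chosen
loci from logit-linear population frequencies
p~w~ = logistic(a + b·env~w~) — sufficient for association-test truth at a
tiny fraction of the cost of forward simulation, but it does not create
linked sweeps or clinal haplotypes.

What passing tests on these data do **not** show: robustness to
genotyping error, allele dropout, batch effects, real LD decay, or
reference bias. The generator's null is cleaner than any RAD dataset.

## Quality control and diversity

`apply_quality_filters()` applies, in order: (1) minor allele frequency —
loci with MAF ≤ 0.03 over all non-missing calls are removed (the boundary
is inclusive); (2) individuals with > 75% missing calls are removed;
(3) loci with > 50% missing calls are removed (both boundaries
exclusive). The order is fixed; MAF is computed globally. Imputation
replaces the study pipeline's haplotype-phasing tool with per-population
Hardy–Weinberg draws at the within-population allele frequency (global
frequency as fallback): downstream statistics here consume dosages and
frequencies, never phase, so a phase-aware imputer would buy nothing.
Expected heterozygosity 2p(1−p) and nucleotide diversity 2p(1−p)·n/(n−1)
are reported per variant site and — when a total sequence length L is
supplied — per sequence site, the scale on which reduced-representation
studies print them (magnitudes of 10⁻³–10⁻⁴).

## Population structure

* **PCA** (`genotype_pca()`): column-centred dosage decomposition,
  optionally 1/sqrt(p(1−p)) scaled; deterministic up to sign.
* **Admixture** (`admixture_fit()`): the individuals × loci frequency
  matrix (dosage/2) is factorized as Q·F with Q rows on the probability
  simplex and F in [0, 1], by alternating projected least squares
  (exact simplex projection per row; ridge 10⁻⁸; max 200 iterations;
  relative-loss tolerance 10⁻⁶). Model choice follows the sparse-NMF
  tradition: a random 5% of matrix entries is held out, predicted as
  binomial probabilities Q·F, and scored by cross-entropy. Two details
  matter for a stable choice of K. First, `admixture_scan()` uses *one
  shared mask* for every K — with per-K masks the cross-entropies score
  different entries and their differences are mostly mask noise. Second,
  `select_k()` applies the one-standard-error convention: the smallest K
  whose mean cross-entropy (over replicate restarts; the mean is markedly
  more stable than the best replicate) lies within one replicate-SE of the
  overall minimum, absorbing the sub-noise dips that otherwise appear one
  past the true cluster number (`one_se = FALSE` gives the plain
  minimizer; exact ties always go to the smaller K). Rare alleles carry
  almost no ancestry information, so K selection is run on MAF-filtered
  data — on unfiltered SNP-mode simulations the cross-entropy differences
  between K values collapse into noise.
* **F~ST~** (`pairwise_fst()`): the Weir–Cockerham/Weir–Hill θ moment
  estimator for unequal sample sizes, per-locus a/(a+b+c) components
  summed over loci before the ratio. Negative estimates are kept raw
  internally and floored at zero only for display.
* **AMOVA** (`amova()`): four strata (among islands, among watersheds
  within islands, among individuals, within individuals), with the two
  alleles of a diploid as the lowest level. Variance components are
  solved from the exact expected sums of squares of the unbalanced nested
  random-effects design (computed from the hierarchy's group sizes via
  trace identities), so percentages sum to 100 by construction and no
  balanced-design approximation is involved.
* **Drift tree** (`drift_tree()`): neighbour joining on θ/(1−θ) with
  bootstrap-over-loci node support, rooted at a declared outgroup. This
  deliberately replaces maximum-likelihood drift-graph fitting: the role
  it serves downstream is a drift summary with support values, and no
  migration edges are fitted (the study's own analysis also declined
  migration-edge search).

## Introgression: Patterson's D

For a trio (P1, P2, P3) with all native-range individuals pooled as the
outgroup, alleles are polarized per locus so the outgroup's major allele
is ancestral; outgroup-polymorphic loci contribute through the (1−p~O~)
weight instead of being discarded. With derived-allele frequencies

D = Σ[(1−p1)p2p3(1−pO) − p1(1−p2)p3(1−pO)] /
    Σ[(1−p1)p2p3(1−pO) + p1(1−p2)p3(1−pO)]

the standard error comes from a delete-one block jackknife over contiguous
blocks of (default) 1000 SNPs in chromosome/position order, Z = D/SE, and
the two-sided normal p is Holm-adjusted over all tested trios by default
(Benjamini–Hochberg by option — the family-wise method is the
`p.adjust()` default and the study does not name its choice).
`enumerate_trios()` generates all C(W, 3) unordered watershed trios, or
only those spanning three distinct islands.

## Demography from the folded SFS

**One population.** `stairway_fit()` estimates a multi-epoch N~e~
trajectory by maximizing the Poisson composite likelihood of the folded
SFS. Expected entries combine the exact branch-subtending probabilities
C(n−i−1, k−2)/C(n−1, k−1) with E[time while k lineages], computed for a
piecewise-constant N(t) by mapping a fixed set of standard-coalescent
interval draws through the time rescaling τ(t) = ∫dt/2N(t) (4000 draws by
default, common random numbers, so the expected spectrum is smooth in the
parameters and fully reproducible; the classical alternating-sum formulas
for lineage-count probabilities are numerically unusable at n ≈ 30–60).
Epoch breakpoints sit at quantiles of the expected coalescent event times
under the Watterson starting value; the epoch count is chosen by BIC on a
grid (default 1–5); uncertainty comes from multinomial bootstrap of the
SNP frequency classes. Populations with fewer than 8 haploid genomes are
refused. `ne_point_estimate()` summarizes the trajectory strictly older
than a cutoff (default 30 years).

**Two populations.** `fit_split_model()` fits the isolation(-with-
migration) model: an ancestral population of size N~ref~ splits T units
of 2N~ref~ generations ago into relative sizes ν1 and ν2, with optional
continuous asymmetric migration (m12, m21, backward per-lineage rates per
2N~ref~ generations) that stops at the split. θ is profiled analytically
(θ̂ = total observed / total expected at unit θ) and optimization is
multi-start Nelder–Mead in log-parameter space with generous box bounds.

Two expected-SFS engines stand behind the likelihood. For the
**no-migration** model the joint spectrum is computed in closed form:
within each deme the lineage-count process over the finite interval
[0, T/ν] follows Tavaré's distribution (with analytic expectations of the
time spent with k lineages), block sizes of a coalescent partition are
uniform over compositions, and the ancestral phase is a plain coalescent
whose per-(k1, k2) branch-class spectra are parameter-free and cached per
sample-size pair. This matters more than elegance: the composite
log-likelihood's sensitivity to expected-spectrum error grows with the
SNP count, so a Monte-Carlo objective with a frozen seed visibly warps
the optimum at realistic S (we measured split-time bias of +30–50% and
bootstrap-CI coverage as low as 0.60 before switching; with the exact
engine the estimator is unbiased and coverage is nominal). The exact form
is reliable to about 25 haploid genomes per deme, past which the
alternating Tavaré sums lose precision. Models **with migration** have no
such closed form and use Monte-Carlo coalescent branch-length averaging
at a fixed seed (a deterministic, if rugged, objective); a property test
pins the two engines against each other at m = 0. Expected cells in
Monte-Carlo likelihoods are floored at S/engine_reps — below the engine's
resolution a cell is indistinguishable from that floor, and log(0) cells
would otherwise dominate the fit.

Numerical caveats we handle explicitly:

* **Engine noise is part of the estimator.** `bootstrap_ci()` refits each
  chromosome-resampled spectrum *from scratch* with the same multi-start
  protocol (warm-started refits cling to the original optimum and
  under-disperse β by a factor ≈ 3); with `fresh_engine_noise = TRUE`
  each refit also draws new genealogies so β includes the Monte-Carlo
  component. CIs are α ± 1.96β with α the original estimate and β the
  bootstrap standard deviation.
* **The adjusted LRT** (`adjusted_lrt()`) re-evaluates both models'
  likelihoods at much higher precision (default 5× the fit's genealogy
  count; the validation experiments use 2 × 10⁵, since the noise of a
  composite log-likelihood grows with the SNP count) on an *independent*
  Monte-Carlo stream
  (reusing the fit's stream would retain the noise the optimizer
  exploited; a negative re-evaluated difference means the migration
  parameters explain nothing and maps to statistic 0). The Godambe-style
  adjustment is estimated entirely from score covariances at the null
  fit's parameter point — the sensitivity matrix from iid multinomial
  resampling of SNPs, the variability matrix from the linkage-aware
  chromosome-block bootstrap — because finite-difference Hessians at the
  m = 0 boundary are not positive definite. Size/time derivatives are
  taken on the log scale, migration derivatives on the natural scale with
  forward stencils. The χ² reference with df = 2 at the boundary is
  conservative; `mixture = TRUE` applies the (¼, ½, ¼) boundary mixture.
* **Time conversion**: years = T·2N~ref~/g with N~ref~ = θ̂/(4μL~eff~)
  and L~eff~ from `effective_length()` (raw length × filtered/unfiltered
  SNP ratio).

## Genotype–environment association

`lfmm_associate()` is a latent-factor association scan: the genotype
matrix is residualized on the (standardized, individual-broadcast)
covariate, its top K left singular vectors become latent factors, each
SNP is regressed on covariate + factors, and z-scores are calibrated by
the genomic inflation factor median(z²)/0.456 before p-values. K defaults
to one less than the selected cluster number. Loci monomorphic in the
tested individuals are untestable and propagate as NA. On QC-filtered
archipelago simulations the calibrated null p-values are uniform
(Kolmogorov–Smirnov p ≈ 0.04–0.96 across seeds at 5,000+ loci) and loci
injected at |b| ≥ 2 logit units per covariate SD are recovered
essentially completely at q < 0.05; without MAF filtering the
heavy-tailed drift of near-fixed rare variants breaks the single-factor
genomic-control calibration, which is why the pipeline always filters
first.

`storey_qvalues()` estimates π₀ on a λ grid with spline smoothing
(fixed at 1 with a warning below 100 p-values) and enforces monotone
q-values. `allele_frequency_shift()` compares the single watersheds at
the extremes of each covariate and flags shifts at or above the empirical
0.95 quantile, ties included — with all-distinct shifts that is exactly
⌈0.05·N⌉ loci (613 of 12,254). `enrichment_test()` is the one-sided
hypergeometric upper tail P(X ≥ x); the published contingency
(13 associated, 1 extreme, 12,254 total, 613 extreme) reproduces
p = 0.487 to three decimals. Candidate SNPs map to genes when within the
gene body ± 200 bp (1-based inclusive).

## Orchestration and reproducibility

`run_pipeline()` executes simulate-or-read → QC → structure →
D statistics → association with one `pipeline_config()`, whose defaults
are the study settings (MAF 0.03, missingness 0.75/0.5, K grid 1–12 × 10
replicates, jackknife blocks {100, 200, 1000, 2000} with 1000 the
reporting default, μ = 4.89 × 10⁻⁸, 3.5 generations/year, q < 0.05,
shift quantile 0.95, 200 bp gene windows). A single global seed is
expanded into per-stage seeds by a fixed counter scheme
(`seed·1000003 + stage mod 2³¹−1`), so any stage can be reproduced in
isolation; identical config + seed gives byte-identical outputs. All
randomness, including the C++ coalescent, runs on R's RNG.

The split-model demographic analysis is exposed as functions rather than
a pipeline stage: it concerns a chosen pair of populations (in the study,
the largest Maui and O'ahu samples) rather than the whole dataset.

## Validation experiments and problem sizes

The `bench_*` functions (shared by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) re-run the known-answer experiments at the
following sizes, chosen to give stable verdicts at desk scale:

* SFS engine: n = 20 haploids, 2,000 genealogies × 50 sites (≈ 10⁵
  sites), per-entry agreement within 3 Monte-Carlo SE; joint-engine
  marginals vs 2/i at 40,000 genealogies.
* D statistics: 200 independent bifurcating trios (16 diploids per
  population, 3,000 SNPs, 50-SNP blocks) for the 5% size check — with much
  smaller samples the frequency-ratio Z is visibly over-dispersed
  (≈ N(0, 1.05)) and with much larger ones slightly conservative; 20
  replicates at 6,000 SNPs and 20 diploids for the 15% pulse power check.
* Split model: 20 replicates of T = 0.01 with 5 diploids per population,
  4,000 Poisson-mutation genealogies (≈ 28,000 SNPs) on 25 chromosome
  blocks, 10⁴ genealogies per likelihood evaluation, 12 bootstrap refits
  per CI. Data volume is the cheap axis here (likelihood evaluations cost
  the same regardless of SNP count), and the larger spectra remove most of
  the small-sample skew of the split-time estimator.
* K selection: 10 archipelago simulations of 5 populations × 12 diploids,
  4,000 SNPs before filtering, K grid 1–7 × 3 replicates.
* Association: the full default archipelago shape (213 Hawaiian diploids)
  at 40,000 simulated SNPs, leaving ≈ 5,000 testable loci after QC;
  60 injected loci at slope 2.

## Known limitations

* The coalescent engine treats loci as exchangeable and unlinked between
  genealogies; no recombination map, no linked selection.
* The drift tree is a neighbour-joining summary, not a fitted admixture
  graph; reticulation shows up only through the D statistics.
* The stairway estimator's epoch grid is data-independent within a fit;
  very recent size changes (younger than the most recent expected
  coalescent events) are invisible, as in any SFS method.
* The split-model composite likelihood ignores within-genealogy linkage
  at the point-estimation stage; all testing and interval machinery is
  linkage-corrected, but the point estimates themselves are only
  asymptotically efficient for unlinked data.
* The association scan's genomic-control calibration assumes a common
  inflation scale across loci; extremely drifted, unfiltered data violate
  this (hence QC first).
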