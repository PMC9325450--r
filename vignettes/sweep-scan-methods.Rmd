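---
title: "SweepScan methods: windowed sweep scans, their estimators, and the synthetic benchmark"
author: "SweepScan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SweepScan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the statistical
model behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, the numerical conventions, and the known limitations. It
states nothing the test suite or `scripts/acceptance.R` does not itself
compute.

## The analysis problem

Resequencing panels of domesticated species and their wild relatives —
the motivating case is a lotus panel with wild accessions and cultivar
subgroups bred for flower, seed or rhizome traits — are scanned for
*selective sweeps*: regions where directional selection during
domestication purged diversity in a cultivated subgroup and increased
its differentiation from the wild subgroup. The scan combines two
windowed statistics, the fixation index F~ST~ and the diversity ratio
π~wild~/π~cultivated~, and calls windows that fall in the top 5%
empirical percentiles of **both**. This joint rule is deliberately
conservative: either statistic alone is noisy, and their intersection
under an independent null selects only ≈ q² of windows (verified by
simulation in the test suite).

## Estimators

**Per-site π.** With `r` called reference and `a` called alternate
allele copies at a biallelic site (n = r + a ≥ 2),
π = 2ra / (n(n−1)) — the unbiased mean pairwise difference among the
called allele copies. Sites with n < 2 are *not estimable*: they are
skipped, not counted as zero diversity.

**Window π.** Σ site π over SNPs in the window, divided by the **full
window length in bp**. Monomorphic and non-SNP positions thus
contribute zero to the numerator and full length to the denominator,
which puts values on the familiar genome-wide per-bp scale (order
10⁻³ in diverse plant panels). An accessible-sites denominator would
be preferable when callable fraction varies strongly along the genome;
that refinement is out of scope, and the per-bp convention is recorded
in every output header.

**Hudson F~ST~.** Per site,
N = (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1) and
D = p₁(1−p₂) + p₂(1−p₁); the window estimate is ΣN/ΣD (ratio of
averages). This estimator was chosen because it is robust to
low-frequency variants and nearly unbiased with unequal sample sizes,
and because under the Balding–Nichols generator its expectation equals
the drift parameter F, giving the package a closed-form recovery
target (the acceptance script recovers F ∈ {0.05, 0.1, 0.2, 0.4}
within ±0.02 from 20 000 sites). Negative per-window values are
*retained*: clamping at zero would distort the empirical percentiles
that the sweep rule depends on. Windows where either group has fewer
than two called allele copies at every site, or where ΣD = 0, are
undefined (`NA`) and excluded from ranking — never silently zeroed.

**Heterozygosity.** Per sample, the fraction of called genotypes that
are heterozygous; subgroup values are means over member samples.

## Site QC

A site passes iff depth ≥ 4 AND RMS mapping quality ≥ 20 AND
MAF ≥ 0.05 AND missingness ≤ 0.1, all comparisons inclusive, so sites
exactly at a printed boundary are retained. Depth and mapping quality
are site-level covariates (the thresholds describe a site filter, not
a genotype filter); MAF is computed over all called alleles of the
combined panel, and missingness is the fraction of uncalled genotypes
at the site. The summary counts failures per criterion independently
because a site may fail several. Filtering is idempotent.

## The sweep caller

**log₂ π-ratio.** log₂(π~wild~/π~cult~) per window. When the
cultivated window has lost all observed diversity (π~cult~ = 0,
π~wild~ > 0) the value is a +∞ sentinel; when both are zero the window
is uninformative and excluded. A pseudocount alternative was
considered and rejected as the default: total diversity loss is
exactly the "strong sweep" signal, and a pseudocount would let the
choice of ε reorder the extreme tail.

**Empirical percentiles.** Mid-rank percentiles,
100·(#less + ½·#equal)/n over the rankable (non-`NA`) windows — stable
and invariant to input order. +∞ sentinels are then assigned
percentile 100 outright. This second step matters: with many
total-loss windows, plain mid-rank would give the whole +∞ tie group a
*shared* mid percentile that can drop below the selection threshold,
an absurd outcome for the strongest possible signal.

**Joint selection.** A window is called iff both percentiles are
≥ 100(1−q), q = 0.05 by default, threshold inclusive; under heavy ties
the selected set may slightly exceed q·n. Fewer than 20 rankable
windows triggers a degeneracy warning, as does an all-ties statistic
(every percentile 50, nothing selectable).

**Merging and genes.** Selected windows that overlap or are book-ended
(gap ≤ `gapBp`, default 0) merge into maximal regions; with sliding
windows this is what collapses runs of overlapping selected windows
into countable sweep regions. Region statistics are maxima over member
windows. A gene is assigned to a region iff its 1-based closed span
overlaps it by ≥ 1 bp — adjacency is not overlap — and gene totals are
deduplicated across regions. Two scans (e.g. wild-vs-seed and
wild-vs-rhizome) can be intersected to count shared sweeps and genes.

## Window geometry

No single window geometry suits all SNP densities, so the geometry is
a parameter, echoed into the run manifest. The package default is
100 kb windows sliding by 10 kb (size/10), a common choice for
~10⁶-SNP resequencing panels. The synthetic benchmark uses 2 kb
windows sliding by 200 bp because its 2 Mb chromosome carries one SNP
per 100 bp, giving ~20 SNPs per window; window size should scale with
SNP spacing, not genome size.

## The synthetic-data generator

The generator emulates exactly the structure the analysis assumes:

* **Allele frequencies.** An ancestral frequency p per site (uniform
  on \[0.05, 0.95\], or a neutral-like 1/x spectrum truncated to
  \[0.01, 0.99\]); each population draws its frequency from
  Balding–Nichols Beta(p(1−F)/F, (1−p)(1−F)/F), mean p, variance
  Fp(1−p); F = 0 copies p exactly. Balding–Nichols was preferred over
  a coalescent simulator because it yields closed-form recovery
  targets (E[F~ST~] = F) — the point of the generator is
  verifiability, not demographic realism.
* **Genotypes.** Binomial(2, p~pop~) dosages — Hardy–Weinberg within
  populations — masked missing independently per genotype with a
  configurable rate (default 2%), the simplest model consistent with a
  site-level missingness filter.
* **QC covariates.** Site depth ~ NegBin(mean 10, size 5) and RMS
  MQ ~ Normal(45, 8) truncated at 0, site-level like the filter. The
  defaults represent a medium-coverage panel (~10×) and make a small,
  realistic fraction of sites fail each threshold, so the QC stage is
  genuinely exercised.
* **Sweeps.** Inside each configured interval the target population's
  frequency moves toward fixation, p′ = p(1−s) + round(p)s, with
  round(0.5) ≡ 1 as a deterministic tie-break; s = 1 is fixation,
  s = 0 a no-op.
* **Fixtures.** VCF v4.2 (GT; INFO DP and MQ), a toy GFF3 of
  non-overlapping genes with exons, a population map and a sweep truth
  table; reading the VCF back reproduces the dosage matrix exactly.

What it does **not** emulate: linkage disequilibrium and recombination
maps (each site is drawn independently), hitchhiking flanks around
sweeps (sweep edges are sharp), per-genotype depth variation, allele
dropout or reference bias, and demographic history beyond a
star-shaped divergence. Passing the recovery benchmarks therefore
shows the *estimators and the calling logic* are correct under the
model the method assumes; it does not show robustness to LD, batch
effects or complex demography in real panels.

## The standard benchmark and selection capacity

The end-to-end benchmark (`standardFixtureConfig()`) is one 2 Mb
chromosome with 20 000 SNPs, a wild and a cultivated population
(n = 20 diploids each, F = 0.05), and ten planted sweeps of intensity
s = 0.95, scanned at 2 kb / 200 bp.

One design constraint deserves emphasis because it is a genuine
limitation of joint-percentile scans: the rule can mark at most a
fraction q of windows, so if planted (or real) sweeps plus the windows
overlapping them cover more than ~q of the genome, the percentile
threshold falls *inside* the sweep-value distribution and the weakest
sweeps are squeezed out regardless of their absolute signal strength.
The benchmark therefore keeps its sweep halo at ~4.5% of windows
(7.5 kb sweeps, each still fully containing 28 scan windows). Under
these conditions the suite verifies 100% of planted sweeps are
overlapped by called regions across ten seeds, with ~4% of windows
selected. Users scanning genomes where selection is pervasive should
treat the top-q rule as a ranking device, not a complete inventory.

## Structure analyses

**p-distance.** Allele-sharing distance, mean |d~i~ − d~j~|/2 over
sites called in both samples (pairwise deletion): opposite homozygotes
1, homozygote–heterozygote ½. Pairwise deletion matches
high-missingness practice; the per-pair co-called count is recorded,
and a pair with no co-called sites is an error, not a zero. The
diploid "p-distance" is not uniquely defined in the field; a
genotype-mismatch mode is available. Under heavy missingness the
matrix can violate the triangle inequality — violations are reported,
never repaired.

**Neighbor joining.** Classic Saitou–Nei agglomeration with the
standard Q-matrix and branch-length formulas, implemented in-package
so its conventions are pinned: ties in Q break to the lowest (i, j)
pair in the current cluster order (deterministic, order-stable), and
negative branch lengths are clamped to zero only after construction,
as a display convention. On additive matrices NJ is exact (Atteson);
the suite verifies exact topology and 10⁻⁹ branch-length recovery on
random trees of 4–8 taxa and agreement with an independent NJ
implementation off additivity.

**PCA.** Missing dosages are mean-imputed per site (deterministic, no
genotype-likelihood machinery), sites centered at 2p̂ and scaled by
√(2p̂(1−p̂)) (Patterson normalization), monomorphic sites dropped, and
the SVD taken; components are ordered by eigenvalue with signs fixed
by the first nonzero loading, so results are reproducible to the sign.

## Determinism and problem sizes

Every random draw flows from one integer seed; the simulator's stages
use fixed offsets of it so each stage is independently reproducible.
Two pipeline runs with the same config and seed produce byte-identical
outputs, which the suite checks by checksum. The test suite's
simulation sizes — 20 000 sites for parameter recovery, the 2 Mb
benchmark over ten seeds for sweep recovery, 100 random trees for NJ —
were chosen as the smallest sizes at which the Monte-Carlo tolerances
(±0.02 on F~ST~, 5% on heterozygosity) are comfortably resolvable.

## Known limitations

* No LD-aware statistics (no haplotype scans, no Tajima's D); the scan
  is the two-statistic joint rule only.
* Biallelic SNPs only; multiallelic records and indels are skipped at
  input with a logged count.
* The π denominator assumes uniform callability across windows.
* Region counts depend on window geometry and the merge gap; they are
  comparable only within one configuration (the manifest records it).
* The +∞ ratio sentinel makes total-loss windows unrankable *among
  themselves*; their internal order is not meaningful.
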