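---
title: "Methods: three-statistic selective-sweep scanning and the CpG selection test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-statistic selective-sweep scanning and the CpG selection test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`sweepscanr` scans phased biallelic SNP data from two populations — a focal
population suspected of recent positive selection and a reference — for the
three classic footprints of a hard selective sweep:

1. **Elevated differentiation**: per-SNP Weir–Cockerham $F_{ST}$, Gaussian
   kernel smoothed along each scaffold, tested against a bootstrap null of
   genome-wide values resampled into each observed window.
2. **Population-specific diversity loss**: per-window
   $x_i = \log_2(\pi_{\mathrm{focal}} / \pi_{\mathrm{ref}})$ standardized
   genome-wide into $Z = (x_i - \bar{x}) / \mathrm{s.d.}(x)$, flagging the
   lower tail.
3. **Extended haplotypes**: cross-population extended haplotype homozygosity
   (XP-EHH), the log ratio of integrated EHH between the populations at each
   core SNP, normalized genome-wide, flagging the positive extreme of the
   top-$1\%$ tail of $|$score$|$.

Candidate sweep regions are intervals supported by **all three** tests. A
companion module tests whether differentially methylated CpG positions are
physically intact (the dinucleotide is still `CG`) at different rates in the
two populations, using an exact $2\times2$ test — the genetic signature
expected when selection maintains a methylated haplotype in one population
while deamination (C$\to$T) erodes unmethylated copies in the other.

The package targets reduced-representation (RAD-style) datasets: sparse,
irregularly spaced SNPs on a fragmented assembly, which motivates kernel
smoothing with a modest bandwidth, per-window bootstrap calibration, and
scaffold filters for the LD-based statistic.

# Estimators

## Per-site FST

We implement the two-population Weir–Cockerham (1984) $\theta$: variance
components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals), with
$\theta = a/(a+b+c)$, computed from per-population sample sizes, allele
frequencies and observed heterozygosity. This is the standard
AMOVA-consistent estimator of the fixation index for two populations and is
fully specified, which matters because the test suite checks it at
$10^{-10}$ against an independently coded nested-ANOVA route.

Two choices are worth making explicit:

* **Negative estimates are kept** by default. $\theta$ is unbiased around
  zero under panmixia, so truncation inflates every window mean and thereby
  the bootstrap null; `clamp_negative = TRUE` exists for comparison with
  pipelines that truncate.
* **Sites monomorphic across both populations are undefined**, not zero;
  they carry no information about partitioning variance and are excluded
  from tracks and from the bootstrap pool.

## Variant-site nucleotide diversity

$\pi$ at a variant site is the sample-size-corrected expected
heterozygosity, $\pi = \frac{n}{n-1}(1 - \sum_a p_a^2)$ with $n$ the
non-missing allele copies, equal (exactly) to the mean pairwise difference
over all $\binom{n}{2}$ haplotype pairs — the identity is part of the test
suite. There is no per-bp normalization: diversity is per *variant site*,
so ratios between populations at the same sites are well defined even when
locus lengths are unknown. Sites with $n < 2$ are undefined, never zero.

## EHH, iHH and XP-EHH

EHH at extension $k$ from a core SNP is the probability that two random
haplotypes are identical over the closed span from the core to $k$;
`ehh_profile()` computes it by incremental partition refinement, and
integration (`ihh()`) is trapezoidal over physical distance, stopping at
the first value below the decay cutoff (default $0.05$). XP-EHH at a core
is $\ln(\mathrm{iHH}_{\mathrm{focal}}) - \ln(\mathrm{iHH}_{\mathrm{ref}})$
using *pooled* EHH (all haplotypes, not allele-partitioned) per population,
the canonical cross-population form; writing it as a difference of logs
makes the population-swap antisymmetry exact in floating point.

Normalization subtracts the genome-wide mean of raw scores and divides by
their standard deviation ("to account for genome-wide differences in
haplotype length" between the populations); it is unbinned by allele
frequency, since the pooled statistic has no core-allele stratification.
Outliers are cores whose $|$normalized score$|$ reaches the empirical
$99\%$ quantile *and* whose score is positive (long haplotypes in the focal
population). The threshold is data-derived and reported with the track —
the quantile, not any fixed constant, is the rule.

Reduced-representation data bring two caveats, both handled explicitly:

* scaffolds must exceed 300 kb and 20 SNPs to enter the scan at all
  (`min_len`, `min_snps`), since EHH cannot decay to the cutoff on short
  fragments;
* cores whose integration hits a scaffold end while EHH is still above the
  cutoff are kept but flagged *boundary-censored* (a strict mode drops
  them). No gap-scaling penalty is applied between distant SNPs — with
  RAD-like spacing, gaps are the norm rather than evidence of missing
  recombination information; this is a deliberate divergence from
  dense-sequencing conventions.

# Kernel smoothing and the bootstrap null

Smoothing is a Gaussian-weighted mean centered on each SNP,
$s_c = \sum_j w_j x_j / \sum_j w_j$ with
$w_j = \exp(-d_{jc}^2 / 2\sigma^2)$, restricted to the same scaffold and to
$|d| \le 3\sigma$ (weights below $e^{-4.5}$ are discarded — standard kernel
practice). The default $\sigma = 25$ kb suits fragmented assemblies with
scaffold N50s in the hundreds of kb.

The outlier test for smoothed $F_{ST}$ resamples, for each window,
$|$window$|$ values with replacement from the genome-wide pool of defined
per-site values and combines them with the window's own kernel weights —
preserving the observed window geometry under the constraints of RAD
sampling. The p-value is $(1+k)/(1+B)$ with $k$ the count of resampled
smoothed values at or above the observed one; it can never be zero, so a
claim of $p < 10^{-5}$ is only possible once $B \ge 10^6$. Replicates
escalate through $B = 10^2, 10^3, \dots$ up to `B_max` (default $10^7$),
and a window escalates only while $\hat{p} \le 100/B$, concentrating
compute in the tail.

Numerical details:

* Ties between a resampled and the observed value count toward $k$
  (conservative), with a relative comparison tolerance of $10^{-9}$ so that
  mathematically tied weighted means are not split by floating-point
  association order.
* Replicate draws are generated independently per window while the level's
  total draw count is small; above a fixed budget, one replicate draw
  matrix per chunk is shared across all windows at that level and combined
  with each window's weights by a BLAS matrix product. Each window's
  p-value remains an exact marginal $B$-replicate bootstrap estimate;
  only independence *between* windows is relaxed, which no reported
  quantity relies on. This is what makes $10^6$–$10^7$-replicate levels
  tractable on a single core.
* All randomness flows through R's RNG, so a single `set.seed()` governs
  both execution paths and results are bit-reproducible.

## The diversity-ratio Z-score

Both $\pi$ tracks are smoothed on identical centers (sites defined in both
populations). Windows where either smoothed $\pi$ is zero use a floor of
half the smallest positive smoothed value genome-wide — keeping the log
finite while preserving rank order; a swept region has reduced, not zero,
smoothed diversity, so the floor rarely engages. Outliers are windows with
$Z \le -z_{\mathrm{cut}}$ (default 5), i.e. diversity loss in the focal
population; the track reports the signed $Z$ and a direction flag.

# Region integration

Flagged SNPs from each test are merged into regions while consecutive
flags are within `merge_gap` (default 50 kb $= 2\sigma$, tying the merge
rule to the smoothing scale). Region bounds snap to the first and last
member SNPs, matching the convention of reporting SNP-bounded 1-based
inclusive intervals. Combined candidate regions are the maximal intervals
covered simultaneously by at least one region from each of the three tests
(interval-level overlap; per-SNP triple support is visible in the tracks).
Region summaries report the maxima of point and smoothed $F_{ST}$, the
minimum $Z$, the maximum normalized XP-EHH, the percent reduction of focal
smoothed $\pi$ inside versus outside the region on the same scaffold
(genome-wide fallback, with a warning, if the region spans the whole
scaffold), and per-population dominant haplotype frequencies over the
region SNPs.

# The CpG selection test

For designated CpG positions in amplicon/locus alignments, each haplotype
is *intact* iff the dinucleotide at $(\mathrm{pos}, \mathrm{pos}+1)$ is
exactly `CG`; the typical disruption is the C$\to$T transition product
`TG`, expected where methylated cytosines deaminate. Counting is at the
haplotype level (heterozygotes contribute one unit to each category),
matching how intactness fractions are naturally reported. The per-site
$2\times2$ table (population $\times$ intact/disrupted) is tested by full
enumeration of the hypergeometric distribution under fixed margins; the
two-sided p sums all tables at most as probable as the observed one
(relative tie tolerance $10^{-12}$; a one-sided option exists). Any zero
margin admits a single feasible table, so $p = 1$ by construction.

The methylation screen takes any per-position table of mean methylation
fractions for the two populations, reports the squared Pearson correlation
between them, and flags positions where the focal mean is $\ge$ `fold`
(default 4) times the reference mean — candidate mutable-CpG positions
under population-specific selection.

# The synthetic data generator

`simulate_dataset()` emulates the statistical structure the scan consumes,
not the sequencing process:

* **Divergence**: ancestral frequencies $p \sim \mathrm{Beta}(0.8, 0.8)$
  truncated to $[0.05, 0.95]$ (a U-shaped SFS as seen through a SNP-calling
  filter), population frequencies Balding–Nichols
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with $F = 0.1$ by default —
  the upper end of the weak-differentiation regime the scan is meant for.
* **LD**: each sample haplotype is a mosaic of $K = 12$ founder haplotypes
  per population, switching founders between adjacent SNPs with probability
  $1 - e^{-\rho d}$ ($\rho = 10^{-5}$/bp), then flipping alleles at
  $\mu = 5\times10^{-4}$; this yields pairwise $r^2$ decaying over tens of
  kb, the length scale the EHH statistics need.
* **The sweep**: inside the sweep interval each focal haplotype is,
  independently with probability $f$ (default $0.85$), an exact copy of
  founder 1 (with residual flips at $10^{-4}$), else it keeps its mosaic.
  This directly produces the observable signature of a hard sweep — a
  dominant haplotype near frequency $f$, collapsed diversity, elevated
  $F_{ST}$ and long shared haplotypes — with one interpretable knob.
* **Scale**: defaults are 20 diploids per population and two scaffolds,
  2 Mb (4000 SNPs) and 200 kb (400 SNPs); the short scaffold exists to
  exercise the XP-EHH scaffold filters. The 2000 SNPs/Mb density keeps
  every stage, including the million-replicate bootstrap levels, fast
  enough for routine testing while preserving ~300-SNP smoothing windows.

What the generator does **not** model: coalescent genealogies, demographic
history (growth, migration, bottlenecks beyond the founder pool),
recombination hotspots, sequencing error, depth variation, or RAD locus
dropout. Passing tests on this generator therefore demonstrate that the
estimators, calibration machinery and region logic behave as specified on
data with the right first- and second-order structure — not that the scan's
power or false-discovery behavior on a particular empirical dataset is
reproduced.

The CpG fixture generator emits `CG`/`TG` dinucleotides per haplotype with
per-population (optionally per-site) intactness probabilities, and a
methylation table equal to expected intact fraction times a shared
site-level propensity plus seeded noise; at zero noise the two populations'
mean-methylation vectors are exactly proportional ($r^2 = 1$).

# Design decisions in brief

* Coordinates are 1-based inclusive internally (VCF convention); BED output
  converts at the boundary. Multi-allelic records are skipped, not split.
* Missing genotypes are allowed in dosage-based statistics (per-site
  non-missing counts are carried along) but rejected where haplotype
  identity is counted (EHH, spectra, bifurcation) — pair-identity is
  undefined under missingness.
* The exact flavor of "AMOVA $F_{ST}$" differs across pipelines; we use
  Weir–Cockerham $\theta$ and treat smoothed-scale behavior, not per-site
  decimals of any particular implementation, as the comparison surface.
* Kernel weights only — no additional weighting of window members by
  per-site allele counts; the per-site sample sizes are reported so users
  can filter first.
* The $\pi$-ratio Z-score is applied to smoothed $\pi$ only; it does not
  reuse the FST bootstrap machinery (the two nulls answer different
  questions, and the 5-SD rule is already a fixed-threshold test).

# Problem sizes used by the test suite

The suite validates estimators on exhaustively checkable sizes (up to 16
haplotypes for EHH, margins up to 30 for the exact test, 200 random sites
for $F_{ST}$), calibrates the bootstrap on 2000 mutually independent
windows at $B = 2000$, and runs the full scan end-to-end on 20 sweep and 20
neutral datasets at the default scale with `B_max` $= 10^6$ — the smallest
maximum at which a $p < 10^{-5}$ call is possible. These sizes are the
package's own choices for a thorough but routine-runnable suite.

# Known limitations

* **Fixed-SD thresholds lose power when the sweep is a large fraction of
  the data.** The $Z$ score standardizes by the genome-wide
  $\mathrm{s.d.}(x)$, which the sweep itself inflates. If a fraction $w$ of
  windows sit in the swept trough, the most extreme standardized value is
  bounded near $\sqrt{(1-w)/w}$ regardless of effect size — about $3.2$
  at $w = 10\%$. On genome-scale data ($w \sim 10^{-4}$) the 5-SD rule has
  ample headroom, but on desk-scale simulations (a 200 kb sweep in a
  2.2 Mb genome) it cannot fire, and three-test combined regions are then
  empty even though the $F_{ST}$ and XP-EHH tests localize the sweep
  cleanly. Quantile-based rules (as XP-EHH uses) do not share this cap.
  Users simulating small genomes should interpret the $Z$ test
  accordingly or enlarge the neutral background.
* **The founder pool is itself drift.** Sampling $K$ founders per
  population adds $\sim 1/2K$ to realized differentiation, so mean
  per-site $F_{ST}$ does not approach zero as $F \to 0$ (with $K = 12$ the
  floor is near $0.07$). Monotonicity in $F$ holds; absolute calibration
  of $F$ to realized $F_{ST}$ does not.
* Windows at scaffold ends are boundary-censored for XP-EHH; power there
  is reduced, as expected for LD statistics on fragmented assemblies.
* The bootstrap null conditions on the observed window geometry and an
  iid genome-wide pool; genuine long-range autocorrelation of background
  $F_{ST}$ (e.g. from pervasive background selection) would make it
  anticonservative.
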