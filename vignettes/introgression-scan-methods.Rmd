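---
title: "Methods: frequency- and haplotype-based introgression scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency- and haplotype-based introgression scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

`introscan` detects gene flow between populations from diploid biallelic
genotypes. This vignette is the package's account of the statistics it
computes, the assumptions behind them, the defaults it ships with and why,
and what the bundled simulator does and does not emulate.

## The genotype model

A panel holds biallelic SNPs with 1-based positions, strictly increasing
within each chromosome, and per-sample allele pairs coded 0 (reference),
1 (alternate) or missing. Half-calls such as `0/.` carry ambiguous
information about the second allele and are collapsed to fully missing —
the simplest defensible reading, applied once at construction so every
downstream denominator is consistent. Missing genotypes are excluded from
every allele-frequency denominator.

Variant filtering follows cohort-level practice for a merged call set:
minor allele frequency is computed pooling all samples (one filter for the
whole cohort, not per population), and the keep rules are inclusive —
MAF ≥ 0.01, call rate ≥ 0.9, autosomes 1–18 by default. Each removed site
is attributed to exactly one rule (chromosome, then call rate, then MAF) so
the per-rule counts plus the retained count always partition the input;
this makes filter reports additive across runs.

## Differentiation: two FST estimators, on purpose

The package exports two FST estimators and documents them as
non-interchangeable, mirroring the two tools a typical study uses:

* `fst_hudson_pair()` — the Hudson ratio-of-sums estimator, used for
  population-level matrices. Per site, numerator
  $(p_A-p_B)^2 - \frac{p_A(1-p_A)}{n_A-1} - \frac{p_B(1-p_B)}{n_B-1}$ and
  denominator $p_A(1-p_B)+p_B(1-p_A)$, summed before the ratio is taken.
  Ratio-of-sums weighting is robust to low-information sites; small
  negative estimates are reported raw rather than clamped, because
  clamping biases averages of near-zero differentiation.
* `fst_wc_window()` — the weighted Weir–Cockerham theta for windows,
  computed from genotypes so observed heterozygosity enters the variance
  components; per window the components are summed and then ratioed.

Gene-flow levels use the island-model relation $Nm = (1-F_{ST})/(4F_{ST})$.
It is a coarse equilibrium summary, not an estimate of a migration rate in
any specific demography; we report it because it is the conventional
companion to an FST matrix. FST ≤ 0 maps to `Inf` with a warning.

## Diversity and divergence in windows

Windows are fixed, non-overlapping tiles anchored at position 1 (window *k*
spans $[(k-1)s+1, ks]$); the final partial tile is kept and flagged.
Internally all coordinates are 1-based inclusive, matching VCF; BED export
converts to 0-based half-open at the boundary of the package, never
internally.

* π (within-population): $\sum_s 2p(1-p)\frac{n}{n-1}$ divided by window
  length in bp. The per-site $n/(n-1)$ factor makes the estimator exactly
  the all-pairs average Hamming distance under missingness, which the test
  suite verifies by enumeration.
* dxy (between populations): $\sum_s [p_A(1-p_B)+p_B(1-p_A)]$ over window
  bp. Both statistics default to the sequence-length denominator
  (monomorphic-site aware); per-site normalization is available behind a
  flag.
* Tajima's D: $(\hat\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the 1989
  constants. $\hat\pi$ uses per-site called-allele counts; the constants
  use the minimum called-allele count across the window's segregating
  sites. This keeps the statistic defined under scattered missingness and
  reduces exactly to the textbook estimator on complete data. Windows with
  no segregating site or fewer than four alleles are missing, not errors.

## The four-taxon tests

Sites are polarized by the outgroup (H4): the outgroup's major allele is
taken as ancestral, sites where the outgroup is polymorphic at minor-allele
frequency above 0.1 are dropped, and frequencies are flipped where needed
so $p_4 \le 0.1$. This operationalizes "derived allele" without requiring a
fixed outgroup.

Per site, $ABBA = (1-p_1)p_2p_3(1-p_4)$ and $BABA = p_1(1-p_2)p_3(1-p_4)$;
genome-wide $D$ is the ratio of summed differences to summed totals.
Positive D means H3 shares more derived alleles with H2. (`d_matrix()`
defaults to the opposite orientation — positive towards H1 — because
differential-affinity heatmaps are conventionally drawn that way; the
argument `positive` makes the choice explicit.)

The standard error comes from a delete-one block jackknife over contiguous
5-Mbp coordinate blocks. Blocks are weighted by their informative-site
count (sites with non-zero ABBA + BABA), using the Busing weighted-jackknife
form, because coordinate blocks have unequal SNP density; with equal
weights the formula reduces to the unweighted delete-one estimator, a
reduction the tests check explicitly. |Z| > 3 is the conventional
significance rule. Two caveats the implementation surfaces rather than
hides: with identical blocks the SE is zero and Z is flagged infinite; and
a jackknife over very few blocks (a short toy chromosome) is degenerate —
the power and calibration experiments below therefore use chromosomes long
enough for 20–200 blocks, which is also the realistic regime (a mammalian
genome contains hundreds of 5-Mbp blocks).

## The fd window scan

Per 100-kb window, the numerator is $\sum(ABBA - BABA)$ and the denominator
is the same sum with both H2 and H3 replaced at each site by the *donor
proxy* — whichever of the two has the larger derived-allele frequency
there. The ratio estimates the local admixture fraction: the denominator
represents the value the numerator would take under complete sharing.
fd is reported missing where the window D is negative (the statistic is
meaningless for BABA excess), where the denominator is zero, or where
fewer than `min_sites = 10` informative sites fall in the window (the
window SNP-count cutoff is the package's choice; values slightly above 1
can occur in noise and are flagged, never clamped).

Outlier windows are those at or above the empirical 99.9% quantile of
non-missing fd (`quantile = 0.001`, i.e. the top 0.1%). A stricter top
0.01% is available by setting `quantile = 1e-4`; the default is the
conventional scan setting and the knob is deliberately exposed rather than
silently reconciled. Same-chromosome outliers with gaps ≤ 1 Mbp are chained
into single signals, each reporting its span and peak window. Signal
validation then asks whether the member windows show the joint pattern of a
real introgressed tract: fd above the outlier threshold *and*
recipient–donor dxy and FST below the genome-wide medians (median rather
than mean, for robustness to the scan's own outliers), recording the
recipient's Tajima's D sign alongside.

## Haplotype evidence

Haplotype statistics require phased input and refuse otherwise —
pseudo-phasing silently corrupts EHH. Sites with any missing call in the
query region are dropped and counted.

* Major-allele sharing: the major allele is pooled across all populations
  (one colour scheme across panels; a per-population variant is behind a
  flag), with a 50/50 tie deterministically resolved towards the alternate
  allele.
* EHH from a core site and allele:
  $EHH(x) = \sum_g \binom{k_g}{2}/\binom{n}{2}$ over distinct
  core-to-*x* haplotype prefixes; 1 at the core, non-increasing outward,
  truncated below 0.05 (the conventional plotting cutoff; the bound is a
  package default, not an estimate).
* Bifurcation trees partition carriers site-by-site outward; leaf counts
  always sum to the carrier count, and EHH recomputed from the tree equals
  the direct prefix-grouping EHH — a two-route identity in the test suite.
* LD: $r^2 = (p_{AB}-p_Ap_B)^2/(p_A(1-p_A)p_B(1-p_B))$ from haplotype
  counts, invariant to allele relabelling.

## The simulator and what passing tests mean

`simulate_panel()` draws, per site, an ancestral derived-allele frequency
from Beta(0.8, 0.8), pushes it through Balding–Nichols drift
(Beta with mean *p* and variance scaled by a branch coefficient *F*) along
the fixed topology (((P1, P2), P3), O), and samples haplotypes binomially.
Introgression is planted by resampling the tract alleles of a fraction *f*
of recipient haplotypes from the donor's frequencies — contiguous,
whole-haplotype replacement, so haplotype-level statistics see realistic
tract structure.

The default drift coefficients (`p12 = 0.1`, `p1 = p2 = 0.03`,
`p3 = 0.35`, `o = 0.5`) were calibrated once so the panel reproduces the
differentiation structure of closely related domestic populations probed
with a congeneric outgroup: sister-pair Hudson FST ≈ 0.03, recipient–donor
≈ 0.23, outgroup ≈ 0.3. This calibration matters for fd: the donor-proxy
denominator takes a maximum of two noisy frequencies, which inflates it —
and biases fd downward — when donor and recipient are weakly separated.
At the default separation, mean fd across tract windows recovers the
planted fraction to within sampling error, which is the generator's design
contract.

The standard experiment sizes, chosen for desk-scale runtimes and stated
here as the package's reference conditions:

* fd recovery: 50,000 SNPs on a 10-Mb chromosome, 20 diploids per
  population, f = 0.5 on a 0.8-Mb tract; 20 seeded replicates.
* Null calibration and D power: the same site count on a 100-Mb or 1-Gb
  chromosome, giving 20–200 jackknife blocks (see the jackknife caveat
  above).

Known limitations, hence what green tests do *not* show about real data:

* Sites are independent outside the planted tract — there is no background
  LD, no recombination map, and LD-based checks therefore exercise only
  the tract.
* Balding–Nichols drift is not a coalescent: the site-frequency spectrum
  carries an intermediate-frequency excess relative to neutral
  equilibrium, so simulated windows have systematically positive Tajima's
  D. Tajima's D correctness is established against brute-force enumeration
  on exact instances, not against the generator.
* The demography is a fixed four-taxon tree with one admixture episode;
  continuous migration, bottlenecks and selection are out of scope.

## Numerical conventions and degenerate inputs

* Ratio-of-sums everywhere ratios of estimators appear (FST, D, fd);
  never means of per-site ratios.
* Empirical quantiles use the default interpolating type; with 10,000
  windows the 99.9% threshold yields exactly 10 outliers. When fewer than
  `1/quantile` windows exist the scan warns and takes the top
  `max(1, round(n * quantile))` windows.
* All randomness flows through a single integer seed per simulation;
  rerunning any pipeline with the same seed and configuration reproduces
  the output bundle byte for byte (no timestamps in outputs).
* Errors are reserved for unusable inputs (no informative sites, absent
  samples, unphased haplotype requests); statistics that are undefined in
  a window (no data, S = 0, negative window D) are missing values, so
  downstream summaries degrade gracefully.
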