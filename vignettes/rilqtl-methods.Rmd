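---
title: "Bin maps and QTL from low-coverage RIL genotyping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin maps and QTL from low-coverage RIL genotyping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilqtl)
library(dplyr)
```

rilqtl reconstructs, as one tested pipeline, the computational chain used to
map plant-architecture QTL in a maize recombinant inbred line (RIL)
population genotyped by sequencing (GBS): sparse biparental SNP calls are
filtered for segregation distortion, converted to genotype blocks with a
sliding window, condensed into population-level recombination bins on a
100-Kb grid, placed on a genetic map with the Kosambi function after
correcting for RIL map expansion, and scanned for QTL by regression with
permutation thresholds. Because no raw data from the original study are
deposited, the package also contains a first-class forward simulator whose
defaults emulate that study's population: 314 F11 lines from the cross
Ye478 x Qi319, a 10-chromosome genome of 2059.7 Mb spanning 1545.65 cM, and
three environments with two replicates for plant height (PH), ear height
(EH) and internode number (IN).

## The simulator: what world it states

`breed_ril_population()` breeds each line by single-seed descent from the
biparental F1. Meiosis is interference-free: the number of crossovers per
chromosome is Poisson with mean equal to the map length in Morgans, and
crossover positions are uniform on the genetic scale, mapped to base pairs
linearly. The linear cM-bp relation is the simplest model that satisfies
every tested expectation; suppressed-recombination centromeres can be
emulated by supplying custom per-chromosome map lengths on a finer
chromosome partition, but are not modelled by default. Two consequences are
used as oracles in the test suite:

* the residual heterozygous genome fraction after $g$ selfing generations
  has expectation $2^{-g}$ (about 0.098 % for the F11 default), and
* the junction (breakpoint) density of the line mosaic approaches $2L$
  junctions for a map of $L$ Morgans as $g \to \infty$ (about 31 junctions
  per line for the 15.46-Morgan default genome).

`observe_gbs()` models low-coverage GBS at the SNP level only (no reads,
barcodes or restriction sites): each segregating SNP of each line is seen
independently with probability `observe_rate`; an observed call is the
founder allele, flipped with probability `allele_error_rate`; heterozygous
segments emit either allele with probability 1/2, because a single
low-coverage read cannot reveal heterozygosity. The study sequenced at
~0.07x coverage and saw about 5 % of its segregating SNPs per line, so the
meaningful quantity is the density of informative calls per line (about 2
per Mb there); defaults are chosen to match that density at whatever SNP
count is simulated.

`simulate_phenotypes()` draws
$y_{ijk} = \mu + e_j + \sum_q a_q x_{qi} + (ge)_{ij} + \varepsilon_{ijk}$
with $x_q \in \{-1, 0, +1\}$ for the A-homozygous, heterozygous and
B-homozygous genotype at each planted QTL; positive $a_q$ means the B
(Qi319) allele raises the trait. `default_qtl_truth()` plants seven QTL,
including a pleiotropic region on chromosome 10 affecting all three traits
(echoing the study's most prominent finding), with grand means and
environment offsets read off the published trait table and noise SDs chosen
once so the line-mean broad-sense heritabilities land in the reported
0.8-0.95 range. A green recovery test therefore establishes that the
pipeline finds what was planted under this stated world — not that it would
reproduce the study's QTL from its unreleased raw data, and not that real
GBS artefacts (shared missingness along restriction fragments, depth
heterogeneity, reference bias) are handled.

## Genotype calling: the 15/11 window and its transitional het runs

Windows of 15 informative SNPs (het and missing calls are excluded from the
counts, following the study's rule that unexpected calls are treated as
missing) slide one SNP at a time; a window with 11 or more calls from one
parent is homozygous for that parent, anything else is heterozygous. Runs of
equal window labels merge into blocks; each adjacent block pair is a
recombination breakpoint. Where fewer than 15 informative SNPs are
available, a single truncated window keeps the 73 % supermajority by
rescaling the threshold to `ceiling(11/15 * n)`.

Two behaviours of this rule deserve emphasis because the source protocol is
silent on both:

* **Breakpoint placement.** Adjacent label runs share 14 SNPs; the cut
  between their blocks is placed at the midpoint of that overlap. This is a
  documented interpretation — window-centre placement would be equally
  compatible with the protocol — and only shifts boundaries by a few SNPs.
* **Transitional heterozygous slivers.** At every clean homozygous junction
  the straddling windows have 5-10 calls from each parent, so the caller
  necessarily emits a short H run between the A and B blocks, and the
  literal block-pair rule then counts *two* breakpoints per true junction.
  No smoothing is applied by default (an opt-in `min_block_windows`
  absorbs short runs); notably, the study's own 40.87 breakpoints per line
  exceeds the theoretical $2L \approx 31$, consistent with some degree of
  the same inflation, and the package does not attempt to resolve which
  mechanism produced their excess.

## Bins, the genetic map, and its known approximations

A 100-Kb grid interval is a *boundary interval* if any line's breakpoint
uncertainty interval overlaps it; maximal runs of quiet intervals form one
bin, with each boundary interval attached to the bin it starts (right
attachment keeps bin starts aligned to recombination events; the protocol
does not state a convention). Per line, a bin's genotype is the block label
covering the majority of its base pairs. Before that assignment, an H block
sandwiched between opposite homozygous blocks is collapsed to a point
junction at its midpoint: in an F11 line (residual heterozygosity ~0.1 %)
such a sliver is breakpoint uncertainty, not genotype. Without this
collapse, every recombinant line reads A-H-B across its junction, no
adjacent bin pair is ever A/B for the recombinant line, and the pairwise
recombination-frequency estimator below degenerates to a zero-length map.
Genuine heterozygous stretches — H blocks with same-label or no homozygous
neighbours — are kept.

Genetic distances are estimated pairwise between adjacent bins: the
observed recombinant fraction $\hat R$ (mismatches among lines homozygous
and non-missing at both bins) is corrected for selfed-RIL map expansion
through the Haldane-Waddington relation $r = \hat R / (2(1-\hat R))$ and
converted to cM with Kosambi's $d = 25\ln((1+2r)/(1-2r))$. This pairwise
chain replaces the multipoint EM estimation used in the study (`est.map`);
it is a good approximation for dense markers with low missingness and is
validated by simulation (chromosome lengths within 10 % of truth for
error-free, fully observed data). Numerical guards: $\hat R$ is clamped at
0.49 before correction, $r$ at 0.4999 before Kosambi; adjacent pairs with
no informative line are flagged and assigned distance 0 with a warning
rather than breaking the cumulative map. The map summary reports average
spacing as chromosome cM over marker count, matching the convention that
reproduces the published per-chromosome values.

## QTL scanning

Genotypes enter the scan as expectations: -1/0/+1 at observed bins, and for
missing genotypes or pseudomarkers (default 1-cM grid) the conditional
expectation given the nearest flanking homozygous bins under the RIL Markov
model, with cM gaps inverted through Kosambi and re-expanded to RIL scale.
Heterozygous flanks are uninformative for imputation (at F11 they are rare
artefacts more often than genotype). The scan itself is a Haley-Knott-style
single-QTL regression: $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$, effect =
regression slope, PVE = $100(1 - RSS_1/RSS_0)$. The study names composite
interval mapping; since neither its cofactor-selection protocol nor any of
its tabulated attributes depend on the variant, the auditable single-QTL
scan is the core here and the permutation protocol is identical: 1000
permutations of phenotypes across lines (one shared permutation per
replicate genome-wide), threshold at the empirical 95th percentile,
declaration floor LOD 3.5, 1.5-LOD support intervals reported via the
flanking bin markers' outer coordinates.

Peaks of the same trait on one chromosome whose support intervals overlap
across environments merge into one QTL carrying environment tags and mean
LOD/PVE/effect — the convention of the published QTL table. "Stable" means
detected in at least two environments (the reading under which the
published stable count, nine, reproduces from its own table). QTL of
different traits with overlapping intervals chain into pleiotropic regions
whose interval is the union of member intervals; the union convention
reproduces the published 14.6-Mb (chromosome 10) and 20.7-Mb (chromosome 1)
regions, though not every row of the published pleiotropic table, which
mixes union and member intervals.

The tabulated additive effect is the fitted slope under +/-1 coding, i.e.
half the homozygote-class difference, sign-anchored so positive means the
Qi319 allele increases the trait. The source is ambiguous about whether its
printed effects are half-differences or full substitution effects; the
half-difference is the default here and the doubling is left to the reader,
since only the convention, not the fit, differs.

## Variance components and heritability

On a balanced lines x environments x replicates trial, method-of-moments
(expected mean squares) estimates are
$\hat\sigma^2 = MS_{err}$, $\hat\sigma^2_{ge} = (MS_{ge} - MS_{err})/r$,
$\hat\sigma^2_g = (MS_g - MS_{ge})/(er)$, clamped at zero with a warning;
unbalanced designs are rejected rather than silently fitted (no REML
fallback). Broad-sense heritability follows the line-mean formula
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/e + \sigma^2/(er))$ — the
published formula's final term is read as $\sigma^2/(er)$, the standard
line-mean form, rather than the literal $\sigma^2 r / e$, which is
dimensionally implausible. Descriptive statistics report the third
standardized sample moment for skewness and *excess* kurtosis (the
published near-zero values for near-normal traits indicate that
convention), and CV is always computed from the data — the published CV
column is internally inconsistent with its own means and SDs and is not
matched. Trait correlations are Spearman rank correlations with mid-ranked
ties, per environment and pooled.

## Reproducibility and scale

Every stochastic step takes a seed; the pipeline derives per-stage and
per-line substreams from one root seed, so `run_pipeline()` is
byte-identical across runs and lines are reproducible individually. The
shipped acceptance script runs the whole chain at a reduced SNP density (10
per Mb instead of 43) with the observation rate raised to preserve the
study's informative-call density per line; the test suite's calibration and
recovery experiments state their reduced scales (200 null replicates at 200
permutations and 150 lines; 50 recovery runs of 314 lines on a
two-chromosome genome) in the test file itself.

## Known limitations

Read-level phenomena (restriction-site dropout, depth variation, mapping
error) are outside the observation model; marker order is taken from the
physical map rather than inferred; the pairwise map estimator ignores
information in lines missing at one of two adjacent bins; double crossovers
closer together than the window span are invisible to the caller, which
biases the map slightly short at sparse observation; and the
permutation threshold assumes exchangeability of line means across
environments within a trait.
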