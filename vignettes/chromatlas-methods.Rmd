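---
title: "chromatlas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromatlas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromatlas builds cell-type-resolved atlases of accessible chromatin
regions (ACRs) from single-cell ATAC-seq Tn5 insertion data and compares
them across species. This vignette explains the statistical models behind
each stage, the parameters that matter, what the synthetic-data module does
and does not emulate, and the design choices taken where the methodology
was genuinely open.

## Signal model and coordinate conventions

The atomic observation is a Tn5 integration site: a single base position
obtained by shifting aligned read ends +4 bp (plus strand) or -5 bp (minus
strand), the standard correction for the 9 bp duplication the transposase
creates. All intervals are 0-based half-open (BED-native); GFF3 input is
converted on read. A point at an interval's start is inside it, a point at
its end is not.

Nucleus quality control (`qc_filter_nuclei()`) keeps barcodes with at
least 1,000 integration sites, a TSS fraction strictly above 0.2, a FRiP
strictly above 0.1 and an organelle read fraction within two standard
deviations above the library mean, capped at 16,000 barcodes ranked by
depth. The companion z-score filters that some pipelines pair with the
absolute TSS/FRiP thresholds require a score model that is not defined
here; the absolute thresholds are authoritative.

## ACR calling

Per cell type, insertions are piled up with a 150 bp window centred on
each site (shift -75, extend 150), mirroring how ATAC peak callers
approximate fragment centres. Candidate peaks are maximal runs of coverage
exceeding the upper 1e-5 quantile of Poisson(lambda * 150), lambda the
genome-wide insertion rate per bp; runs closer than 150 bp merge, and the
summit is the leftmost coverage maximum. This Poisson caller is
deliberately simple: the stage that actually governs the final calls is
the empirical permutation FDR that follows, so the candidate heuristic
only needs to be permissive and reproducible.

For the permutation FDR (`permutation_fdr_filter()`), an equal number of
intervals with the same width multiset is placed uniformly in mappable,
non-exonic space. Tn5 density (insertions per bp of span) is computed for
real and permuted sets, and the threshold is the minimum real density t
with `#{perm >= t} / #{real >= t} < 0.05`. Permuted intervals may overlap
each other or real peaks; the procedure needs only their marginal density
distribution. Peaks with more than 50% of their span covered by nucleosome
calls, or whose overlapping insertions have mean fragment size above
150 bp, are dropped; survivors become 500 bp windows centred on the
summit (slid inward, never truncated, at chromosome ends). Per-cell-type
pools are merged by interval union and re-centred on the pooled-coverage
summit.

## Entropy specificity and its bootstrap test

For ACR counts CPM-normalized per cell type, with proportions
$p_c = \mathrm{CPM}_c / \sum_k \mathrm{CPM}_k$ and entropy
$H = -\sum_c p_c \ln p_c$, the specificity score of cell type $c$ among
$K$ types is

$$s_c = p_c \left(1 - \frac{H}{\ln K}\right),$$

which is 1 for a point mass in one cell type and 0 for a uniform profile.
The weighting by $p_c$ follows the standard entropy-specificity form; the
qualitative contract (1 for point mass, 0 for uniform) is what downstream
stages rely on.

Significance comes from a bootstrap: in each of 5,000 real replicates
every cell type's pseudobulk is rebuilt from 250 cells resampled with
replacement from that type's own population; the matching null replicate
swaps only the focal type's profile for a 250-cell draw from the pooled
mixed population (the "random shuffle"), keeping the other types'
bootstrap profiles. Real and null replicates therefore differ in exactly
one thing — whether the focal cells carry their true label — which is
the hypothesis under test. The empirical p-value is
`(1 + #{null > median(real)}) / (1 + 5000)`, whose floor 1/5001 sits
below the 0.001 decision cut; ACRs whose median real score is 0 report
p = 1. Three design points deserve emphasis. First, the other types'
profiles must stay at their (bootstrap) observed values: a null that
randomized all profiles at once would test mere deviation from complete
uniformity, and any asymmetric ACR would come out "specific" in every
cell type. Second, the comparison is strict (`>`, not `>=`): in the
noiseless corner where an ACR's signal is confined to one type and all
other profiles are exactly zero, the mixed focal draw still carries all
of the signal and real and null scores tie at 1 — a non-strict rule
would make the most perfectly specific ACR the least significant.
Third, the bootstrap pool should comfortably exceed the 250-cell
resample size; with pools near 250 the finite-pool variance inflates
the tail slightly.

ACRs significant (p < 0.001) in one or two cell types are labelled
cell-type-specific in `leaf` mode; `atlas` mode admits up to three,
matching the under-5%-of-59-cell-types convention for large atlases.

## Candidate silencers: H3K27me3-associated broad ACRs

Accessibility is a per-(ACR, cell type) call requiring all three of:
maximum per-base coverage in the peak, scaled per million insertions,
strictly above 2; at least 20 integration sites; and quantile-normalized
CPM strictly above 2 (CPM via edgeR, quantile normalization by
column-quantile averaging as in limma). With $n$ cell types, an ACR
accessible in at least $n-1$ ($n < 10$; $n-2$ for $n \ge 10$) is broad;
fewer than 3 (resp. 4) is cell-type-specific; the rest are intermediate.
An ACR is H3K27me3-associated when it overlaps a domain or lies within a
500 bp flank — "surrounding" is not quantified in the originating
methodology, so one ACR width is the default and the flank is a
parameter. Candidate silencers are the associated broad ACRs; at atlas
scale in plants a large share of these carry Polycomb-response-element
(PRE) motif classes (CTCC, CCG, G-box, GA-repeat, AC-rich, Telobox),
shipped here as replaceable IUPAC assets.

Linked genes sit 500-5,000 bp downstream of the ACR (gap measured TSS to
nearest ACR edge, strand-aware, boundary-inclusive) with H3K27me3 covering
more than half of the gene body. The expression contrast is a paired
one-sided Wilcoxon signed-rank test per cell type against an equal-count,
expression-rank-matched set of genes linked to H3K27me3-absent broad
ACRs.

Broad methylation regions (BMRs) are maximal runs of at least three
consecutive 500 bp windows with methylation strictly above the
genome-wide mean.

## Motif scanning and the three enrichment tests

PWM hits use the log2 likelihood ratio against a background model with a
score threshold computed exactly: the score distribution under the
background is obtained by dynamic programming over per-column scores
discretized at 1e-3, and the threshold is the smallest attainable score
whose tail probability is at most 1e-5. Scanning uses the same
discretized scores, so threshold and scan are consistent by construction.
Note an 8 bp motif cannot attain p <= 1e-5 under a uniform background
(the single best word already has probability 4^-8 > 1e-5); such motifs
yield no hits at that threshold, which is the mathematically correct
behaviour. Pattern motifs are matched by IUPAC expansion; both strands
are always scanned.

The three enrichment procedures:

* **Negative-binomial regression** (per motif, per cell type): cells are
  downsampled to 412 per type; the motif's per-cell count follows
  `log mu = b0 + b1 * 1[cell in type] + b2 * log(nonzero peak entries)`.
  A Poisson fit supplies a method-of-moments dispersion, the model is
  refit once with that dispersion, and `b1` is the enrichment score with
  Wald p-values BH-adjusted across motifs within each cell type
  (per-cell-type scope is the default; the alternative global scope is a
  documented switch). Enriched: q < 0.01 and b1 > 0.05.
* **Exact binomial against simulated nulls**: 100 null region sets with
  the target's exact width multiset, placed uniformly in allowed space
  and not overlapping the targets; the mean null capture ratio is the
  hypothesized success probability for a one-tailed (greater) exact
  binomial test. Degenerate null ratios are clamped away from 0/1 and
  flagged.
* **Family-level hypergeometric**: one-tailed upper tail of the
  hypergeometric for target ACRs containing any motif of the family
  versus the universe.

## Cross-species conservation inside syntenic blocks

Syntenic blocks are consumed as paired intervals, filtered to one-to-one
(any overlapping interval on either species drops both pairs involved),
with inverted blocks reverse-complemented so alignment is always
plus-strand against the block. The aligner is seed-and-extend: exact
7-mer seeds, ungapped X-drop extension, then affine-gap extension
(open 5, extend 2, on a +1/-1 match/mismatch scale) from both segment
ends via banded dynamic programming in C++. Significance uses
Karlin-Altschul statistics, $E = K m n e^{-\lambda S}$ with raw sequence
lengths (no edge correction; the sequences are short). For +1/-1 scoring
on a uniform background $\lambda$ solves
$\tfrac14 e^{\lambda} + \tfrac34 e^{-\lambda} = 1$, i.e.
$\lambda = \ln 3$ exactly — one reason the synthetic genomes use i.i.d.
uniform background sequence. $K$ defaults to 0.62; the E-value ranking
does not depend on it, and the cutoff behaviour is validated empirically
by a null-calibration test (hits at E <= e occur at most 2e times per
shuffled pair). Hits pass when E <= 1e-3 and alignment length exceeds
20 nt. Reported identity covers the ungapped core segment.

A query ACR whose passing hit, lifted through the block's orientation
transform, overlaps a partner-species ACR by at least 1 bp is `shared`
(the stricter reading: the alignment itself must land in the partner ACR,
not merely in a block containing one); a passing hit without partner
overlap is `variable`; no passing hit is `species_specific`. ACRs outside
every block are reported as non-syntenic rather than forced into a
class. For shared cell-type-specific ACRs, the partner's labels decide
`retained` / `switched` / `broadened`.

## Pseudotime trajectory comparison

Motif deviations follow the chromVAR idea: observed insertions in
motif-containing peaks minus the depth-scaled expectation, over the
expectation, z-scored against 50 background peak sets matched on
accessibility decile. Curves are interpolated to a fixed 200-point grid
by Gaussian-kernel weighted means (bandwidth 0.1 of the pseudotime range)
and z-scaled per motif; numerically flat curves scale to zero rather than
amplified rounding noise. Neighbour-diffusion imputation is available
conceptually but off by default — the classification contract is defined
on the kernel-interpolated curves.

Dynamic time warping uses absolute-difference local cost with a
boundary-anchored monotone path; the distance is the summed path cost
over $\sqrt{G}$ ($G$ = features aligned jointly, 1 per motif pair).
K-means (k = 2) on the distances separates a high group (shifted
candidates) from a low group. Two places where the obvious statistic
fails motivated design decisions:

* The difference of two time-shifted sigmoids is a bump, so regressing
  `delta(t)` on pseudotime alone has essentially no power; the
  significance gate is the F-test of `delta(t) ~ t + t^2`, BH-adjusted,
  and shift labels require q <= 0.05 (`unknown` otherwise).
* The mean DTW path lag is dominated by plateau stretches where the
  warping path is uninformative, and flips sign for a noticeable
  fraction of genuinely shifted motifs at moderate noise; the lead
  direction therefore comes from the grid shift maximizing the
  cross-correlation between the two curves (positive shift = species A
  leads → `shiftEarlyA`). The DTW path lag is still reported.

Low-group motifs whose per-species linear slopes share a sign are
`conserved`; the conserved call does not require a significant
difference curve (a conserved pair has none by definition). A related
reading ambiguity — whether the high- or low-distance cluster should be
called conserved — is resolved here in favour of low distance, since a
conserved pair is one whose curves align with little warping cost.

## The synthetic-data module

The generators produce every input the pipeline consumes, with planted
truth: uniform background genomes laid out in 10 kb units (gene body at a
fixed offset; distal/proximal/genic 500 bp peak slots placed so each
context is unambiguous by construction); negative-binomial per-cell
depths; insertion positions from a peak/background mixture in which the
in-peak rate is `snr` times the background rate; bimodal fragment sizes
(subnucleosomal inside true peaks, nucleosomal inside decoy peaks so the
fragment-size filter has something to catch); H3K27me3 domains embedding
a chosen fraction of broad peaks (the planted silencers, each receiving a
PRE consensus in the sequence); methylation windows with planted BMR
runs; a second species produced by substituting bases at a set divergence
outside conserved ACR cores, with shared/variable/species-specific truth
and optional inverted blocks; and paired sigmoid deviation trajectories
with planted pseudotime lags. Context proportions default to 19/52/29%
(genic/proximal/distal), the distribution typical of compact plant
genomes.

Deliberate simplifications, hence what passing tests do **not** show
about real data: background insertions are uniform (no Tn5 sequence
bias, no chromatin-state covariates); cell types are discrete with no
doublets or continuous gradients; species divergence is
substitution-only (no indels or rearrangements within blocks, which
keeps planted coordinates exact — indel robustness of the aligner is
exercised only implicitly through its gapped extension); trajectories
are single sigmoids, not mixtures; and sequencing error is absent.
Recovery rates on these fixtures certify the implementation against its
specification, not performance on tissue.

Domain padding around planted silencers defaults to 400 bp, below the
spacing between peak slots, so an H3K27me3 domain never creeps within
the 500 bp association flank of a neighbouring non-silencer peak — a
layout constraint, not a tuning knob.

## Numerical choices and problem sizes

PWM score discretization 1e-3 (configurable); ties in candidate summits
break leftmost; the empirical-p add-one smoothing uses `>=` for ties;
degenerate k-means input (all equal distances) collapses to a single low
group; zero-variance vectors are skipped in correlations and flagged in
z-scores. The test-suite problem sizes are chosen to finish in minutes on
one CPU while leaving the planted signals unambiguous: a 2 x 1 Mb
six-type atlas (2,400 cells, about 7 x 10^5 insertions) for end-to-end
ACR calling; 3,000 cells and 1,000 bootstrap replicates (scaled from the
5,000 used at atlas scale; the p floor 1/1001 still sits below the 0.001
cut) for the specificity test; 10 seeds of two-species simulations at
divergence 0.15 for conservation; 1,000 shuffled pairs for E-value
calibration; and 20 seeds of 412-cell-per-type regressions for the
NB-enrichment recovery. The vignette states these as the package's
validation conditions; all are parameters the user can scale up.

## Limitations

The pipeline consumes upstream outputs (nucleosome calls, H3K27me3
domains, Hi-C loops, syntenic blocks, pseudotime) as given and does not
re-derive them. The candidate peak caller is intentionally minimal and
should not be compared parameter-for-parameter with model-building
callers. The entropy-specificity weighting follows the standard form but
the originating description defers to earlier work without printing the
formula; results that depend on the exact weighting (rather than the
point-mass/uniform contract) should be interpreted with that in mind.
E-values use ungapped Karlin-Altschul parameters also for gapped
alignments, as short-sequence search tools commonly do; for the supported
sequence lengths the factor-2 calibration bound holds empirically.
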