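---
title: "Auditing STARR-seq peak sets against a predicted CRM annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing STARR-seq peak sets against a predicted CRM annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starraudit)
```

## The problem

STARR-seq and its variants measure enhancer activity episomally: candidate
fragments are cloned downstream of a minimal promoter and transcribe
themselves when they act as enhancers. Two structural limitations follow.
Fragments lack their native chromatin context, so sequences that are
silenced in the genome can score as active on the plasmid (false
positives); and the insert size (typically ~500 bp, at most ~1500 bp) is
shorter than most enhancers, so long elements are assayed only as truncated
pieces that may no longer function (false negatives).

`starraudit` quantifies both failure modes by confronting a STARR peak set
with an independent genome-wide annotation that splits the analyzable
genome into predicted cis-regulatory modules (CRMs) and non-CRMs, and
splits the CRMs per sample into predicted *active* and *non-active* states.
Crossing these annotations with peak overlap assigns every analyzable base
exactly one of six categories:

| category | CRM annotation | functional state | STARR peak |
|----------|----------------|------------------|------------|
| A | CRM | non-active | no |
| B | CRM | active | no |
| C | CRM | active | yes |
| D | CRM | non-active | yes |
| E | non-CRM | — | yes |
| F | non-CRM | — | no |

The audit's headline quantities are base-position shares derived from these
counts: `C/(C+D+E)` (the share of peak bases supported by an active CRM),
`D/(C+D+E)` and `E/(C+D+E)` (peak bases on repressed CRMs and on non-CRMs —
candidate false positives), and `B/(B+C)` (the share of active-CRM bases
missed by the assay — the candidate false-negative rate).

## Base labels versus element pairing

The annotation literature defines peak/CRM *identity* by reciprocal
overlap: a peak and a CRM match when their intersection covers at least
50% of both lengths. A base-level partition cannot use that rule directly
and stay exhaustive and exclusive, so the package separates the two ideas:

* **Base labels** use direct base intersection: a peak base inside an
  active CRM is C, no matter whether that peak/CRM pair passes the
  reciprocal test. Only this reading makes the shares `C/(C+D+E)` and
  `C/(B+C)` internally consistent (they are ratios of base positions).
* **Element pairing** (`match_peaks_to_crms()`) applies the 50% reciprocal
  rule, inclusive at the boundary, and feeds the element-level statistics:
  full/partial containment of CRMs in peaks and peaks-per-CRM counts.

We considered a strict mode applying the reciprocal rule to base labels as
well; it is deliberately not provided, because the element-level pairing
table already exposes everything such a mode would compute, without
creating a second, inconsistent set of base counts.

Peak bases falling outside the analyzable regions (where no CRM/non-CRM
call exists) are reported as a separate `unassessed` count and excluded
from all shares, never silently dropped.

## Preprocessing filters

CRMs that reciprocally overlap a silencer or a CTCF peak at the 50%
threshold are removed (they may be silencers or insulators rather than
enhancers), as are CRMs within 1000 bp of a transcription start site
(likely promoters). Distance is measured from the nearest CRM edge — zero
for a TSS inside the CRM — because a midpoint rule would retain long CRMs
straddling promoters; the boundary is inclusive. For the removal report,
an element is counted once under the first matching filter (silencer,
then CTCF, then promoter); the retained set itself is order-independent.
When `run_audit()` applies these filters, the removed CRM footprints are
also removed from the analyzable regions, so the remaining CRM/non-CRM
annotation still covers exactly what is analyzed — the source procedure
does not specify this step, and without it the exhaustive-partition
invariant cannot hold.

Replicate STARR peak sets are folded into a consensus as the base-level
intersection of any-overlap-matched peaks: conservative, deterministic,
and every consensus base is supported by both replicates. More than two
replicates fold sequentially.

## The functional-state caller

CRM states are called by a logistic-regression classifier on four marks:
chromatin accessibility (ATAC), H3K4me1, H3K4me3, and H3K27ac. The
published audit used pretrained weights from a 67-cell-type compendium
that is not distributed; this package therefore ships the same model
family with a trainer, and accepts user-supplied weights via the JSON
serialization (`write_ufsp()` / `read_ufsp()`).

Each feature is `log1p` of the element's mean per-base fold enrichment of
the mark over input, both normalized by library size. Bases with zero
input receive a pseudocount of one read-equivalent in numerator and
denominator, bounding the ratio. The original description says only that
the four signals "were used as the features"; averaging over the element,
the log transform, and z-standardization at training time are this
package's documented concretization. The fit is maximum-likelihood
logistic regression with a small L2 ridge (`lambda = 1e-3` on standardized
features) so that separable data still yield a defined optimum; the fit is
deterministic. The classification threshold defaults to 0.5 (the source
does not state its cutoff) and the rule is inclusive: probability exactly
at the threshold is called active.

Chance-level behaviour on null data is assessed by held-out AUROC
(train/test split) rather than training AUROC, because with four
predictors and moderate n the training AUROC of even a null fit sits
visibly above 0.5.

## Structure complexity, enrichment, and statistics

**Complexity.** For an element with `n` TFBS hits (any 1-bp overlap maps a
hit into an element; hits spanning the boundary count once),
`N_TFBS = n / (length/100)` and `D` is the mean degree of the hits'
*unique* motifs in the motif interaction network (a motif with many hits
in one element contributes its degree once; motifs absent from the network
get degree 0 and a warning). The score is `log(N_TFBS × D + 1)`. The log
base is not stated in the source; the natural log is used (configurable) —
any base preserves ordering.

**Enrichment.** Fold change is `(N − M)/M`, where `N` is the foreground
quantity (bases covered by a chromatin-state label, or the count of
transposable elements overlapping by ≥ 1 bp) and `M` the same quantity on
random background sets matched in element count and exact length multiset,
optionally also in GC content (rejection sampling, tolerance ±0.02,
10,000 attempts per template). Backgrounds are placed uniformly over
chromosomes proportional to length, rejecting placements that cross
chromosome ends or an exclusion set. How many random draws the source used
is not stated; the default averages `M` over 10 draws (a single draw
reproduces the literal procedure; `n_draws = 1`). Note that `(N − M)/M` is
a ratio estimator: with a noisy `M` its null mean is biased upward, which
is why the calibration checks use template sets large enough for `M` to be
stable.

**Gene association and tests.** Each element is assigned the gene with the
closest TSS by edge distance on the linear chromosome (0 inside the
element; ties broken by distance then lexicographic gene id; strand
ignored). Within a category a gene contributes one expression value even
when several elements point to it; a gene may appear under multiple
categories. Distributions are compared with the two-tailed Mann–Whitney U
test — exact when the smaller sample has ≤ 8 observations and there are no
ties, otherwise the normal approximation with tie and continuity
corrections — and the Kolmogorov–Smirnov test (asymptotic p). Raw p-values
are primary; a Benjamini–Hochberg column is optional and off by default.

**Profiles.** Signal profiles take a 6-kb window centered on the element
midpoint (lower-median base for even lengths), tiled into non-overlapping
100-bp bins ("w0"-style binning, not a rolling mean); each bin holds the
mean fold enrichment over input with the same pseudocount rule as the
state features, so peak strengths, state features and profiles share one
definition. Off-chromosome bins are masked, not zero-filled, and masked
entries are excluded from column means. Row sampling per category follows
the audit's heatmap rules: all C, D and E elements, at most 10,000 random
A and B elements, and F downsampled to the size of E.

## The synthetic-data generator

`generate_scenario()` builds a complete scenario — genome FASTA, CRM /
non-CRM / peak / TFBS / chromatin-state / TE intervals, eight signal
tracks, genes with expression, a motif network, and ground-truth labels —
deterministically from a seed. It emulates the statistical structure the
analysis assumes:

* **Geometry.** Chromosomes alternate CRMs and non-CRM gaps. CRM lengths
  are log-normal with mean 1181 bp (the average length of the predicted
  CRM catalog the audit was built on); peak lengths are log-normal with
  median 500 bp, matching typical STARR insert sizes. Defaults use
  3 × 800 kb of genome and 900 CRMs (≈ 45% CRM bases, near the real
  catalog's share).
* **Peak mixture.** Each peak draws a category from the configured C:D:E
  mixture (default 0.23 : 0.28 : 0.49, the averaged peak-position shares
  reported across nine cell lines/tissues) and is placed entirely inside a
  host element of the right type, so intended labels are consistent by
  construction. With same-shaped length distributions across categories
  the realized base-share mixture tracks the count mixture to within
  binomial error (±3 points at 1000 peaks).
* **Active fraction.** 40% of CRMs are active by default. The real audit
  has ≈ 11.5% active CRM bases per sample, but at desk scale that would
  leave too few active CRMs to host the C peak mass without saturating
  them; 0.4 keeps hosting unconstrained while preserving every ordering
  the analysis tests. This is the one deliberate departure from the
  real-data proportions, and `C/(B+C)` is therefore not comparable to the
  real study's 2.1%.
* **Marks.** Tracks are Poisson read counts per 10-bp step at
  `input_rate × effect`, with per-category effects: active CRMs carry
  strong ATAC/H3K4me1/H3K27ac and moderate H3K4me3; category-A CRMs are
  moderately marked by both repressive marks; D is heavily marked by
  H3K27me3; E peaks are heavily marked by H3K9me3 (the heterochromatin
  signature of the false-positive class). STARR signal is strongest in C,
  then D, then E.
* **Annotation plantings.** The `Het` chromatin state covers 60% of each
  E peak (centered), and the background rate outside E peaks is solved so
  the genome-wide Het share is exactly 10% in expectation — making the
  expected enrichment `(0.6 − 0.1)/0.1 = 5`. TFBS hits are planted at
  10/5/6/2 hits per kb in C-hosting CRMs / other CRMs / E-hosting
  non-CRMs / background, with C hits drawn from the network's hub motifs
  (higher degree), reproducing the complexity ordering C > B ≈ A and the
  TFBS-density excess of E peaks over random non-CRMs. Conservation is a
  Gaussian track shifted by +1.5 inside CRMs only. Genes are scattered
  uniformly; a gene whose nearest element is an active CRM gets a 4-fold
  TPM boost. TEs are placed uniformly and retained with probability 0.15
  when their center falls in a CRM (depletion).
* **Null scenarios.** `generate_null_scenario()` keeps the skeleton and
  removes every planted effect; it drives the type-I-error and enrichment
  calibrations.

What the generator does **not** emulate: mappability and assembly gaps,
repeat structure beyond the planted TE intervals, spatially correlated
read noise, nucleosome positioning, multi-TSS genes, and the real
catalog's extreme class imbalance. Passing tests therefore demonstrate
the correctness and calibration of the computations, not that real data
would yield the published shares.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; IRanges' 1-based closed
  convention is translated at the package boundary. Chromosome-name
  mismatches are errors unless an explicit alias map is given.
* Overlap counting merges book-ended/overlapping intervals first; counts
  may differ marginally from a procedure that does not normalize.
* All reciprocal-overlap and threshold comparisons are inclusive (`>=`).
* `fold_change` with `M = 0`, GC of an all-N sequence, an element on a
  chromosome without genes, and an empty category all return NA sentinels
  with warnings rather than errors.
* Every stochastic step (background draws, row sampling, the generator)
  takes an explicit seed and is bit-reproducible given it.

## Problem sizes used by the test-suite calibrations

Oracle-equivalence checks run 500 random genomes of up to 10 kb against a
literal per-base labeling. Mixture recovery uses the default 1000-peak
scenario. Type-I calibration uses 200 null scenarios of 60 kb / 25 CRMs /
80 genes; enrichment null calibration 100 background-vs-background
simulations of 40 matched templates; the null AUROC check 20 null
scenarios of 200 CRMs with held-out evaluation. These sizes were chosen so
each calibration's sampling error is comfortably inside the asserted
band.

## Limitations

The UFSP trainer reproduces the model family, not the published weights,
so state calls on real data will differ from the original audit's. The
closest-gene rule is a deliberate simplification (the source argues
dedicated target-assignment methods are not clearly better). Enrichment
significance is not tested (the audit reports fold changes only), and the
cross-category expression grid reports raw p-values by design.
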