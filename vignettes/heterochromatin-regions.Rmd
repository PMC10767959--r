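---
title: "Classifying, annotating and comparing heterochromatin regions"
author: "hcregions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying, annotating and comparing heterochromatin regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcregions)
```

## Background and scope

Heterochromatin is operationally defined from ChIP-seq by three repressive
histone marks: H3K9me2 and H3K9me3 for constitutive heterochromatin and
H3K27me3 for facultative heterochromatin. A common workflow calls peaks
per mark (e.g. with MACS2), then asks which genomic regions are supported
by one, two or all three marks; annotates the regions against gene models;
and compares a case sample with a control to find differential
heterochromatin regions. `hcregions` implements this post-peak-calling
stage. Upstream read processing is out of scope: the package consumes peak
files, and takes them exactly as called — peaks are never merged within a
mark before classification.

All coordinates inside the package are 0-based half-open (BED convention).
GTF input, which is 1-based closed, is converted at the reader boundary,
and adjacent intervals `[a,b)`/`[b,c)` do not overlap. Chromosome names
are matched by exact string equality — `"chr1"` and `"1"` are different
sequences; silent aliasing hides input errors, so any normalization is the
caller's explicit step.

## The multi-mark recognition model

Two peaks of different marks jointly recognize a region when their overlap
is *strictly greater* than 50% of the length of at least one of the peaks.
Because the overlap never exceeds either length, "greater than half of at
least one" is algebraically the same as "greater than half the shorter
peak", and the package property-tests that equivalence. The three-mark
rule is analogous on the three-way intersection. Two readings of "any one
region" are possible — *at least one* or *every one* — and the package
uses the inclusive reading; it is the one under which the min-length
equivalence makes the rule well defined, and the exclusive reading is
recoverable by filtering on the reported overlap.

Published compendia report disjoint one-/two-/three-mark counts, which
implies each peak is counted once. Classification is therefore
hierarchical and exclusive: candidate triples are accepted first, greedily
by descending three-way intersection length (ties: leftmost interval, then
lexicographic mark order), consuming their peaks; remaining peaks form
pairs, greedy by descending overlap; whatever is left becomes single-mark
regions with their full peak extent. The greedy order and tie-breaks are
package decisions — the rule itself does not dictate an assignment when,
say, one H3K9me3 peak could pair with either of two H3K9me2 peaks — and
canonical pre-sorting makes the result independent of input order. A
multi-mark region's coordinates are the intersection of its contributing
peaks, i.e. the genomic span every recognizing mark actually covers;
`extent = "union"` is available for users who prefer the merged footprint.

Classification runs within one sample (one peak file per mark). Combining
samples into tissue-level tracks, or consensus/IDR analysis across
replicates, is deliberately left to the caller.

## Differential regions

For each case region the binary flag `F` is 1 when the region shares no
base pair with the control region set — presence in the case with *no*
control counterpart is treated as differential by construction. Overlap
here means any overlap of at least 1 bp: the differential step uses plain
set intersection, not the 50% recognition rule. For overlapping regions
`F` equals `M = 1[p ≤ α]` with an inclusive threshold at α = 0.05 and no
multiple-testing correction by default; `adjust = "BH"` applies the
threshold to Benjamini–Hochberg adjusted p-values instead, and the set
`{F = 1}` grows monotonically with α.

The p-value comes from a conditional exact count test implemented in the
package. Given per-region counts `x_case`, `x_control` and library sizes
`N_case`, `N_control`, the test conditions on `n = x_case + x_control`; at
the default `dispersion = 0` the conditional law is
`Binomial(n, N_case/(N_case + N_control))`, and the two-sided p-value sums
all outcome probabilities no larger than the observed one (the
minimum-likelihood convention, well defined for asymmetric success
probabilities; a doubled-tail alternative is available). For overdispersed
counts, `dispersion = d > 0` enumerates the conditional law of two
independent negative binomials with common size `1/d` and means split by
library share — the classic exact-test model for sequencing counts —
normalized over `0..n`. At `d → 0` this reduces to the binomial, which a
unit test verifies, and an optional test cross-checks the enumeration
against edgeR's exact test on the same counts. Counts are accepted
pre-summed per group as opaque integers (reads in region or summed peak
signal); the package does not estimate dispersion from replicates because
it takes no replicate model as input.

Two numerical details worth stating: `p = 1` when `n = 0` (no
information), and minimum-likelihood comparison uses a `1 + 1e-7` relative
slack so ties in floating point do not drop outcomes.

## Annotation conventions

Regions are anchored at their midpoint (`floor((start+end)/2)`). The peak
summit or start would be defensible anchors too; the midpoint is simple,
symmetric under strand, and documented — results will therefore differ in
detail from annotators anchored elsewhere (e.g. ChIPseeker), which is
expected. Signed distance to a TSS is positive downstream of the TSS in
the transcript's direction of transcription; the nearest transcript
minimizes the absolute distance with deterministic tie-breaks
(lexicographically smaller gene name, then transcript id). The feature
category is the highest-priority label achieved by any same-chromosome
transcript: Promoter (TSS ± 3000 bp, inclusive at both edges) > 5'UTR >
3'UTR > Exon > Intron > Downstream (within 3000 bp past the 3' end) >
Distal Intergenic; the priority vector is an argument for users who want a
different precedence. UTR labels require an annotated CDS — they are
undefined without one — so non-coding transcripts contribute only
Promoter/Exon/Intron/Downstream calls. A region on a chromosome absent
from the annotation is reported as Distal Intergenic with empty gene
fields plus a warning, rather than an error, so one stray scaffold does
not abort a run.

GO/KEGG identifiers are attached from user-supplied two-column gene→ID
mappings rather than a bundled ontology snapshot: shipping a frozen copy
of a versioned external database invites silent staleness.

## Enrichment

`enrich()` performs one-sided hypergeometric over-representation (no
depletion testing) with BH correction across sets. The default universe is
the union of all gene-set members — the only background derivable from the
inputs alone — and a `universe` argument overrides it; the choice of
background materially changes p-values, so it is always reported in the
output rows. Query genes and set members outside the universe are dropped
with a warning, never silently.

## What the simulator emulates — and what it does not

`simulate_peakset()` generates per-mark peak sets on a toy genome (default
two 5-Mb chromosomes) with log-normal peak lengths, parameterized by
natural-scale mean 1000 bp and sd 600 bp, floored at 50 bp — lengths in
the range MACS2 typically reports for repressive marks. Planted two- and
three-mark groups are constructed so the group's common overlap is
*exactly* `round(f × shortest length)` for planted fraction `f`, anchored
on the shortest peak, which makes the ground truth unambiguous under the
min-length form of the rule: groups planted at `f = 0.6` must all be
recovered, groups at `f = 0.4` never. Below the threshold the two partner
peaks of a planted triple straddle the opposite ends of the anchor peak,
so that no *pairwise* overlap reaches 50% either — with both partners on
the same side a failed triple would still contain a valid pair, which is a
geometric fact about the rule, not a simulator artifact. Planted groups
are placed by rejection sampling so their footprints never overlap another
planted group (bounded retries, then an error suggesting larger
chromosomes); background peaks are placed uniformly and may overlap
anything, as real peaks do.

`simulate_counts()` draws per-region counts i.i.d. from a count model with
mean 50; a planted fraction of regions has its case mean multiplied by the
fold change (default 8). The default dispersion is 0 (Poisson), matching
the default dispersion-0 exact test so that null simulations are exactly
calibrated; setting `nb_dispersion > 0` gives negative-binomial counts,
which stay calibrated when analysed with the matching `dispersion` — a
unit test checks that pairing at dispersion 0.1. Note that with a single
pre-summed count per group, overdispersion costs real power: an 8-fold
change at mean 50 that the binomial test flags essentially always is
frequently non-significant under the NB conditional law at dispersion 0.1.
That is a property of the statistics, not a defect; users with replicates
should sum them only if they accept the implied dispersion-0 analysis.

What the simulator does **not** emulate: genomic sequence content,
mappability structure, copy-number bias, peak-width/signal correlation,
spatial clustering of heterochromatin domains, or replicate structure.
Passing the planted-recovery and calibration tests therefore demonstrates
algorithmic correctness of the classifier and the exact test under their
stated models — not robustness to the full messiness of real ChIP-seq.

Library sizes are set to the totals of the simulated counts, as in real
pipelines. One consequence is worth knowing: when many regions carry a
planted fold change, the case library grows accordingly and the implied
null proportion shifts for every region — the same composition effect that
normalization methods like TMM exist to correct. The package accepts
library sizes as given and leaves such normalization to the user.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in well under a minute: oracle equivalence on
500-interval random instances over 20 seeds, exhaustive rule grids on a
60-bp toy chromosome, 2000-region null and power simulations, and
120-group planted-recovery runs. Every stochastic step is seeded
(`withr::with_seed`), simulations are byte-reproducible given the
configuration seed, and classification output is invariant to input-row
order by canonical sorting.

## Known limitations

* The greedy exclusive assignment maximizes overlap locally, not globally;
  a maximum-weight matching could differ on dense pile-ups.
* Anchor-point annotation ignores region width; a 100-kb domain gets one
  feature label at its midpoint.
* The differential caller treats the control region set as given; whether
  it is one sample or a union of controls is the caller's modelling
  decision.
* No dispersion estimation, no replicate-aware testing, no library-size
  normalization beyond the conditional library-share.
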