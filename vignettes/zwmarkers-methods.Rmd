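---
title: "Evaluating intron-length-polymorphism sex markers in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating intron-length-polymorphism sex markers in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwmarkers)
```

## The problem

Birds use ZW sex determination: females are ZW, males ZZ. Because many
species — turacos (Musophagiformes) almost universally — show no sexual
dimorphism, sexing is done with PCR markers built on conserved genes
(*CHD1*, *NIPBL*, *SPIN*) whose Z and W gametolog copies differ in the
length of an intron. One primer pair amplifies both copies; on a gel a
female shows two bands (Z and W products of different length), a male one
band. Whether a marker works for a given species is then a question with
several computable parts:

1. Which intron does the primer pair actually bracket, and how long is
   the Z-specific product? (gene structure + in-silico PCR)
2. Does a second genomic copy of that product exist, where, and how long
   is it? (homology search + copy pairing)
3. Is the Z/W length difference ΔL separable on a practical agarose gel?
   (gel model)
4. Given all that, is the marker informative for sexing, and is a single
   band safe to call "male"? (verdicts and sex calls)

`zwmarkers` implements each part as a tested, reusable function and wires
them into one pipeline (`run_marker_pipeline()`). The `analysis/` scripts
in the repository run the pipeline over a packaged synthetic reference
landscape and over randomized synthetic genomes.

## Gene structure: spliced mapping

`map_exons()` maps an mRNA onto a genomic sequence to recover exon/intron
coordinates. It is a maximal-exact-match chainer, not a general
splice-aware aligner: exact anchors of at least `min_anchor` bases
(default 20) are clustered by alignment diagonal, same-diagonal clusters
separated by isolated substitutions are merged under the overall mismatch
budget (`max_mismatch_rate`, default 0.02 — the intended use is mapping a
transcript onto the *same individual's* assembly, so near-exactness is an
assumption, not a limitation), and clusters are chained co-linearly by
dynamic programming maximizing transcript coverage. A chain covering less
than 95% of the mRNA is an error ("unmappable"), and multiple equally
scoring chains raise an ambiguity error rather than an arbitrary pick.

When consecutive exons overlap a repeated motif, the exon/exon junction
is ambiguous at the sequence level. The package resolves it to the
leftmost placement whose implied intron starts with `GT` and ends with
`AG` when such a placement exists in the ambiguity window, otherwise
simply leftmost. This is a convention: canonical splice dinucleotides
make it biologically sensible, and leftmost makes it deterministic. Real
annotation pipelines differ in this choice; coordinates of junctions
inside repeats should be read with that in mind.

Intron *i* is the gap after exon *i* in transcription order; 1-based
inclusive coordinates are used everywhere internally, converted exactly
to 0-based half-open only on BED export. This numbering is what lets the
pipeline state that a primer pair *named* for intron 16 in fact amplifies
intron 17 in a given genome — the composition annotation, not the primer
name, is authoritative.

## In-silico PCR

`scan_primer()` finds binding sites for IUPAC-degenerate primers with at
most `max_mismatch` mismatches (default 2) and an exact 3'-terminal match
of `three_prime_exact` bases (default 3) — polymerase extension is
intolerant of 3' mispairing, and this cheap constraint removes most
spurious sites. An `N` in the genome never matches: an unsequenced
position is not evidence of a binding site. A site's `pos5` is the
genomic coordinate of the primer's own 5' base (left footprint end on the
plus strand, right end on the minus strand), so a convergent pair's
product length is `rev.pos5 − fwd.pos5 + 1`; this is the only convention
consistent with published marker position/length arithmetic, and it is
asserted in the tests.

`enumerate_amplicons()` reports **all** convergent products up to
`max_product` (default 5000 bp — comfortably above the longest product of
interest, 2997 bp; thermocycling extension times are not modelled).
Nonspecific and multiple products are real and diagnostic, so there is no
"shortest product wins" rule. Composition annotation intersects each
product with the gene model and emits segments like
`E22(30)/I22(185)/E23(152)`, whose lengths always sum to the product
length.

## Homology search and copy pairing

`local_search()` is a k-mer seeded (word size 11, sampled every 4th query
position), diagonal-banded, affine-gap local aligner (Rcpp) under the
fixed scoring match +1 / mismatch −2 / gap open −5 / gap extend −2. The
scoring is fixed so that "correct" is well defined: the tests compare
the best hit against an exhaustive Smith–Waterman under the same scoring
computed by an independent implementation. Seeds whose diagonals differ
by more than ~20 form separate clusters; each cluster is aligned within
its own band, so a copy interrupted by a large insertion or deletion
yields two co-linear hits which `chain_hits()` reassembles into one
region. Small indels (≲20 bp) stay inside one band and are bridged by
the aligner directly. Both routes report the same, correct subject-side
span.

Two definitions matter downstream:

* **Second-copy length** is the *subject-side span* of the (chained)
  region, indel-inclusive — genomic copy lengths are what differ between
  gametologs, not alignment column counts.
* **Query cover** is *span* coverage, `(qend − qstart + 1)/qlen`. A copy
  with a large interior deletion covers the query end to end and is a
  complete (shorter) copy; only an end-truncated copy — e.g. a fragment
  matching query positions 398–923 of a 923 bp product at a scaffold
  edge — has low span cover and is flagged `partial` (threshold 0.90).
  Partial copies are excluded from ΔL rather than extrapolated: an
  incomplete longer copy must not masquerade as a shorter variant.

`pair_copies()` takes the best non-Z region by `identity × query_cover`,
preferring a W-labelled subject over a scaffold on ties (the
sex-chromosome reading is the parsimonious one), and computes
ΔL = |len(Z) − len(second)| with a direction flag. Role labels (Z / W /
scaffold) come from a sidecar map, never from sequence headers, and the
package carries the label without asserting chromosomal identity — for
these markers, whether a scaffold copy is a misassembled W fragment or a
translocation is genuinely unresolved.

## Gel model

Band migration follows the classic log-linear mobility law

\[ d = t \cdot V \cdot \exp\big(\alpha(g) - \beta(g)\,\ln L\big) \]

with run time *t* (minutes), voltage gradient *V* (5 V/cm default),
fragment length *L* (bp) and per-gel-percentage calibration
(α, β). The shipped calibration — β = (0.6, 1.0, 2.0) for 1/2/3% gels,
with α set by reference distances 1000 bp → 50 mm (1%), 500 bp → 45 mm
(2%), 300 bp → 55 mm (3%) at 60 min — was fit once to the qualitative
contrasts the method must reproduce (an 11 bp difference near 370 bp
unresolvable below 3%; 43 bp near 500 bp resolvable at 2% after an hour
but not after 10 minutes; 413 bp at ~900/500 bp resolvable at 1% within
10 minutes) and frozen as package defaults.

Two bands are **separated** when their distances differ by at least
2×`band_sigma` (band half-width, 1 mm default); a positive but smaller
difference is **indistinct** — the one-fat-band phenomenon that makes
~10 bp polymorphisms useless on standard gels — and equal lengths
**comigrate**. A finite `lane_length` (80 mm default) adds a fourth
state, **run_off**: the pure power law would let short fragments travel
arbitrarily far at low gel percentages, so any band past the lane end is
unscorable. Resolvability is monotone in time and in ΔL *within the
on-gel regime*; with `lane_length = Inf` the pure law (and global
monotonicity) is recovered. The model is deliberately free of reptation
physics, intensity and diffusion: it is a decision aid for "which gel
percentage, how long", not a simulator.

## Verdicts and sex calls

`evaluate_marker()` maps each copy-pair report to exactly one verdict:
`not_found` (no Z product), `z_only` (no second copy), `partial_copy_only`
(second copy truncated, ΔL untrustworthy), `unresolvable_polymorphism`
(ΔL zero or below gel resolution), `informative` (at the smallest
resolving gel percentage), or `confounded` (a known nonspecific product
lands in the diagnostic band window). `sex_call()` applies the two-band
female / one-band male rule with one deliberate asymmetry: a single band
is called *male only under an informative verdict*. Under any other
verdict a single band also arises from dropped-out markers or degraded
DNA, so the call is `indeterminate` — the design goal is that the caller
is never confidently wrong, only silent. `recommend_panel()` ranks
informative markers by (lowest gel percentage, largest ΔL, fewest
caveats) with a deterministic tie-break.

## The synthetic generator and what passing tests mean

`simulate_zw()` builds a Z sequence carrying one or more multi-exon genes
with planted primer footprints, and W/scaffold sequences carrying copies
of each marker region with (i) substitutions at the configured gametolog
divergence (default 0.05; published gametolog identities for these
markers run roughly 0.75–0.99), (ii) one mid-intron indel of the
configured signed size ΔL, and (iii) optionally a different realization
of degenerate primer positions on each gametolog, an end-truncated copy,
a translocated decoy copy, or planted nonspecific products. Background
sequence is i.i.d. uniform ACGT and the whole build is rejection-checked:
if any primer has an unplanned site at the scanning tolerance anywhere,
the build is redrawn. Planted truth is therefore unique by construction.
Two generator conventions guarantee *exact* recovery rather than
approximate: introns get `GT..AG` termini with junction uniqueness
enforced (the first intron base differs from the next exon's first base,
the last intron base from the previous exon's last base — so the spliced
mapper's boundary placement is unambiguous), and substitutions avoid
primer footprints, region ends, and the indel's immediate neighbourhood
(each failure mode is exercised by its own switch, not by accident).

The random stream is partitioned per output sequence, so adding a
scaffold does not perturb Z/W content at a fixed seed, and identical
configurations are byte-identical.

What the generator does *not* emulate: real base composition and repeat
content (uniform background has no transposable elements, whose role in
these introns is an open question), sequencing error, assembly gaps
beyond explicit `N` handling, and cross-species primer-site drift beyond
the mismatch knobs. Passing the recovery suite therefore shows the
pipeline is correct *given its assumptions*, not that those assumptions
hold for any particular genome.

The packaged reference landscape (`turaco_reference_fixture()`) is a
deterministic synthetic stand-in engineered so the full pipeline
reproduces the marker geometry reported for the published turaco
assemblies: amplicon lengths 367/258/2997/504/464/923 bp with their
printed exon/intron compositions and per-primer positions, second-copy
lengths 378/269/623/461/421/510 bp (ΔL 11/11/2374/43/43/413, Z shorter
only for the intron-22 markers), an equal-copy bundle (ΔL 0) and an
end-truncated copy (query cover 526/923). One engineering detail: the
published positions place the two intron-22 upstream primers on
overlapping, sequence-incompatible footprints, so no single sequence can
carry exact sites for both pairs; the fixture ships two Z-region
variants, each exact for one pair, with matching transcripts. The
SPIN-derived marker is absent from the fixture on purpose, reproducing
its unlocatable status.

## Numerical and scale choices

* Scanning: mismatch counting is bit-mask based and exact; ties and
  orderings everywhere are deterministic (position, then length, then
  lexical ids).
* Alignment: band margin 25 around seed-cluster diagonals; gap cost of a
  length-g gap is 5 + 2g (first gap base pays open + extend), matching
  the convention of the independent oracle used in tests.
* Problem sizes: the reference landscape is ~170 kb across eight
  sequences; the validation study runs 100 random genomes of roughly
  2–10 kb. These sizes make every stage exactly checkable while keeping
  the full suite in minutes; nothing in the method is size-limited
  beyond memory for the alignment traceback.
* Genome-scale questions (chromosome gene-content maps, real-assembly
  placements) require the actual assemblies and are out of scope here;
  the homology-search functions accept arbitrary FASTA, so such runs are
  possible but never required by the tests.

## Known limitations

* The spliced mapper assumes co-linear, plus- or minus-strand genes with
  unique anchor-length exon content; paralog-rich or repeat-heavy loci
  can trigger its ambiguity error (by design, rather than guessing).
* Primer thermodynamics (melting temperature, dimers, hairpins) are not
  modelled; a predicted binding site is a sequence-level statement only.
* The gel calibration is qualitative. It reproduces the decision-relevant
  contrasts above; it is not fit to densitometry and should not be read
  as predicting absolute migration distances.
* Nonspecific products enter the evaluation only as configured or
  planted lengths; the package does not predict them from sequence.
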