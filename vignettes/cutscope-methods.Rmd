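---
title: "cutscope: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cutscope: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutscope)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the choices made where the design was genuinely open.
Every coordinate in the package is 1-based (the R/Bioconductor
convention).

## The digenome cut-site model

In vitro digestion of purified genomic DNA by a Cas9/gRNA complex converts
cleavage sites into fragment boundaries. After shearing, library
preparation, and sequencing, a cleaved position is visible as a pile-up of
read 5′ ends on both strands: forward reads begin at the right fragment's
first base, and reverse reads end (their 5′ end) at the left fragment's
last base. Background fragmentation spreads read starts approximately
uniformly, so genuine cut sites are distinguished by the *fraction* of
covering reads that start exactly at the site.

The detector computes, per strand, read-start counts `S` and coverage `D`
at every position, then applies two filters: `S >= min_starts` (default 5)
and `S / D >= min_frac` (default 0.25), both inclusive, each strand
against its own coverage. The strand-specific reading of the 25% rule is
deliberate: in the source tables every per-strand percentage equals
`100 * S / D` of its own strand.

Filtered plus- and minus-strand starts are joined with a one-base
tolerance. For a plus start `p` and minus start `m`, the gap is
`g = p - m - 1`:

* `g = 0` — blunt cut (the canonical Cas9 product);
* `g = +1` — 1-bp gap: one base is covered by neither fragment, as arises
  from end polishing during library preparation or staggered cleavage;
* `g = -1` — 1-bp overhang: one base covered by both fragments.

The gap sign convention and the minus-strand read-start convention
(rightmost aligned base) are pinned here and used identically by the
simulator and the detector; they are what make a blunt cut satisfy
`p = m + 1`.

Each joined candidate is scored
`100 * (S_plus + S_minus) / (D_plus + D_minus)` and reported when the
score strictly exceeds `score_threshold` (default 60). The score formula
is a reconstruction: the source material prints per-strand counts, depths
and a combined total but not the formula itself. The reconstruction
reproduces every combined total we checked (all candidate tables, treated
and control), which is strong but indirect evidence; it is recorded here
as an inference, not a quotation. One locus can legitimately yield several
gap configurations (e.g. a blunt and a gap reading of the same pile-up);
all passing configurations are reported, best score first, with
`(contig, start, gap)` lexicographic tie-breaking for determinism.

Secondary alignments are excluded by default when reading SAM/BAM. The
source experiment mapped with up to 20 reported placements per read;
counting those placements would double-count evidence, so inclusion is an
explicit escape hatch (`detector_config(count_secondary = TRUE)`).

## Guide homology and context

A candidate's homology to the guide is measured over the full
guide-plus-PAM length — 22 positions for a 19-nt protospacer — by
position-wise matching. The denominator is always 22, making identities
multiples of 100/22 (81.8 = 18/22, 77.3 = 17/22, 72.7 = 16/22), which is
exactly the granularity of the published identity column. At most one gap
character is allowed in the candidate (the published sequences contain at
most one); the gap consumes a column and counts as a mismatch. For the
published gapped rows, printed identities differ by one match from
straightforward counting under any single alignment convention we tried;
the convention above is pinned and the discrepancy recorded rather than
reverse-engineered row by row.

The scan enumerates every ungapped offset and every single-gap placement
on both strands in a window of ±25 bp around the reported cut point
(generous, since the cut sits 3 bp inside the protospacer). Ties prefer a
PAM-bearing hit, then the leftmost, then the plus strand. A candidate is
"with homology" when the best hit reaches 70% identity *and* carries an
NGG PAM; NAG is not accepted by default. The 70% default is the lowest
value that admits every published with-homology row (the weakest prints
72.7).

Genomic context labels follow the priority coding > intron > antisense >
intergenic when features overlap; positions with no overlapping feature
are "Intergenic", and a missing annotation yields "unknown" rather than a
guess.

## Amplicon indel quantification

Reads are dropped when their median per-base Phred quality is at or below
5 (the published rule; the median of an even-length list is the mean of
the two central order statistics). Retained reads are aligned globally to
the expected amplicon under match +1, mismatch −2, gap open −6, gap extend
−1 (a gap of length L costs `6 + (L - 1)`). Any affine scheme that keeps a
near-identical 155-bp read globally alignable would do; one must be pinned
for reproducibility, and the alignment engine is cross-checked against an
independent quadratic dynamic-programming oracle in the test suite.
Identical read sequences are aligned once and weighted by multiplicity,
which keeps 90,000-read samples fast without changing any result.

Indels are left-aligned within homopolymers to a canonical placement.
This matters for the headline metric: an adenine inserted "between the A
and T" of `...GACGCC-ATG...` is equivalent, after left-shifting, to an A
inserted before the codon's A. A 1-bp insertion is therefore counted as
"in the start codon (between A and T)" when its placement-equivalence
interval — leftmost to rightmost homopolymer shift — contains the
insertion point immediately after the codon's A. For 1-bp insertions the
inserted base is invariant under these shifts, so the A:T:G:C composition
is well defined.

Classification looks only at events inside ±10 bp of the codon: the
amplicon contains no other expected edit, and a window must be pinned
because the source does not state one. Reads whose alignment does not
cover the whole window are discarded as "truncated". A read with only
insertions in the window is an insertion; only deletions, a deletion;
both, the type with the larger total event length, ties going to
insertion (a pinned decision, not an inference about the original
analysis). Percentages are over total retained reads, reported to 0.1%,
and conserve exactly at the count level: `no change + indel = total`,
`insertion + deletion = indel`.

The Kozak assessment reconstructs the edited sequence, looks for an ATG
whose A lies within two bases of the original codon position, and reports
the base three positions upstream (−3 with the A as +1). A or G there is
the favourable context; an adenine insertion into the codon creates a
cryptic ATG whose −3 base is C, predicting reduced translation — the
mechanism that makes single-A insertions phenotypically silent-positive
knockdowns.

## Cell-number normalisation

Indel rates measured on dissected tissue underestimate editing in the
target cell layer when contaminating cells contribute gDNA. The model
infers total cells from purified gDNA mass and scales the raw rate by
inferred over expected cells:

* expected endothelial population: 2300 cells/mm² × π·(1 mm)² ≈ 7225.7
  (the source's "approximately 7200" is its own rounding);
* per-cell diploid genome mass: 5.46×10⁹ bp × 660 g/mol / 6.022×10²³
  = 5.984 pg by the formula. The package default is 5.988 pg — the unique
  constant that reproduces all four published cell-number cells exactly —
  with the formula value available via `formula_per_cell_mass_pg()`.
  The published *normalised* column is reproduced exactly by the formula
  constant and to within 0.1 percentage points by the pinned constant;
  both paths are exercised in the tests.

The normalised rate may exceed 100% when inferred cells far outnumber the
expected population; that is a property of the estimator, not an error.

## Restriction-digest screen

CviAII and Hin1II both recognise 5′-CATG-3′; the source treats them
interchangeably, and both are modelled as CATG cutters cutting after the
C (C^ATG), with the offset configurable per enzyme should a different
convention be needed. `digest_fragments()` honours overlapping motif
occurrences and always conserves total length.
`indel_band_prediction()` reports which reference cut sites are destroyed
in an edited sequence and the resulting bands as merged *reference*
fragment lengths: destroying the start-codon site of a 560-bp amplicon
with fragments 303/131/126 predicts a 434-bp merged band (the physical
band additionally shifts by the net indel size, matching the observed
"~430 bp"). Destruction is decided by matching edited cut coordinates to
reference cut coordinates within the slack allowed by the net length
difference — adequate for amplicon-scale edits, not for rearrangements.

## The synthetic-data generator

The generator stands in for two sequencing experiments:

* **Digestion read sets.** Background fragmentation is lognormal
  (`meanlog = log(350)`, `sdlog = 0.35` — a heavy-ish unimodal law
  standing in for physical shearing; the exact law is immaterial to the
  detector). Coverage defaults to 30× (the depth of the source's
  whole-genome run) with 100-bp reads. Each fragment emits one forward and
  one reverse read sharing a name, mirroring a paired-end library whose
  mates the detector treats independently. At a cut site with efficiency
  `e`, that fraction of spanning fragments is split with the requested
  blunt/gap/overhang geometry. The in-vitro digestion efficiency at a
  target site is not stated in the source and is exposed as a free
  parameter rather than fixed. Alignments are emitted directly with their
  true coordinates: read mapping is out of scope, so mapper artefacts
  (mismapping, clipping, multi-placement) are *not* modelled.
* **Amplicon read sets.** Reads are full copies of the edited amplicon
  with per-base qualities drawn from a normal model (default mean 30,
  sd 3, clipped to [2, 40], Phred+33), emulating a MiSeq amplicon library.
  The event spectrum used in tests mirrors the study's observed mix
  (~84% of edits insertions, ~99% of insertions 1 bp, A:T:G:C near
  48.7:44.6:1.8:4.9, deletions dominated by 2 bp).

Not modelled: base-calling errors in the sequence (qualities are the only
noise), adapter contamination, PCR duplicates, chimeric reads. A green
end-to-end test therefore establishes that the *computational* pipeline
recovers planted truth through the standard file formats — not that it is
robust to mapper or chemistry artefacts, which enter upstream of this
package's contract.

Determinism: every generator takes a seed and restores the caller's RNG
state; identical seeds give byte-identical outputs, which the pipeline
manifests record.

## Numerical and degenerate-input choices

* Percentages are reported to 0.1 (tables) or 0.01 (candidate scores),
  matching the precision of the published tables; comparisons in tests are
  exact at that precision.
* `digenome_score` requires positive combined depth; zero-depth positions
  are never scored because they cannot pass the start filter.
* Candidate ranking ties break lexicographically by (contig, start, gap).
* `filter_start_positions` treats both thresholds inclusively (S = 5 of
  D = 20 is kept); candidate calling is strict (score exactly 60 is
  excluded) — both follow the wording of the filtering rules.
* An empty indel spectrum is valid (all reads unedited); an empty
  composition is reported as absent rather than 0/0; zero retained reads
  is an error naming the discard reasons.
* Terminal restriction cuts that would create empty fragments are no-ops.

## Known limitations

* The digenome detector assumes coordinate-sorted single-end-style records
  and does not mark duplicates; statistical significance of scores is out
  of scope (a plain threshold is used, as published).
* The homology scan allows at most one gap; two-gap off-targets would be
  under-scored.
* `indel_band_prediction`'s site matching assumes the edited sequence is
  the reference plus small local indels.
* The generator's truth sidecars list event identity per read (amplicon)
  and cut geometry per site (digestion); they do not record per-fragment
  provenance.
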