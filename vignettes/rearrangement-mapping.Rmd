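---
title: "Mapping and classifying large genomic rearrangements with rearrangemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and classifying large genomic rearrangements with rearrangemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rearrangemap)
```

## The problem

Large genomic rearrangements (LGRs) — multi-exon deletions and duplications —
account for a substantial share of pathogenic germline variation in the
mismatch-repair gene *MSH2* in Lynch syndrome, yet routine screening with
MLPA only brackets an event between probes. Molecular characterization
requires localizing the breakpoints (array-CGH or sequencing of a junction
amplicon), resolving the junction at base resolution, and reading the
mutational mechanism off its architecture: substantial microhomology between
two same-orientation Alu elements points to nonallelic homologous
recombination (NAHR), whereas blunt joins or short untemplated insertions
point to nonhomologous end-joining (NHEJ). `rearrangemap` implements that
workflow end to end as testable code, together with a synthetic-data module
that generates repeat-dense loci, rearranged alleles with known truth,
amplicon reads, MLPA/aCGH tables and carrier cohorts, so every stage can be
validated without downloading the human reference.

## Dosage screening

### MLPA

MLPA reports one amplification-peak area per probe. `normalize_mlpa()`
computes, per reaction, each sample's probe areas relative to its summed
reference-probe area, then divides by the batch median of that quantity.
The expected ratio is copy number / 2: ≈0.5 for a heterozygous deletion,
1.0 for two copies, ≈1.5 for a duplication. Two design points deserve
emphasis:

* **Reference-probe normalization.** Normalizing by the sum over *all*
  probes would make every other probe's ratio drift when one exon is
  deleted (the sample total shrinks). Dividing by always-diploid reference
  probes — mirroring the control probes of commercial kits — keeps the
  dosage arithmetic exact: in a noise-free simulation, copy number *c*
  yields ratio *c*/2 exactly, which the tests assert.
* **Batch median as reference.** The median across batch samples is robust
  to a single aberrant sample, but a batch in which *every* sample carries
  the same deletion self-normalizes to 1.0. This blind spot is inherent to
  cohort-internal normalization and is asserted as a documented property.

`call_dosage()` applies the screening thresholds: ratio < 0.7 is a
deletion, > 1.2 a duplication, with **strict** inequalities (values exactly
at a threshold call normal; the protocol wording does not state
inclusivity, so the conservative reading was chosen). An aberration is
*confirmed* only when two independent reactions agree on the same
non-normal state; a threshold-straddling pair is reported normal with a
discordance flag. The simulator runs two reactions per sample accordingly
(the replicate count beyond "a second independent reaction" is not
specified anywhere; two is assumed). `segment_exon_calls()` collapses
confirmed calls into maximal same-state exon runs ("E11-16 del").

Noise model: lognormal per-peak scatter (`area × exp(N(0, σ))`, default
σ = 0.05) on top of per-probe efficiencies and per-reaction loading
factors — the simplest model producing the qualitative behavior of peak
tables, including scale invariance of the dosage quotient.

### Array-CGH

Probe log2 ratios sit near 0, −1 and log2(3/2) for two, one and three
copies, with Gaussian noise (default σ = 0.1, i.e. a well-behaved
hybridization). The vendor's proprietary aberration statistic (ADM-2) is
replaced by a documented threshold-and-merge segmentation:

1. estimate the noise SD robustly from **first differences of adjacent
   probes** (`mad(diff(x))/√2`) — unlike the plain MAD of the ratios this
   is not inflated by the aberrant segments themselves;
2. flag probes with |log2| above `z_threshold` (default 4) times that SD;
3. merge consecutive same-sign flagged probes, bridging up to
   `gap_tolerance = 2` unflagged probes;
4. apply the consecutive-probe filter: segments with fewer than 10 flagged
   probes inside the densely covered gene regions (5 elsewhere) are
   discarded. Counting *flagged* probes means a lone noise outlier bridged
   onto a run cannot rescue a sub-threshold segment.

The probe minima are operative filters taken as stated; everything else in
the segmentation is this package's replacement design and is validated by
simulation (boundary recovery within ±1 probe in ≥95% of noisy
replicates).

## Breakpoint mapping from reads

The mapper emulates the junction-amplicon strategy: long reads (defaults:
400 bp, 30×, substitution errors only) are aligned to the locus and
*chimeric* reads — those matching two discrete reference regions — define
candidate junctions.

`split_align()` anchors the read prefix and suffix independently with
terminal k-mer seeds (k = `min_anchor` = 20; exact hash lookup, single
mismatch variants only when the exact lookup fails) and extends each
anchor while the cumulative mismatch rate stays within
`max_mismatch_rate` (default 0.05). Two refinements beyond plain
extension matter in practice:

* **Joint cut-point search.** At an Alu–Alu junction the prefix extension
  does not stop at the breakpoint: the read continues into the partner
  element, which the reference locally resembles at ~2× the element
  divergence, well within a 5% budget. The exact junction is therefore
  chosen by minimizing total mismatches over *all* pairs of cut points,
  with an affine penalty (0.5 opening + 0.5 per base) on unaligned middle
  bases. The penalty stops junction-adjacent read errors from being
  hidden inside a spurious "insertion" while still preferring a genuine
  untemplated insertion over forcing its bases onto the flanks.
* **Contained-versus-chimeric model comparison.** A read spanning a
  repeat-mediated junction is often alignable end-to-end at an elevated
  mismatch rate, so containment alone is not decisive: the chimeric
  interpretation is accepted only when it removes at least two mismatches
  relative to the best full-length placement.

A junction is reported when both anchors hold ≥ `min_anchor` bases and the
two segments are separated by more than `min_sv_distance` (100 bp), or the
suffix maps upstream of the prefix (the head-to-tail tandem-duplication
signature). Ambiguous anchors — several placements with equally long
extensions — reject the read rather than assigning it silently.

Every reported per-read junction is immediately **leftmost-normalized**
against the reference (see below), so reads cut anywhere inside a
microhomology stretch report identical coordinates; `cluster_chimeras()`
then single-links `(bp5, bp3)` pairs within `tol` = 10 bp and discards
clusters below `min_support` = 3 reads. These three knobs are not stated
anywhere for the original ~20,000-read amplicons; the defaults are chosen
for desk-scale simulated depth and are exposed as arguments.
`reconstruct_junction()` stacks member reads in the suffix-diagonal frame
(invariant to per-read cut ambiguity) and majority-votes a consensus over
±150 bp around the join.

## Junction resolution and normalization

`resolve_junction()` re-anchors the error-corrected consensus with *exact*
matching: the maximal exact extension of its head gives the rightmost
admissible 5′ breakpoint, the maximal exact backward extension of its tail
the leftmost admissible 3′ breakpoint. Overlap between the two is the
junction **microhomology**; a gap is an untemplated insertion.

`compute_microhomology()` defines the microhomology length as the longest
common suffix of the sequences ending at the two joins plus the longest
common prefix of the sequences starting after them — equivalently, the
number of alternative junction placements reconstructing the identical
allele. A brute-force oracle that tries every junction shift validates
this equivalence on a thousand random breakpoint pairs.

Because a junction inside shared sequence has no unique coordinate, the
package defines one **canonical form** used by the simulator's truth
records, the per-read aligner and the annotator alike: first, inserted
bases templated from the adjacent reference are absorbed into the flanks
(the representation with the minimal untemplated insertion); then a
residual blunt junction is shifted to its leftmost admissible position.
Absorption matters for duplications — an insertion whose tail happens to
repeat the interval end admits representations with different interval
sizes, and only minimal-insertion normalization makes truth recovery
well defined. Coordinates are 1-based inclusive throughout; BED
conversion happens only at I/O.

## Mechanism classification

`classify_mechanism()` encodes the rule used to read Table-3-style
junction features:

* **NAHR** requires microhomology ≥ `min_homology` (default 10 bp — the
  observed NAHR junctions at this locus carry 15–48 bp) *and* both
  breakpoints inside same-orientation repeat elements of the same
  superfamily (AluY × AluSp qualifies; Alu subfamilies recombine freely).
* **NHEJ** is called for microhomology below `short_homology_cap`
  (default 5 bp) regardless of repeat context — a breakpoint *inside* an
  Alu is explicitly not a proxy for NAHR.
* Everything else (intermediate homology, or homology without qualifying
  repeats) stays `unclassified` rather than being forced.

Pathogenicity flagging is rule-based metadata only: events overlapping an
annotated exon are flagged as transcript-disrupting, purely intronic
events are not (their significance rests on co-occurrence, as with the
intron-10 deletion carried on the same allele as a pathogenic
duplication). No clinical classifier is implemented.

## Nomenclature

`format_nomenclature()` returns both the compact clinical dialect
(`g.47654696-47659152del4457`; bracketed insertion-plus-copy allele
strings for duplications, with the second insertion coordinate shortened
to its differing digits) and plain HGVS-style descriptions
(`g.x_ydel`, `g.[p_p+1insSEQ;x_ydup]`). Unresolved breakpoints raise an
error directing the caller to bounded MLPA-style notation
(`c.212-?_366+?del`). Sizes are `end − start + 1`, validated against all
five printed deletion designations.

## Cohort statistics

`lgr_frequencies()` recomputes pathogenic-LGR fractions (of screened
families, of locus alterations, per Amsterdam criteria class) as
percentages rounded half-up to one decimal. `phenotype_table()` is pure
counting over an individual-level cohort; tumor frequencies are reported
as floor-rounded integer percentages because that is the only rounding
consistent with the printed 55%/11%/42% given the printed counts
(15/27, 3/27, 45/107). `cohort_from_counts()` reconstructs an
individual-level cohort exactly matching published margin counts so the
table is recomputed, not transcribed.

The published table names no statistical test. Continuity-corrected
chi-square reproduces the printed affected/healthy P = 0.547 (and the
endometrial-cancer P = 0.936) on the printed counts, so it is the primary
method; the uncorrected chi-square and Fisher's exact test are always
reported alongside. Notably the printed colorectal-cancer P = 0.278
matches Fisher's exact (0.279) rather than either chi-square variant —
the original analysis apparently mixed tests — so the package reports all
three and does not force agreement. When any expected cell count falls
below 1, only Fisher's exact test is reported, with a note. Ages are
compared by an equal-variance two-sample t-test.

## What the synthetic world does and does not establish

The generators emulate: a repeat-dense locus (fixed ~300 bp Alu-like
consensus, per-base divergence ≤ 0.3, random strand, exact annotations);
NAHR deletions through an identical stretch forced into two
same-orientation elements (so planted microhomology is recovered exactly,
10–60 bp); blunt and insertion-bearing NHEJ deletions with flanks edited
to share no identity; head-to-tail duplications with untemplated
insertions; uniform-start reads with uniform substitution errors; and
Bernoulli tumor histories. They do **not** emulate: real 454 homopolymer
indel errors (the aligner is substitution-only — a documented limitation),
the true Alu subfamily structure or density of the real locus (whose
47%-repeat content and printed 24/48/15 bp microhomologies would require
the human reference), pedigree structure, or ascertainment. A green test
therefore establishes algorithmic correctness on the stated synthetic
world, not concordance with the original wet-lab measurements.

Simulation defaults are the stated study conditions where given (400 bp
reads; dosage thresholds 0.7/1.2; probe filters 10/5; cohort margins) and
field-typical values elsewhere (30× desk-scale depth, 1% substitution
error, lognormal MLPA σ = 0.05, Gaussian aCGH σ = 0.1, 100 bp in-gene
probe spacing), fixed once and not tuned.

## Numerical choices and degenerate inputs

Ties in the consensus vote resolve deterministically (first of A,C,G,T by
count). Equal-cost cut-point pairs prefer the shorter insertion, then the
leftmost cut. Exact threshold values in dosage calling go to "normal".
Empty inputs return typed empty tables (no NULLs). All simulators are
byte-reproducible under a seed, and seeds derived inside scripts stay
below 2³¹. Noise-free aCGH input yields a zero noise estimate and exact
segmentation; a flat track returns no segments.
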