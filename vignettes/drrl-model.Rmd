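---
title: "Double replications and random loss: model, inference and design notes"
author: "mitoDRRL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double replications and random loss: model, inference and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoDRRL)
```

## The problem

Vertebrate mitochondrial genomes are circular and almost always carry the
same 37 genes (13 protein-coding genes, 22 tRNAs, 2 rRNAs) plus one control
region (CR) in a deeply conserved arrangement. Genome-scale rearrangements
are rare, and when they occur the pattern of displaced genes, duplicated
control regions and unusually long intergenic spacers preserves a record of
the mechanism that produced them. The flatfish *Samariscus latus* is an
extreme case: its mitogenome keeps the first eight genes in place, then
scatters the remaining gene complement into two clusters separated by
control regions and noncoding remnants.

`mitoDRRL` implements the *double replications and random loss* (DRRL)
model for such rearrangements, alongside the classic *tandem duplication
and random loss* (TDRL) model, as

* forward simulators that generate rearranged orders from explicit event
  parameterizations,
* an inference engine that decides whether an observed order is derivable
  from an ancestral order by one event and enumerates every explanation,
* annotation statistics that tie the model's predicted residues to the
  intergenic spacers of a real annotation table, and
* seeded synthetic-case generators with ground truth.

## The DRRL model

A DRRL event transforms a circular order in three steps.

1. **CR duplication and translocation.** The control region, which houses
   the heavy-strand replication origin (O~H~), is duplicated and one copy
   (CRI) translocated to a new insertion edge; the original (CRII) stays
   put. The mechanism of this initial duplication is left open — the
   package treats it as a primitive `duplicateTranslocate()` and does not
   commit to one.
2. **Double replication.** With two origins on one circle, a first
   replication starts at CRI's origin, passes CRII's origin before that
   origin fires, and a second replication then starts at CRII; both
   terminate back at CRI. The net product duplicates exactly the genes
   *strictly between CRI and CRII* in the replication direction and leaves
   a third control region (CRIII) at the distal end of the second copy —
   the position the original CR occupied. Genes upstream of CRI stay
   single-copy. `doubleReplication()` returns this state with both copies
   tagged.
3. **Random loss.** One copy of each duplicated gene pair is lost
   independently; the survivors of copy 1 form one cluster and the
   survivors of copy 2 a second cluster, *each preserving the ancestral
   relative order*. The three CRs follow separate fates: `functional`,
   `remnant` (a degenerated noncoding element) or `lost`.

TDRL differs in that the duplicated block is arbitrary and placed in
tandem, with no origins and no CR bookkeeping; after loss it produces the
same two-increasing-run signature but cannot explain clusters separated by
control regions and their remnants.

### The derivability criterion

Writing the duplicated block as ancestral ranks $1 \dots k$, the observed
arrangement of the block is the concatenation of the copy-1 survivors and
the copy-2 survivors, both strictly increasing. An observed arrangement is
therefore reachable by one event **iff it has at most one descent** (a
position where the next rank is smaller). With exactly one descent the
split into clusters is unique; with none, every prefix split is valid and
`explainDrrl()` reports all of them rather than collapsing the
multiplicity — the identity order, for instance, is trivially derivable at
every edge. This descent criterion is verified against an independent
exhaustive oracle (`bruteForceExplanations()`, which replays all
$\text{edges} \times 2^k$ loss assignments and all CR fate combinations)
on every ancestral order of up to six genes and on 200 seeded random cases
with blocks up to 10 genes.

### Remnant support

An explanation predicts where CRII and CRIII residues must sit: CRII
between the two survivor clusters, CRIII at the ancestral CR position.
Matching is positional — an observed element of class CR at a predicted
site implies fate `functional`, a remnant/NC element implies `remnant`, an
empty site implies `lost`. Residue *lengths* (86 bp, 376 bp in the
*S. latus* annotation) are annotation-layer data and are deliberately not
part of the order-level match. Because a published annotation may simply
not annotate a short residue, `requireRemnants` defaults to `FALSE`;
remnant support is always reported per explanation so the caller can
filter.

## The S. latus reconstruction

`reconstructSlatus()` replays the inferred six-stage chain:

```{r stages}
st <- reconstructSlatus()
vapply(st, length, integer(1))
orderIdentical(st$F, samariscusLatusOrder())
```

Stage B inserts the CR copy between `trnQ` and `trnM`; the double
replication then duplicates the 29 genes `trnM..trnP`; the loss step keeps
an 11-gene cluster from copy 1 and the remaining 18 genes (including
`trnP`) from copy 2; a final duplication translocates `CR-trnC-trnY`
between `trnL2` and `trnP`. Cluster sizes are exposed both raw (11/18
survivors per copy) and in the 11/17 + `trnP` convention, in which `trnP`
is set aside as retaining its typical position next to the CR remnant.

Two stage-F bookkeeping choices are worth stating. The CRII remnant is
reduced to an 86-bp residue in the real genome — below annotation scale —
so stage F drops that element and the residue survives only as the
`trnT`--`trnM` spacer; and the surviving CRs take their annotation names
(CR1/CR2, CRIII's remnant becoming NC). `slatusScars()` tracks, junction
by junction, how many gene copies were deleted and where remnants were
absorbed; `residueConsistency()` then checks that every annotated spacer
over 50 bp lies at such a scarred adjacency. When a later duplication
inserts a segment into a scarred junction (stage E to F), both junctions
created by the insertion inherit the scar, since the residue may end up on
either side of the inserted copy.

## Annotation arithmetic

Coordinates are 1-based and inclusive; the intergenic spacer between
consecutive features is `next.start − prev.end − 1`, negative for
overlaps, computed circularly for the wrap pair. This is the only
convention under which the packaged *S. latus* table reproduces its
printed intergenic column exactly (42 values including the six overlaps),
and under which feature sizes plus spacers tile the 18,706 bp circle. The
printed intergenic column, when present, is cross-checked against
recomputation; a mismatch warns and the recomputed value wins. The
wrap spacer is counted like any other, so the "19 intergenic regions" of
the summary are the strictly positive spacers anywhere on the circle.
Thresholds (50 bp for long spacers, 300 bp for large noncoding regions)
are parameters of `summarizeAnnotation()`, not constants.

The table records CR1 as 893 bp and CR2 as 899 bp; the two copies are
reported as annotated and never asserted equal in length.

## Conventions and numerical choices

* **Naming.** Compact labels (`trnF`, `rrnS`, ..., `CR`, `NC`) with a
  vocabulary table (`geneVocabulary()`) mapping to the one-letter figure
  names and canonical positions 1–38. `trnS1` is Ser(TGA), `trnS2`
  Ser(GCT), `trnL1` Leu(TAA), `trnL2` Leu(TAG); cross-species imports
  should map anticodons, not letters.
* **Replication direction** is fixed as the direction in which genes
  follow CRI; this is the convention that reproduces the duplicated
  layout and places CRIII (hence the NC remnant) at the typical CR
  position. The strand-level replacement narrative of the double
  replication is mechanism prose, not simulated.
* **Strands** are carried on every element and never changed by either
  model; an observed order that inverts a gene is flagged and returns no
  explanations rather than being silently accommodated.
* **Circular indexing** is 0/1-based internally per R convention and
  rendered 1-based everywhere user-facing, matching annotation
  coordinates. Circular equality is equality of canonical rotations
  (anchored at untagged `trnF` when present, else the smallest label).
* **Randomness.** Every stochastic entry point takes an explicit integer
  seed and runs under `withr::with_seed`, leaving global RNG state
  untouched; loss draws are independent fair coins per gene pair.
* **Blocks never span the original CR**: a DRRL block runs from the
  insertion point forward to CRII only, so wrap-past-CR events are
  rejected by construction.
* **Tie-breaks.** Explanations are deduplicated by (insertion edge,
  copy-1 survivor set) and sorted by edge then split. When several
  observed noncoding elements could occupy several predicted CR sites in
  one gap, they are assigned in cyclic order (leftmost first); any
  consistent assignment replays to the same order, so the identity of the
  explanation is unaffected.

## What the synthetic generator emulates — and what it does not

`randomGeneOrder(n, seed)` produces a circular order of `n` synthetic
genes plus one CR; `randomDrrlCase(n, seed)` applies a DRRL event with a
uniformly random insertion edge, fair-coin loss and the fate pattern
{functional, remnant, remnant} — the pattern of the *S. latus*
reconstruction. `syntheticAnnotation()` lays gene-class-specific feature
sizes and parameterized spacers (including overlaps) on a circle that
closes flush, so drawn spacers are exactly recovered by
`computeSpacers()`.

These generators emulate order-level structure only. They do not emulate
nucleotide sequence, sequence similarity between CR copies, tRNA
structure, codon usage, or rate heterogeneity among lineages; passing
round-trip tests on synthetic cases shows the inference engine inverts
the simulator faithfully, not that real genomes satisfy the model's
assumptions. Test problem sizes — exhaustive oracle comparison to six
genes, 200 seeded oracle cases with blocks to 10 genes, 1000 round-trip
cases — were chosen so each property is exercised across the full
combinatorial range a desk check can enumerate.

## Known limitations

* Single-event inference only: no minimum-event distance, no multi-event
  search, no phylogenetic placement, and no probabilistic choice between
  DRRL and TDRL when both fit.
* Annotation import is the TSV dialect only; GenBank flat-file feature
  tables are out of scope since no sequence-level data is consumed.
* Origin-spanning features are not supported (the packaged dataset has
  none), and repeated-segment reduction scans the canonical
  linearization, so a repeat spanning the rotation anchor would be
  missed.
* Inversions, recombination, non-random loss and miss-priming mechanisms
  are documented contrasts, not implemented models.
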