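# mitoDRRL

Rearrangement models for vertebrate mitochondrial gene orders, built around
the **double replications and random loss (DRRL)** mechanism, with the
genome-scale rearrangement of the flatfish *Samariscus latus* as the worked
reference case.

Vertebrate mitogenomes are circular, carry 37 genes plus one control region
(CR), and almost never change their gene order. When they do, the pattern
of displaced genes, duplicated CRs and long intergenic spacers records the
mechanism. Under DRRL, a duplicated-and-translocated CR puts two
heavy-strand replication origins on one circle; two successive replications
launched from them duplicate exactly the genes between the two CRs and
leave a third CR at the original's position; random loss of one copy of
each duplicated gene then yields two gene clusters that each preserve the
ancestral relative order, separated by CRs and their degenerated remnants.

Writing the duplicated block as ancestral ranks 1..k, an observed order is
reachable by **one** event iff the block's observed arrangement has at most
one *descent* (a position where the next rank is smaller); the descent
splits the block into the copy-1 and copy-2 survivor clusters. The package
provides this inference (`explainDrrl()`, with an exhaustive
`bruteForceExplanations()` oracle), forward simulators
(`duplicateTranslocate()`, `doubleReplication()`, `randomLoss()`,
`simulateDrrl()`, `simulateTdrl()`), circular annotation statistics
(`computeSpacers()`, `summarizeAnnotation()`), seeded synthetic-case
generators, and the packaged *S. latus* annotation with its six-stage
reconstruction (`reconstructSlatus()`).

This is for researchers in mitochondrial genomics and molecular evolution
who want to test whether an observed gene order is one-step derivable
under duplication-and-random-loss mechanisms, and to reproduce the
*S. latus* analysis end to end.

## Worked example

Genome organization of the packaged *S. latus* annotation (42 features on
an 18,706 bp circle):

```r
library(mitoDRRL)
summarizeAnnotation(slatusAnnotation())
#> Mitogenome annotation summary
#>   genome length: 18706 bp
#>   features: tRNA=24 rRNA=2 CDS=13 CR=2 NC=1 (H=31, L=11)
#>   intergenic spacers: 19 positive, 9 over 50 bp, 6 overlaps
#>   noncoding regions over 300 bp: CR1, CR2, NC
```

The 19 strictly positive spacers, the 9 over 50 bp and the 6 overlaps are
recomputed from coordinates (`next.start − prev.end − 1`, circularly); the
recomputation reproduces the table's printed intergenic column exactly.

Inferring the rearrangement: replay the reconstruction to the
post-loss intermediate and ask for the one-step DRRL explanations from the
canonical vertebrate order that are supported by observed remnants:

```r
stageE <- reconstructSlatus()$E
ex <- explainDrrl(canonicalVertebrateOrder(), stageE, requireRemnants = TRUE)
ex[[1]]
#> DRRL explanation (split 11, remnant support: yes)
#>   insertion edge: trnQ | trnM
#>   clusters: [trnC trnY trnS1 trnK trnR trnS2 ND5 ND6 trnE CYTB trnT] | [trnM ND2 trnW trnA trnN COI trnD COII ATP8 ATP6 COIII trnG ND3 ND4L ND4 trnH trnL2 trnP]
```

There is exactly one such explanation: the CR copy was inserted between
`trnQ` and `trnM`, the 29 genes `trnM..trnP` were duplicated, and the loss
step kept an 11-gene cluster from the first copy and the remaining 18
genes (17 plus `trnP`, which stays at its typical position next to the CR
remnant) from the second. Of the two ways to strip the recent
`CR-trnC-trnY` duplication from the observed order
(`reduceRecentDuplications()`), exactly one is one-step derivable — the
asymmetry that identifies which copy is the translocated one.

A command-line front end wraps the same functions:

```sh
exec/mitodrrl annstats inst/extdata/slatus_mitogenome_annotation.tsv --json
exec/mitodrrl demo slatus
exec/mitodrrl explain --ancestral anc.txt --observed obs.txt --json
```

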