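---
title: "Methods: typing homeobox duplicates after a whole-genome duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: typing homeobox duplicates after a whole-genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxwgd)
```

## The inference problem

A single ancestral whole-genome duplication (WGD) leaves a clade with
three kinds of gene duplicates: ohnologues created by the WGD, tandem
duplicates that predate it, and tandem duplicates that postdate it.
Telling these apart requires combining two signals: *when* a duplication
node falls on the species tree (gene-tree/species-tree reconciliation) and
*where* the copies sit in the genome (chromosomal linkage). `hoxwgd`
formalizes that decision for homeobox-scale families — tens to hundreds of
families, each with a handful of copies per genome — and ships a forward
simulator so the whole chain can be validated by event recovery.

## Coordinates, strands, trees

Gene coordinates are 0-based, half-open; GFF3 input (1-based, inclusive)
is converted at the boundary, so `end - start` is always the gene length
and intergenic distance is `downstream.start - upstream.end`. Strands must
be `+` or `-` (`.` is rejected) because the cluster orientation score is
meaningless without a defined strand. The species tree is rooted, may
contain polytomies, and carries exactly one WGD-marked branch (a node
label containing `WGD` at the branch's child end). Gene trees are rooted
and strictly binary with `species|gene` leaf labels; they are *inputs*
(or simulator truth), never inferred here.

## Reconciliation and category rules

Each gene-tree node maps to the LCA of its leaves' species; a node is a
duplication iff it maps to the same species-tree node as one of its
children. A duplication mapping to the node directly under the WGD branch
("crown") is WGD-compatible; one mapping strictly above is pre-WGD; any
other is post-WGD/outgroup. Two refinements close gaps that pure LCA
mapping leaves open:

* **Nested crown duplications.** An ancient tandem duplication whose both
  copies were re-duplicated by the WGD produces two crown-mapped
  duplication nodes *below* another crown-mapped node. Only one WGD
  exists, so a crown-mapped duplication with crown-mapped duplications in
  both children must predate it and is classified pre-WGD; a crown-mapped
  duplication below an already-designated WGD node is post-WGD.
* **Observational category definitions.** Ohnologue-pair categories are
  defined on the surviving presence pattern, identically in the truth
  labeller and the classifier. A stem loss (SOL: absent from all spiders,
  retained elsewhere in the WGD clade; EOL: absent from all entelegynes,
  retained in a non-entelegyne spider) is only called when the duplication
  is still visible — the LCA of the combined presence must coincide with
  the LCA of one lineage. A pair eroded reciprocally (each lineage lost
  where the other survives) is indistinguishable from a single-copy family
  and is SC; a pair whose combined span has shrunk below the crown is
  indistinguishable from a post-WGD dispersed duplication and is RT. This
  mirrors how such categories are assigned from real genomes, where only
  the surviving pattern is observable.

Each family receives one category with the fixed precedence
AT > O > SOL > EOL > RT > SC (real heatmaps use compound labels for
families that are both ancient tandems and ohnologue-bearing; a single
label forces a choice, and the ancient duplication is the rarer, more
informative signal). Linkage — clustered within 10 intervening genes and
1 Mb, linked on one chromosome, dispersed otherwise — is evaluated per
duplication node as one vote per species carrying both copies, with a 0.7
majority fraction (the field's "most genomes" has no published number);
where linkage contradicts the reconciliation the tree wins and a conflict
is recorded, because duplication timing is the primary criterion and
linkage the secondary one.

Losses are mapped by Dollo parsimony: the character is gained once, at the
WGD, and the minimum-loss placement puts one loss on every branch whose
entire subtree lacks the copy while its parent's does not. The brute-force
check enumerates all loss subsets on 6-leaf trees.

## Cluster integrity

Clusters are maximal runs of template-family genes on one chromosome in
which consecutive members are separated by at most 10 intervening genes
and 5 Mb. Non-template genes never break a run (real clusters interleave
unrelated genes); they only consume gap budget. The defaults keep
described clusters intact while splitting described "linked but not
clustered" cases separated by tens of Mb; both bounds are arguments and
are echoed in outputs. Scores:

* completeness = |template families present| / |template|;
* order = LCS(observed order or its reversal, canonical order) / number of
  members present — reversal-tolerant because a wholesale inversion
  preserves organization; a reordered 3-gene cluster (R-H-O against
  canonical H-R-O) scores 2/3;
* orientation = largest fraction of members on one strand.

Ohnologous cluster copies are paired by maximal mutual-ohnologue count;
within a pair the more intact copy (completeness, then order, then
chromosome id) gets the `intact_label` ("A" by default; conventions that
call the intact Hox copy "B" are honoured by passing `"B"`).

## Macrosynteny

Chromosome orthology is content-based: a contingency table of shared
orthogroups per chromosome pair, assigned greedily by descending count
(ties by chromosome id) with a minimum of 10 shared orthogroups; fusions
and fissions surface as 2:1/1:2 assignments. Orthogroup inference itself
is out of scope — families serve as orthogroups for simulated data, and
user tables are accepted for real data. Collinear chains are detected by
dynamic-programming chaining of orthogroup matches, monotone in both
genomes in either orientation, with positional gaps of at most 25 and a
minimum reported length of 5; chains are extracted best-first. Cluster
placement flags a relocation only when a cluster's chromosome maps to a
reference block carrying *no* cluster of that template: ohnologous blocks
share most of their content under family-level orthogroups, and per-copy
A/B labels are intactness-based per species, so comparing against either
template block avoids spurious flags from label swaps.

## dN/dS by Nei–Gojobori counting

Site counts use the synonymous fraction of *sense* single-nucleotide
changes at each codon position (changes to stops excluded from the
denominator), so each codon contributes exactly 3 sites and S + N = 3L
exactly. Codons differing at d positions are resolved by averaging the
synonymous/nonsynonymous step counts over all d! orderings whose
intermediates are sense codons; if every ordering crosses a stop (rare),
all orderings are averaged with stop steps counted as nonsynonymous and
the fallback is flagged. Proportions are Jukes–Cantor corrected
(dS = −3/4·ln(1 − 4/3·pS)); ω is reported as NA — never infinity — when
dS = 0 or a proportion saturates the correction. This counting estimator
replaces likelihood codon models deliberately: it is self-contained and
exactly testable (all 61×61 sense-codon pairs are checked against an
independent pathway enumeration), and in the low-divergence regime typical
of within-clade comparisons it agrees with ML estimates in rank and order
of magnitude, though not digit-for-digit. The neutral sanity simulations
use a transition/transversion ratio of 1: a pure neutral null isolates
the counting method from compositional bias; the ratio is a parameter.

## What the simulator emulates — and what it does not

The simulator evolves a root genome down a user tree: tandem duplication
(copy inserted adjacent, same strand), dispersed duplication (uniform
random position, random strand), gene loss, inversion (contiguous run
reversed, strands flipped), translocation (runs of up to 3 genes),
per-branch fusion/fission, one WGD duplicating every chromosome
(midpoint of the marked branch, new chromosome ids suffixed `_w`), and
codon-level sequence evolution with a transition/transversion ratio and
stop-codon suppression. Pseudogenization writes one internal stop into the
homeodomain and freezes the sequence. A single seeded random stream fixes
the output byte-for-byte; every structural event is logged, and replaying
the log from the root genome reproduces each leaf genome exactly (the
structural oracle).

Default study conditions: 200 families (29 of them in six cluster
templates of sizes 10/6/4/3/3/3, instantiated at the root as contiguous
canonical-order runs with alternating strands), 8 root chromosomes, and a
14-leaf ultrametric tree of root depth 3 with nine WGD-descendant species
and five outgroups, whose `spiders` and `entelegynes` internal-node labels
drive the stem-loss categories. Rates are free parameters fixed once at
values that produce repertoires of realistic shape: per-gene rates of
0.008 (tandem duplication), 0.001 (dispersed duplication) and 0.02
(background loss) per branch-length unit; per-genome rates of 0.5
(inversion) and 0.2 (translocation); fusion/fission probability 0.02 per
branch; codon substitution rate 0.02 per site per unit with ts/tv 2;
pseudogenization probability 0.002 per gene per branch. One deviation from
a flat-rate model was necessary: copies of families with more than one
copy in a genome are lost at an elevated rate (0.35 per gene per unit,
`redundant_loss`). This fractionation bias is what concentrates ohnologue
losses on the stems just after the WGD — with a single flat loss rate high
enough to halve the ohnologue complement, singleton families are destroyed
wholesale and no stable SC/SOL/EOL structure exists.

Coordinates live on a fixed 10 kb grid re-spaced after insertions, keeping
intergenic-distance semantics deterministic (the configured tandem offset
range is recorded but the grid governs placement). Genes created
mid-branch evolve their sequence over the whole branch. The simulator does
not emulate intron/intergenic sequence, population processes, gene
conversion, more than one WGD, or rate variation across sites and
branches. Passing recovery tests therefore shows that the inference chain
is correct *given* true gene trees and clean assemblies; it does not show
robustness to gene-tree estimation error, fragmented assemblies or
annotation noise, which dominate real-data difficulty.

## Family assignment

Similarity is ungapped identity over the 60-column homeodomain (queries of
55–65 aa are slid to their best ungapped fit); there is no affine
alignment because homeodomains are effectively fixed-length. The
assignment threshold (0.55) and the novel-family cross-similarity (0.8,
single linkage, at least two species) are configuration defaults — random
60-mers score near 0.05 against any consensus, so the threshold separates
signal from background by a wide margin. Diagnostic residues are optional
per family (absent set passes vacuously) and dominate the ranking ahead of
similarity; the simulator's generated catalogs leave them empty because no
published per-family residue sets are machine-readable, and randomly
invented ones would create spurious ranking flips. Pseudogenes keep their
best family label but are excluded from all repertoire counts.

## Problem sizes

The test suite and the acceptance script run, by choice: the 200-family
default simulation once; 1,000 random gene trees of up to 8 leaves against
the reconciliation oracle; all 63 presence patterns on a 6-leaf tree
against exhaustive Dollo minima; 500 random layouts against the
cluster-detection oracle; 200 random instances of up to 15 genes against
brute-force chaining; all 3,721 sense-codon pairs against pathway
enumeration; and 50 replicate pairs of 300 codons for each selection
regime. These sizes make every oracle comparison exact while keeping a
full run in the low minutes on one core.

## Known limitations

* LCA reconciliation undercounts duplications when losses erase one side
  of a split; the observational category rules absorb the common cases,
  but deep hidden paralogy is irrecoverable by design.
* Conflict resolution always prefers the tree over linkage; a
  systematically wrong gene tree (e.g. long-branch artefacts) will
  propagate into categories, flagged but not corrected.
* The A/B cluster labels are per-species intactness labels, not lineage
  assignments; cross-species copy identity requires the gene-level
  ohnology evidence, not the labels.
* NG86 with equal-weight counting is biased under strong
  transition/transversion or codon-usage bias; it is a screening
  statistic here, not a substitute for codon-model ML on real data.
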