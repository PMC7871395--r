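---
title: "Quantifying mitochondrial gene-order rearrangement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial gene-order rearrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgrquant)
library(dplyr)
```

## The scoring model

A mitochondrial genome is treated as a circular sequence of gene
occurrences over a closed 38-label alphabet: 13 protein-coding genes, 22
tRNAs (single amino-acid letters; `L1`/`L2` and `S1`/`S2` separate the two
leucine and serine isoacceptors), 2 rRNAs, and the control region `CR`,
which is deliberately treated as a single gene so that its relocations are
scored like any other gene's. Pseudogenes and the origin of light-strand
replication are excluded at parse time: their annotation across public
records is too inconsistent to compare, which also means arrangements that
differ only in O~L~ placement are not distinguished.

Scoring is purely local. Given a reference arrangement in which every label
occurs exactly once, each occurrence of a gene is compared with the
reference context of its label: the score is the number of its two circular
flanking neighbours that differ from the reference neighbours (0, 1 or 2).
The genome score is the plain sum over occurrences. The locality is the
point of the method — it needs no event reconstruction, no breakpoint or
inversion distance, and it handles duplications and losses without special
cases: each copy of a duplicated gene is scored independently against the
label's single reference context, and a lost gene contributes nothing
itself but surfaces through the changed flanks of its surviving
ex-neighbours.

Two worked consequences pin the arithmetic down. A tandem duplication of a
single tRNA scores 1 + 1 = 2 (the first copy's right flank and the second
copy's left flank are new) while its outer neighbours are untouched; and
the typical neobatrachian arrangement — the L2-T-P-F cluster relocated 3'
of CR — scores 10 against the typical vertebrate reference, decomposed as
S2:1, L2:2, nad5:1, cob:1, CR:2, T:1, P:1, F:1.

### Comparison mode

Neighbour comparison is directional by default (`mode = "ordered"`: left
against left, right against right), because the reading direction of a
mitogenome record is fixed by convention. A weaker `"unordered"` mode
compares the flank pair as a 2-element multiset; its score never exceeds
the ordered score, and the two agree on the anchor cases above. Since
nothing in the method's description fixes the choice, both are implemented,
the mode is a flag on every scoring function, and report headers record it.

### Rearrangement frequency and its denominator

Within a group, a gene's RF is its accumulated RS divided by the maximum
attainable, as a percentage. The maximum is 2 per *occurrence*, not 2 per
genome: duplicated genes enlarge the denominator, which keeps RF in [0,
100] for any copy structure and reduces to 2 x (number of genomes) for
single-copy genes. A gene with no occurrence in a group has RF reported
missing (`NA`), never zero — absence of evidence of rearrangement is not
conservation. RF is computed in full precision and rendered to two
decimals. Maximal circular runs (length at least 2) of RF-zero genes are
reported as conserved segments; genes with missing RF break a run.

## Patterns: canonicalization and the census

Two records of the same circular arrangement may be linearized at different
cut points, so before merging, every arrangement is rotated to a canonical
start: the first occurrence of trnF (the conventional vertebrate record
start), falling back through rrnS, cox1, nad5 when absent, and to the
lexicographically minimal rotation when all four are missing. A duplicated
start gene resolves to the occurrence giving the lexicographically minimal
tuple. These tie-breaks make canonicalization deterministic, idempotent and
rotation-invariant for arbitrary inputs, including heavily rearranged
simulated genomes.

The census groups identical canonical tuples and classifies them by count:
*major* when seen at least 3 times, *rare* otherwise (subdivided into
*double* and *single*). Major classes are ranked by descending count with
ties broken by first appearance in the input. Local arrangements come in
two flavours: projection (keep a label subset, e.g. the 13 PCGs, preserving
circular order) and anchored regions — the span strictly between two anchor
genes. The built-ins follow the rearrangement-hotspot geography of
amphibian mitogenomes: Region 1 between `nad4` and `rrnS` (the nad5-CR
neighbourhood), Region 2 between `nad1` and `cox1` (IQM-nad2-WANCY), and
Region 3, the nad5-nad6-cob cluster after PCG projection. A genome whose
anchor is missing or duplicated is excluded from that region's census with
a warning rather than guessed at. Region tuples are anchored and therefore
compared as linear tuples, not re-canonicalized. Strand is parsed and
carried through I/O but ignored in scoring and pattern identity: the
method's comparisons are order-based, and orientation-sensitive analysis
can be layered on by the user via the strand column if needed.

## Phylogenetic statistics

The clustering question — do rearranged genomes concentrate in clades? —
is operationalized as per-clade hypergeometric enrichment: for every
internal node with clade size between 2 and N-1, the upper-tail probability
of drawing at least the observed number of labelled tips when the clade is
drawn blindly from all tips, Bonferroni-corrected over the nodes tested,
summarised by the minimum adjusted p. This is the simplest construction
consistent with calling the procedure a hypergeometric test; because the
exact published construction behind such tests is rarely stated, the per-
node table is returned in full and the summary records how many tests the
correction spans. The same upper tail drives the sampling-density test
(are rare arrangements concentrated in sparsely sampled families, default
threshold: at most 2 species per family?). Tails are computed by
`stats::phyper`, which works in log space internally; the test suite checks
them against exhaustive enumeration of draws for populations up to 12.

Occurrence-time bounds take the tree and its dates as given: the age of
the most recent common ancestor of the species sharing a pattern is the
latest possible origin of that pattern, on the assumption that a shared
arrangement is inherited rather than convergent. Ages come either from
ultrametric branch lengths or from a sidecar table keyed by node label;
divergence-time estimation itself is out of scope, as is tree inference.

## The simulator

`simulate_tree_dataset()` generates datasets with the statistical structure
the analysis assumes, plus ground truth. Five event types act on the
circular order: tandem duplication; tandem duplication–random loss (the
block is duplicated in tandem, then one copy of each duplicated gene is
deleted uniformly at random — the classic mechanism for mitogenome
rearrangement, and the only one here that can reproduce the original order
as a legitimate outcome); transposition; inversion (label order only, since
comparisons are strand-agnostic); and single-gene loss, rejected when it
would leave fewer than two genes. Event counts per branch are Poisson with
mean rate x branch length; descendants inherit their ancestor's
arrangement, so one event on a stem paints exactly that clade — the
clustered structure the enrichment test is designed to detect.

Placement follows hotspot weights over gene labels. The default
concentrates all mass uniformly on the Region 1 and Region 2 spans,
emulating the empirical concentration of rearrangement there; spans are
drawn so every gene in the span has positive weight, and transposition
re-insertion gaps must touch a positive-weight gene. A useful consequence,
exercised in the tests: with mass confined to Region 1, the only genes that
can acquire positive RF are the span's genes and its two anchors (whose
inner flanks face the span).

Parameter defaults, and why:

* rates (events per unit branch length): `tandem_duplication = 0.15`,
  `tdrl = 0.15`, `transposition = 0.10`, `inversion = 0.05`, `loss = 0.05`.
  Realistic relative rates of the five mechanisms are unknown; these are
  placeholders, weighted toward the duplicative mechanisms that dominate
  published accounts, and every analysis function takes the model as an
  argument.
* span length: geometric with mean 2 genes, capped at 6. Unstated by any
  source; small blocks match the tRNA-cluster scale of observed
  rearrangements.
* loss: single genes only, never emptying the genome — keeps every
  simulated order scoreable.

Every event is logged with its full parameters (span, insertion gap, which
copies a TDRL deleted), and `replay_events()` re-derives every tip from the
root through the log, erroring on any mismatch. Identical seeds give
identical datasets; the RNG state is restored on exit.

What the generator does *not* emulate: sequence evolution entirely;
duplication of the control region with concerted evolution; mechanistic
variants (non-random loss, dimer-mitogenome models) beyond the five
operators; intraspecific variation; and annotation error, which in real
data is a major source of spurious "rearrangements". Passing
parameter-recovery tests therefore shows the pipeline is sound on cleanly
generated orders, not that real GenBank annotations are clean — the
O~L~/pseudogene exclusions and the closed-alphabet validation are the
package's first line of defence there, not a cure.

## Numerical and degenerate-input choices

* Circular indexing is exact integer arithmetic throughout; there are no
  tolerances in scoring.
* Orders must have length at least 2 for neighbours to exist; shorter
  inputs error at validation, projection errors when fewer than 2
  occurrences survive, and region extraction of adjacent anchors returns an
  empty span (a valid, countable pattern).
* In unordered mode the changed-flank flags are assigned under the
  pairing that maximizes matches, with the directional pairing preferred on
  ties, so `rs = left_changed + right_changed` holds in both modes.
* Unknown gene tokens are an error naming the row and token; the sole
  deliberate exception is the undefined token `V1` seen in one published
  arrangement string, mapped to `V` with a warning rather than guessed
  silently or dropped.
* Leucine/serine numbering is positional (`L2` beside nad5, `S1` after
  cox1), matching the usage the reference arrangements encode; the synonym
  table also accepts anticodon spellings (`tRNA-Leu(CUN)` is `L2`), so both
  conventions parse to the same labels.

## Test design and problem sizes

The suite freezes the two desk anchors (tandem-duplication RS = 2,
neobatrachian RS = 10) and checks the scorer against an independent
brute-force implementation that materializes every (gene, left, right)
triple — exhaustively, on all 97,650 circular orders of length 2–7 over a
5-letter toy alphabet, in both modes. Stochastic properties use fixed
seeds: rate-monotonicity of mean tip RS averages 5 replicate simulations
per rate on a 40-tip tree; the enrichment power check paints one clade of a
64-tip coalescent tree and compares against 50 label shuffles; the
end-to-end consistency check runs the full pipeline on a simulated 232-tip
survey, the scale of a realistic amphibian census. These sizes keep the
whole suite within a couple of minutes while leaving the exhaustive sweeps
genuinely exhaustive.

## Known limitations

* RS is a descriptive distance to a reference, not an evolutionary
  distance: a single transposition of a long block scores the same as
  several independent single-gene moves with the same flank footprint, and
  no attempt is made to reconstruct event histories between two orders.
* The choice of reference matters; RF ranks are fairly stable under
  reasonable references but absolute values are not, which is why every
  report embeds the reference name.
* The clade-enrichment construction tests each clade marginally;
  Bonferroni over nested, strongly dependent clades is conservative.
* MRCA bounds are upper bounds only and inherit all uncertainty of the
  input dates; they say nothing about how much later a pattern arose.
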