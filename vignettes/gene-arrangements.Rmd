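---
title: "Analysing mitochondrial gene arrangements with MitoRearr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing mitochondrial gene arrangements with MitoRearr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoRearr)
```

## The problem

Insect mitochondrial genomes are circular molecules of 14--20 kb carrying a
remarkably stable inventory: 13 protein-coding genes, 22 tRNAs, two rRNAs and
one large A+T-rich control region (CR). While the inventory is stable, the
*relative order* of the genes is not: tandem duplication followed by random
loss of the redundant copies (TDRL), inversions and transpositions
occasionally shuffle genes, and the resulting arrangements are heritable
rare events that carry phylogenetic signal. In the cricket-and-katydid
lineage (Ensifera), eight distinct arrangement types have been described,
with the ancestral insect arrangement (Type I) shared by most species.

MitoRearr turns that style of analysis into a reusable, testable pipeline:

1. **genbank I/O** -- read annotated mitogenome flat files into
   `AnnotatedMitogenome` objects, normalising heterogeneous gene names to
   canonical symbols;
2. **composition** -- AT/GC skew, per-region base composition, codon usage
   and RSCU;
3. **gene orders** -- extract signed circular gene orders, canonicalize and
   classify them into arrangement types;
4. **rearrangement quantification** -- per-gene rearrangement scores (RS),
   per-genome RS and cohort rearrangement frequencies (RF), in the style of
   the qMGR method;
5. **event inference** -- exhaustive minimal TDRL / inversion /
   transposition histories between orders;
6. **selection** -- pairwise Ka/Ks per protein-coding gene by
   Nei--Gojobori (1986) counting;
7. **synthetic data** -- a fully seeded generator for every input the
   pipeline consumes.

## The data model

A `SignedGeneOrder` is a circular sequence of up to 38 signed symbols; sign
+1 is the majority/J strand (defined as the strand encoding cox1), -1 the
minority/N strand. Some published figures use the opposite convention
(minus on the heavy strand); the package normalises everything to its own
convention at the boundary. Two orders are *circularly equal* when one is a
rotation of the other with signs preserved (`orderIdentical`). On top of
that, `canonicalizeOrder` fixes the two free conventions a deposited record
has: the linearisation point (rotation: the anchor gene cox1 is put first,
with rrnS as fallback because Type IV lacks trnI and no type rearranges
cox1) and which strand the record calls "plus" (if the anchor carries sign
-1 the whole order is reflected -- reversed with all signs flipped -- since
a circular signed order and its reflection describe the same molecule read
from the opposite strand). `sameArrangement` compares two orders after this
normalisation and is the equality used by type classification and event
inference.

Coordinates in `AnnotatedMitogenome` are 1-based inclusive (GenBank
convention). The molecule is circular, so a feature may span the origin;
such features are stored *unwrapped* (`end > record length`), which keeps
`end - start + 1` the true length and makes the modular arithmetic explicit
in exactly one place.

## Arrangement types as package data

The eight Ensifera arrangement types are shipped as canonical orders
(`arrangementTypeOrders()`), transcribed from their published descriptions:

* **Type I** -- the ancestral insect order (also `ancestralOrder()`).
* **Type II** -- the trnN-trnS1-trnE cluster inverted to the minority
  strand (major cricket lineage).
* **Type III** -- Type II plus an interchange of trnV and rrnS.
* **Type IV** -- trnI deleted (the dune cricket *Comicus campestris*).
* **Type V** -- a strand-flipping tRNA translocation. The published account
  of this type is figure-only; the packaged order is a best-effort
  transcription and is excluded from every hard assertion in the test
  suite.
* **Type VI** -- trnM translocated 5' of trnI (M-I-Q).
* **Type VII** -- I-M-ND2-Q, the outcome of a TDRL of the Q-M-ND2 block.
* **Type VIII** -- the most rearranged type: in the cox3..trnF
  neighbourhood, trnA/trnR interchanged, trnS1 transposed after trnR, and
  the trnG-nad3 block relocated after trnN. The textual description of this
  type does not fully determine strands, while reporting both that the
  genome shows "more inversions and transpositions" and that it attains the
  highest genome RS of the eight types. We therefore encode the two
  relocated blocks as true inversions (sign-flipping) and the trnS1 move as
  a transposition -- the reading consistent with all of those statements at
  once. Like Type V, the exact order is a transcription choice and is
  documented as such.

```{r}
rs <- vapply(arrangementTypeOrders(), genomeRS, integer(1))
rs
```

## Rearrangement scoring

The scoring contract is fixed as follows. Against a reference order
(default: ancestral), each gene receives a score in {0, 1, 2}: the number
of its two oriented adjacencies (predecessor -> gene, gene -> successor,
compared with strand signs) that differ from the reference. Two conventions
complete the contract:

* a gene whose own strand sign flipped scores 2 regardless of neighbours
  (a strand flip is a maximal disruption of that gene's context);
* a gene deleted from a genome scores the maximal 2, so gene loss (Type
  IV's trnI) registers; the package logs a note whenever this convention
  fires.

The control region anchors the adjacencies of its neighbours but is itself
unscored: the method scores *genes*, and the CR is not a gene. The genome
RS accumulates the per-gene scores; the cohort rearrangement frequency of a
gene is `RF = 100 * (sum of its scores) / (2N)` percent over `N` genomes --
the fraction of its maximal possible score mass. The published description
of the underlying method prints no formula, so this reconstruction is
fixed here as the package's contract and is validated against an
independent brute-force adjacency-set comparator in the test suite rather
than against plotted bar heights. Whether strand flips were counted
separately from positional moves in the original is unknowable from the
text; our rule (flip means 2) is flagged in this paragraph precisely
because it is a choice.

## Event model and inference

Three mechanisms are modelled on the circular order:

* **TDRL(block, loss set)** -- the block appears twice in tandem; each
  duplicated gene then keeps its first copy, its second copy, or neither
  (complete gene loss). Losing the whole second copy is the identity.
* **inversion(block)** -- the block is reversed and every sign flipped.
* **transposition(block, destination)** -- the block is excised and
  reinserted, signs unchanged.

`inferEvents` searches breadth-first over this event space for *all*
minimal-length histories from a source to a target order, comparing states
by canonical equality. Solutions that differ only in parameterisation but
pass through the same intermediate arrangements are deduplicated to one
representative, chosen lexicographically by (kind, block start) with TDRL <
inversion < transposition. Blocks never include the CR: no described type
moves, duplicates or loses it, and the duplications the TDRL model invokes
are themselves seeded from CR stem-loop structures. When nothing within the
limits maps source to target the result carries the explicit status
`"limits exhausted"` -- never a silent empty answer.

The search is exhaustive within its limits but exponential in depth: on a
38-gene order with blocks up to 3 genes one level is a few thousand
events, and each further level multiplies by the (deduplicated) frontier
size. Depth-1 searches run in well under a second; depth 2 and 3 are
practical on reduced alphabets, which is how the depth-completeness
property is tested. The default block-length limit of 6 is generous
relative to every described Ensifera event (none exceeds 3 genes).

```{r}
inferEvents(ancestralOrder(), arrangementTypeOrders()$VI,
            max_events = 1, max_block_len = 3)
```

## Composition statistics

`skews` applies AT-skew = (A-T)/(A+T), GC-skew = (G-C)/(G+C). Whole-genome
skews are computed on the published strand of the record as deposited
(matching how one overall skew per genome is conventionally reported);
per-gene and per-class statistics reverse-complement each feature to its
coding strand first. N bases are excluded from every count and denominator,
and a skew with a zero denominator is `NA` (undefined), never 0.

RSCU under the invertebrate mitochondrial code (translation table 5) is
`count * family size / family total`; incomplete terminal codons (the
truncated T/TA stops of mitogenome annotation) are dropped rather than
completed, because RSCU should count only observed full codons, and stop
codons never enter the table. A codon family entirely unused has RSCU 0 and
is flagged instead of dividing by zero.

## Ka/Ks by NG86

The paper-scale analysis this package emulates used a maximum-likelihood
tool for its selection figures; here the deliverable *implements* rather
than calls, so the classic Nei--Gojobori (1986) counting method is built
in: per-codon synonymous site fractions from the mitochondrial code
(averaged over the two sequences), difference counts averaged over all
minimal mutational pathways with equal weight, and the Jukes--Cantor
correction `d = -(3/4) log(1 - 4p/3)` for each proportion. Consequences of
that choice: plotted likelihood-based values are not reproduction targets;
the package's claims are the qualitative purifying-selection signature
(omega < 1) and exact agreement with an exhaustive pathway-enumeration
oracle, both covered in the tests.

Conventions, stated because NG86 leaves them open: mutations creating stop
codons are excluded from site denominators and pathways through stops are
discarded (a codon pair whose every pathway crosses a stop is excluded and
tallied); codon columns containing gaps or N are excluded pairwise and
tallied; a proportion >= 3/4 is reported as saturated (`NA` rate, explicit
status); identical sequences report status `"identical"` with omega `NA`,
never 0/0. There is no transition/transversion weighting -- that is what
makes it NG86 and not a later refinement.

## The synthetic-data generator

The generator exists so that every stage is testable without downloads,
and its defaults are the study conditions the analyses assume:

* **Event regime** -- rearrangements are rare accidents, so per-genome
  event counts are Poisson with a low mean (default 0.5); `fixed_events`
  forces an exact count for controlled recovery experiments. Every
  described Ensifera rearrangement involves a block of at most three genes
  (I-Q-M, Q-M-ND2, N-S1-E, rrnS-V, single tRNAs), so the default
  `max_block_len` is 3. Events are conditioned on actually changing the
  arrangement, so a logged event is a real event, and they never touch the
  CR. TDRLs lose one copy per gene, with a small probability (0.02) of
  losing both (complete gene loss, as in Type IV).
* **Sequences** -- tRNAs are 63--72 bp; protein-coding and rRNA genes use
  typical insect mitochondrial lengths (e.g. cox1 1536 bp, rrnL about
  1285 bp); the CR is 1275 bp. Base frequencies default to about 72
  percent AT genome-wide and 80 percent AT in the CR, matching the
  AT-richness of real insect mitogenomes. Protein-coding genes are
  generated in frame with no internal stops (rejection sampling), an ATG
  start and a TAA stop.
* **Codon pairs** -- an ancestor of uniform sense codons is mutated
  site-wise; proposed changes are accepted with probability `p_syn` or
  `p_nonsyn` according to their effect, stops rejected. Probabilities are
  capped below 0.5 as a saturation guard.

What the generator deliberately does not emulate: phylogenetic structure
(events on a tree), pseudogenes and duplicated-gene remnants, strand-
asymmetric mutational bias (so generated skews are near zero, unlike the
pronounced negative skews of real records), tRNA secondary structure, and
overlapping genes. Tests that pass on synthetic data therefore validate
the *arithmetic and inference machinery*, not field realism of the inputs;
conclusions about a real cohort still require real records.

## Numerical and degenerate-input choices

* Feature ties at one start coordinate order longer-first, with a warning.
* An unmappable gene name is a structured condition
  (`mitoRearr_unresolved_symbol`); the parser converts it into a warning
  and skips the feature, so one bad annotation does not kill a cohort run.
* The pipeline treats per-record parse failures as logged warnings and
  aborts only when nothing parses; every bundle carries a machine-readable
  `warnings.json`, and timestamps are confined to the run log so reports
  are byte-reproducible.
* All report tables are single-header TSV; JSON is written with sorted
  keys.

## Problem sizes used in validation

The automated checks run at sizes chosen to exercise every code path at
interactive speeds: oracle comparisons on 500 random single-event genomes
and 100 random 200-codon alignment pairs, recovery experiments on 200
simulated single-event genomes, purifying-regime cohorts of 13 genes x 3
pairs x 150 codons, and end-to-end pipeline runs on cohorts of 4--10
synthetic records. Depth-completeness of the event search is established
exhaustively on 7--10-gene alphabets, where the full event space is
enumerable.

## Known limitations

* Types V and VIII are transcriptions of under-determined textual
  descriptions (see above); the classification machinery does not depend
  on them, but their exact packaged orders should be treated as
  provisional.
* The event search guarantees minimality only within its declared limits;
  a history using blocks longer than `max_block_len` or more than
  `max_events` steps is reported as `"limits exhausted"`, not approximated.
* NG86 is a counting method; it underestimates rates at high divergence
  relative to likelihood methods, and saturated pairs are excluded rather
  than extrapolated.
* Tree-aware analyses -- ancestral order reconstruction, divergence
  dating, substitution-rate estimation on a phylogeny -- are out of scope.
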