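---
title: "Methods: synteny-aware annotation of yeast assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny-aware annotation of yeast assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(syntann)
```

This vignette documents the models and procedures behind `syntann`, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic fixtures do and do not demonstrate
about real data.

## The annotation model

The premise is that related yeast genomes already tell us which genes to
expect in a genomic region, and that orthologs tend to share intron/exon
structure. The reference database is a set of *pillars* — manually curated
columns of orthologous (and WGD-paralogous) genes across reference species
— plus the ordered list of pillar loci in the inferred pre-duplication
ancestor. Species descending from the whole-genome duplication (post-WGD)
stand in a 2:1 syntenic relationship to that ancestral order; the user
declares the target genome post-WGD or non-WGD, and that single switch
drives reference-gene preference, intron eligibility and the copy-number
cap.

### Homology search

Every pillar protein is used as a query against the six-frame translation
of the scaffolds. The built-in engine is a classical seed-and-extend
aligner: exact 4-mer amino-acid seeds, grouped by diagonal, extended
without gaps under BLOSUM62 scoring with an X-drop of 40 raw score units;
bit scores and E-values follow the Karlin–Altschul form with the ungapped
BLOSUM62 constants (lambda = 0.3176, K = 0.134) and the total translated
length as the search space. Hits at `E >= 1e-5` are discarded. The engine
is deliberately ungapped: an assembly indel or an intron interrupts the
alignment and yields two HSPs, and that break is exactly the signal the
downstream classifier consumes. Gapped sensitivity, bit-exact agreement
with any particular external search tool, and neighborhood seeding are
non-goals; externally computed hits can be supplied as a 12-column tabular
file instead (`parse_search_tabular()`), with subject coordinates
normalized to 0-based half-open forward-strand intervals on input.

All internal coordinates are 0-based half-open on the forward strand; the
GFF3 writer and the tabular reader are the only conversion points. Gene
logic runs on the coding strand through local reverse-complement views.

### Locus retention and synteny

For each pillar, the member with the lowest E-value defines the primary
locus; its other hits are clustered into candidate loci by single-linkage
with a 5000-nt gap (chosen to exceed intron and indel spans while
separating tandem paralogs; the choice is exposed as `max_gap_nt`).
Secondary loci are retained iff the decimal exponent of their E-value is
below −30 and below half the exponent of the best E-value; `exponent10()`
is `floor(log10(e))` with an exact zero mapped to −324 (double underflow),
so zero E-values always pass the halved-exponent gate. The prose rule is
ambiguous between comparing `E/2` and `exponent(E)/2`; the worked
1e-100 → 1e-50 example fixes the exponent-halving reading used here.

Overlapping candidate loci from different pillars form one ambiguous locus.
Resolution is purely positional, ignoring E-values: scanning outward on the
scaffold for the nearest unambiguous assignments (at most 10 assigned loci
per side — the radius is a bounded-locality choice, not a published value),
a candidate wins iff it lies strictly between those two anchors in the
ancestral order, on the same ancestral chromosome. Cross-chromosome anchors
never satisfy the test, which avoids spurious resolution at rearrangement
breakpoints. At a scaffold end, where only one anchor exists, a candidate
within 10 ancestral positions of that single anchor is accepted — a
documented extension of the two-anchor rule to a case the original
description leaves open. The pillar database format carries one ancestral
order; where a reference-species order is also wanted, it can be encoded as
additional ancestral chromosomes, but the interval test itself consults a
single ordering — a simplification relative to pipelines that fall back
from the ancestral to a reference-species order.

Unresolved multi-candidate loci are annotated as genes but left outside the
pillar system (`unresolved-singleton`). Post-WGD runs cap assignments at
two loci per pillar, non-WGD runs at one; excess loci are demoted to
singletons, keeping the strongest evidence (unique hit before
synteny-resolved, then lowest E). Two adjacent same-pillar loci are treated
as a tandem duplication: the copy whose flanks match the pillar's ancestral
neighborhood keeps the pillar (ties go to the 5'-most copy, for
deterministic output), the other moves to a derived `<pillar>.tandemN`
pillar.

### Gene models

The reference gene *R* for a locus prefers, in order: a same-group
intron-bearing member with a hit, a same-group member, any intron-bearing
member, any member — ties by E-value, then bit score, then gene id.
Consecutive HSPs of *R* along the coding strand are classified with two
tolerances: `gap_tol = 30` nt for "similar distance" (small enough to
exclude real yeast introns, which are ≥ ~50 nt, while tolerating small
indels) and `overlap_tol = 15` aa of query overlap before a pair is called
a duplication outright. Because query gaps are whole codons, the frame
offset between two HSPs reduces to the subject gap modulo 3; a non-zero
offset with similar gaps is a frameshift, a zero offset with similar gaps
and no in-frame stop between merges as low similarity, dissimilar gaps
(small query gap, subject gap ≥ 40 nt) with an intron-bearing same-group
member make an intron call, and everything else splits the locus into two
models. Chains longer than two HSPs are evaluated pairwise left to right;
a duplication call closes the current model and opens the next.

Start codons: a seed already starting with ATG is kept; otherwise the frame
is walked upstream to the furthest ATG reachable without crossing an
in-frame stop; if a stop intervenes first, the first 45 nt inside the seed
are scanned for a leading ATG; failing that, the seed start is kept and the
model tagged `manual-check`. Stops: the frame is walked downstream from the
chosen start to the first in-frame stop, which trims into the seed when one
lies inside it (the stop-side trim is unbounded within the seed; only the
start side carries the 45-nt budget, the conservative reading of an
underspecified rule). Walking into an N run tags `runs-into-N`; the mean
group protein lengths of the pillar bound the upstream walk at three times
the group mean — the database computes those means at this stage and this
is their natural use, but the cap is an interpretation and can be disabled
(`cap_start_extension = FALSE`).

### Introns

Intron calls are built only from the canonical motif inventories (eight
donors, three branchpoints, CAG/TAG acceptors) and only one intron per gene
is ever predicted; evidence for a second flags the model for manual
curation instead, since almost all intron-bearing yeast genes have exactly
one intron and the combinatorial space of multi-intron models is not
trustworthy without transcript data. Between two HSPs, all
donor/branch/acceptor combinations in the inter-HSP window (±45 nt into
each HSP) with length 40–1000 nt are enumerated; a combination is valid
when the spliced product is in frame and stop-free with donor < branchpoint
< acceptor, and candidates are ranked by agreement between intron length
and the subject-minus-query gap difference, then by donor proximity to the
upstream HSP. The motif scan uses zero-width lookahead so overlapping motif
occurrences are all visible. The branchpoint is constrained only to lie
between donor and acceptor; canonical yeast branchpoints sit ~10–60 nt
before the acceptor, and leaving that distance unconstrained is a known
divergence risk, accepted to keep the rule minimal.

When only exon 2 produced a hit and the reference gene carries an intron,
exon 1 is reconstructed: acceptors are searched around the HSP start
(the alignment may overshoot a few codons into the intron, so the window
extends 45 nt past the HSP start and the exon-2 stop scan is anchored at
each candidate acceptor, not at the HSP), donors up to 1000 nt further
upstream, and an ATG within 600 nt of the donor, requiring the spliced
protein length within ±20% of the reference protein (a generous band for
divergence that still rejects frame-luck ORFs). Among valid candidates the
one minimizing the length error wins. Recovery is attempted whenever the
reference is intron-bearing and the HSP leaves a query prefix unmatched,
and the recovered interpretation replaces the single-exon one only when it
matches the reference length better — otherwise short first exons whose
spurious downstream ATG happens to land inside the tolerance band would be
silently mis-annotated.

### Frameshift repair

A frameshift call extracts the scaffold region from 50 bp upstream of the
first HSP's end to 50 bp downstream of the second HSP's start. When the two
HSPs overlap on the subject — both alignments extending slightly past the
indel — that definition degenerates below one read length, so the window
generalizes to the junction region with the same 50 bp pads (identical
whenever the HSPs are disjoint). Reads sharing a 20-mer with the window are
aligned locally (Smith–Waterman, match +1 / mismatch −2, gap open 2 /
extend 1); alignments with `E < 1e-30` contribute their indels, keyed by
exact (offset, operation, bases) after normalizing positions to the
leftmost placement within a homopolymer run (so reads reporting the same
physical indel at different offsets of a run vote together, while distinct
errors are never merged). Candidates seen in fewer than two reads are
dropped; the remainder are tried in order of support, and the first whose
application yields a stop-free in-frame translation across the junction is
applied. Without reads, `(3 − d) mod 3` N bases (d the subject gap mod 3)
are inserted at the codon-aligned midpoint of the gap — the estimated-site
placement is an interpretation, chosen so the junction translates as a
clean X residue. Edits are batched and the edited assembly re-annotated
once (rather than re-annotating after each edit); genes spanning an applied
edit are tagged `frameshift-corrected`, genes whose frameshift persists
`frameshift-uncorrected`, and with repair disabled the same detections are
reported as tags only.

### Rescue passes and retrotransposons

After the main annotation: (1) for each ancestral locus whose two neighbors
are mapped to one scaffold but which itself is unannotated, the pillar's
intronless members are aligned against the intergenic gap alone with no
E-value threshold. Because exact-seed heuristics miss short genes near 40%
identity, this pass uses exhaustive Smith–Waterman over the six gap
translations — affordable precisely because the search space is one gap.
"No threshold" cannot mean no sanity constraints: the rescued ORF must
reach 30 codons, cover half of the shortest member protein, and overlap no
existing feature; it is emitted with tag `searchdogs`. (2) All maximal
ATG-to-stop ORFs of ≥150 aa (stop codon excluded, the common ORF-finder
convention) that overlap no feature on either strand — the stricter of the
two possible readings — are emitted as `large-orf` singletons. (3) Models
overlapped by a Ty-labelled reference gene at `E < 1e-5` are tagged `ty`
and detached from the pillar system; no attempt is made to resolve LTR
structure. tRNA features are ingested from a precomputed track (the
external predictor is not re-implemented), and no protein-coding model may
overlap a tRNA.

### Assembly QC

Paired reads (suffix conventions `/1,/2` and `.f,.r`) are placed on the
scaffolds by exact full-length matching on both strands; only reads with
exactly one placement are kept and assigned the contig containing them.
Pairs linking two contigs increment a symmetric matrix ordered by scaffold
position. Declared (adjacent) joins form the expected band; a band cell
below `max(2, 0.25 × median band support)` is flagged, and off-band cells
with ≥3 pairs are reported as possible alternatives. The tool reports
only — breaking joins is the user's call.

## The synthetic fixtures

`fixture_spec()` fixes the world: pillars with one ancestral protein each
(uniform amino-acid composition, length lognormal around 450 codons —
adequate for exercising homology search, with no pretense of realistic
composition), four members per pillar (two species per group) at 2%
divergence from the ancestral protein, 4% of pillars intron-bearing by
default with motif-compliant splice sites, genes placed in ancestral order
with occasional adjacent swaps and 20% strand inversions, random intergenic
spacers of 300–800 nt, and optional paralog pairs (identical ancestral
proteins, separable only by synteny), tandem duplicates, Ty cassettes and
WGD derivation (two scaffolds, 20% duplicate retention). Every output is a
deterministic function of the seed.

Two constructions are deliberate idealizations. Each gene block carries an
in-frame TAA immediately before its ATG, pinning the furthest-upstream-ATG
rule to the true start; real intergenic sequence offers no such guarantee,
so exact start recovery on real genomes will be worse than on fixtures.
Second, reads are simulated error-free from the true (pre-edit) sequence at
the requested coverage while the assembly carries the planted indel —
isolating the voting logic from a full pyrosequencing error model. Planted
indels are 1-bp, biased to homopolymer runs (deletions three times as
common as insertions, mirroring the dominance of base additions among real
assembly corrections), and kept ≥35 codons from gene ends so both broken
fragments can seed hits. Passing fixture tests therefore demonstrates the
logic of every stage under known ground truth — not sequencing-platform
realism, pseudogene handling, or subtelomeric gene-family behavior, which
remain the hard cases on real data.

Test problem sizes: end-to-end recovery uses 200-pillar fixtures (clean,
and 0.2 divergence with 4% introns), frameshift repair 120 pillars with 50
planted indels at 20× paired coverage, copy-number checks a 120-pillar
post-WGD fixture at 20% retention; module tests use 6–40 pillars.

## Numerical choices and degenerate inputs

E-value exponents use `floor(log10(e))` with 0 → −324; below 1e-308
doubles are subnormal, so literal powers of ten lose exactness there —
irrelevant for real E-values, but worth knowing when testing with synthetic
ones. Ties are broken deterministically throughout (bit score, then lexical
gene id; 5'-most tandem copy; first-listed intron call). Seeds shorter than
one codon, pillars without hits, empty gaps, windows without motifs and
vote lists exhausted without an ORF all degrade to explicit no-result
returns or `manual-check` tags rather than errors. The pipeline itself is
deterministic; the only randomness in the package lives in the fixture
generator, under its seed.

## Known limitations

Single-intron cap (two-intron genes are flagged, never modeled);
no pseudogene calling; no non-ATG starts; ungapped HSPs only in the primary
search; E-values are search-space-scaled analytics, not calibrated to any
external tool; the synteny test consults one ancestral ordering; Ty
elements are flagged, not structurally annotated; QC reports weak joins but
does not re-scaffold.
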