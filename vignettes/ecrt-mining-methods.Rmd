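---
title: "Mining endogenous caulimovirid RT loci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining endogenous caulimovirid RT loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrtminer)
```

## The problem

Plant genomes carry endogenous viral elements (EVEs): fragments of
viral DNA captured into the nuclear genome and left to decay by
substitution, indel accumulation and pseudogenization. The
*Caulimoviridae*, the plant-infecting family of reverse-transcribing
dsDNA viruses, are the most common source of plant EVEs. Because the
reverse-transcriptase (RT) domain is the most conserved part of any
viral retroelement, translated homology search for RT domains is the
most sensitive way to ask whether a genome contains endogenous
caulimovirid RT loci (ECRTs) and which viral lineages they descend
from. The difficulty is that ECRTs must be distinguished from the
closely related Ty3/Gypsy LTR retrotransposons that litter the same
genomes, and that heavily decayed copies no longer carry intact open
reading frames.

`ecrtminer` implements that survey as a reproducible pipeline with a
synthetic benchmark attached, so each stage can be validated without
any external data:

1. **Translated search** — a seed-and-extend tBLASTn-like search of RT
   protein queries against the six reading frames of a genome, with
   Karlin–Altschul E-values.
2. **Locus assembly** — merging of overlapping hit footprints and a
   fixed 120-bp flank extension.
3. **Two-pass classification** — pass 1 translates loci, keeps
   stop-free segments of ≥ 200 residues and accepts a locus only when
   its best library hit is caulimovirid over ≥ 170 aligned residues;
   pass 2 drops the ORF requirement and asks instead for a translated
   alignment spanning ≥ 80% of the subject in base pairs
   (generically 576 bp for a 240-residue RT domain).
4. **OTU delineation** — greedy centroid clustering of accepted
   proteins (80% within a species, 55% globally) and connected
   components of a similarity network over cluster representatives.
5. **Phylogenetic placement** — maximum-likelihood attachment of
   eligible locus sequences onto a fixed reference tree under
   GTR+Γ, one placement kept per query, with OTU labels read off the
   subtended clade or `"inner"` for placements on mixed edges.
6. **Summaries** — per-genome counts, ECRT density per ungapped
   megabase, a count-versus-log10(size) trendline with its R², and
   the OTU × species distribution matrix.

## The synthetic benchmark

`make_benchmark_bundle()` emulates the survey's raw material: i.i.d.
background genomes at a chosen GC content into which decayed viral
copies are planted at uniformly chosen, non-overlapping, non-nested
cut points on random strands, with exact ground-truth intervals and
edit logs. Two donor families are planted: *caulimovirid* donors —
the coding sequences of the packaged 8-leaf reference tree's leaves —
and *Ty3/Gypsy-like decoys* derived from an unrelated synthetic
240-residue RT ancestor. Everything is regenerated deterministically
from a seed; no sequence data ships with the package.

The decay model has four knobs, all rates per site unless noted:

| parameter | default | meaning |
|---|---|---|
| `sub_rate` | 0.10 | substitution probability per base (always to a different base) |
| `indel_rate` | 0.001 | indel event probability per base |
| `indel_len_mean` | 3 | mean of the geometric indel-length distribution (bases) |
| `stop_rate` | 0.5 | forced premature stops per 100 codons of the donor's original frame |

The defaults describe a moderately decayed EVE population. At
`sub_rate = 0.10`, roughly a quarter of residues change, which leaves
family assignment easy but sequence identity to the source around
75–80%. The indel rate is kept low (≈ 0.7 events per 720-bp donor)
because a single frameshift truncates every translated alignment at
that point; at 0.001 roughly half of the planted copies stay
frameshift-free. `stop_rate = 0.5` adds about one engineered stop per
RT domain; together with stops arising from random substitutions this
splits the planted population into copies with intact ≥ 200-residue
ORFs (captured by pass 1) and copies recoverable only at the DNA
level (captured by pass 2), which is precisely the situation the
two-pass design exists for. The geometric indel-length distribution
is a single-parameter choice whose heavy-enough tail produces both
in-frame and frameshifting events.

What the generator deliberately does **not** model: real plant genome
composition (repeats, isochores, GC gradients), nested or overlapping
insertions, segmental duplication of EVEs after insertion, and
lineage-specific codon usage. Passing benchmarks therefore
demonstrate the pipeline's internal correctness and its behaviour
under neutral decay — not performance against tandem-repeat-rich
backgrounds or ancient highly fragmented elements.

## Translated search

Seeds are exact amino-acid 4-mers over the 20 standard residues (no
BLAST neighbourhood words); each seed is extended ungapped along its
diagonal with an X-drop of 20, and segments scoring ≥ 30 enter a
windowed affine-gap Smith–Waterman (BLOSUM62, gap open 11, extend 1;
a gap of length *g* costs 11 + *g*). E-values use the published
gapped BLOSUM62/11,1 Karlin–Altschul parameters λ = 0.267,
K = 0.041, with the effective subject length excluding runs of `N`
(assembly gaps). HSPs with E ≤ 1e−5 are kept. On 20-kb genomes the
seeded search recovers every seed-containing HSP found by full
per-frame Smith–Waterman at the same score; the tests assert this
against `Biostrings::pairwiseAlignment` as an independent oracle.

Merging is strandless — hit footprints on the forward strand are
unioned whenever they overlap, with touching half-open intervals kept
apart — because the locus is the unit of downstream translation and
strand is recovered later from the best translated frame. The
alternative (strand-aware merging) would double-count loci hit on
both strands.

## Classification details

Pass-1 candidates are maximal stop-free segments of each of the six
frame translations; the longest segment represents the locus. A
locus with no ≥ 200-residue segment receives the status
`rejected_no_orf`, so that `accepted`, `rejected_family`,
`rejected_length` and `rejected_no_orf` partition every input locus.
"Reciprocal" classification is operationalized as best-score family
assignment against the combined two-family library (caulimovirid
targets plus Ty3/Gypsy outgroup): a candidate is accepted only when
its single best hit is caulimovirid, which is equivalent to winning
the reciprocal comparison against the outgroup, with ties broken by
higher identity and then lexicographic subject id.

Pass 2 measures the nucleotide span of the best frame-aware local
alignment as 3 bases per alignment column. The eligibility threshold
is ⌈0.8 × 3 × subject length⌉ with a numerical guard so that the
generic 240-residue subject yields exactly 576 bp rather than
suffering a binary-representation ceiling artifact.

## Clustering and the similarity network

Pairwise identity is computed on a global alignment with free
terminal gaps; identical columns are divided by alignment columns
excluding terminal-gap columns (`mode = "core"`), the convention
closest to centroid-clustering tools and tolerant of fragments of
different length. Because the optimal free-end-gap alignment of two
*unrelated* sequences can be a short perfect overlap, core identity
can spike to 1.0 on random pairs. The two stages therefore use
different defaults: greedy clustering compares homologous fragments
and uses `"core"`, while network construction — whose node pairs may
be entirely unrelated families — uses the `"full"` denominator
including terminal gaps, so edges cannot arise from accidental short
overlaps. Greedy clustering processes sequences by decreasing
length (ties lexicographic), joining the first centroid at or above
the threshold — deterministic by construction. OTUs are the
connected components of the thresholded identity graph over cluster
representatives; component labels are numbered by their
lexicographically smallest member so labels are stable across runs.
The original workflow's manually curated split-network is replaced by
these components because manual curation is not reproducible; the
edge threshold is exposed (`network_id`, default 0.35) rather than
fixed.

The trimAl-style `filter_alignment()` drops sequences whose
well-supported residues (columns where ≥ 75% of the other sequences
are non-gap) cover < 50% of alignment columns, then columns with
< 50% non-gap rows, then repeats the sequence round — two overlap
rounds separated by a gap-column round. An alignment that empties is
flagged, never an error. The default `run_pipeline()` does not
construct a multiple alignment (no de-novo MSA builder is included),
so this filter applies when the user supplies an alignment; the
pipeline's global clustering round operates directly on pairwise
identities instead.

## Placement model and numerics

The reference package is an input: a tree with branch lengths, a
reference nucleotide alignment over its leaves, a GTR+Γ model (four
discrete categories, category means; shape defaults to 1 when not
supplied) and a leaf → OTU map. The packaged toy reference (8
leaves, two OTUs given by the root bipartition, 720 gap-free columns
simulated along the tree) ships as a deterministic generator,
`toy_reference_package()`.

Queries are projected into reference column space by a pairwise
overlap alignment against the best-matching ungapped reference row
(both strands tried; a query sharing no 8-mer with any row is
reported unalignable), with query insertions relative to the
reference dropped — keep-length semantics, so every aligned row has
exactly the reference width.

Placement attaches the query at the **midpoint** of each candidate
edge by a pendant branch optimized with golden-section search on
[1e−9, 4] substitutions/site to a tolerance of 1e−4; the
attachment position along the edge is not optimized (it is exposed in
the result for future refinement). This is cheaper than full
EPA-style position optimization and the brute-force all-edge oracle
in the test suite bounds the error: on the 8-leaf reference the
midpoint surrogate selects the same edge as exhaustive grid
evaluation of every edge. The like-weight ratio is the exp-normalized
optimized likelihood of an edge over all edges and sums to one before
the keep-at-most-1 truncation. Likelihood evaluation uses Felsenstein
pruning with per-node rescaling; gaps are missing data. Per-edge
clade-side and rest-of-tree messages are precomputed once per
reference (`placement_engine()`), so each pendant evaluation costs
one 4×4 matrix exponential per category plus a dot product per site.
The rooted representation of the tree is used as-is: the two edges
incident to a binary root are evaluated separately rather than
collapsed into one unrooted edge, which only affects placements that
fall exactly at the root.

## Summary surfaces

Density is loci per megabase of (assembly length − gap length),
where a gap is any run of ≥ 1 `N` (`min_gap_run` exposed because the
choice of minimum run length is a convention, not a fact). The
trendline is ordinary least squares of per-genome locus counts on
log10 of ungapped size in Mb — count on log-size, matching the
figure-axis convention of genome surveys — with a log–log variant
left to the user. Per-genome counts are the post-pass-2 eligible
loci; counting placements instead would conflate mining sensitivity
with placement rejections. The distribution matrix has one row per
species, one column per OTU plus `"inner"`; its cells sum to the
number of placed loci by construction.

## Problem sizes used in the checks

The packaged checks run the full pipeline on 5 genomes of 1 Mb with
20 caulimovirid and 10 decoy insertions each (the bundle's
defaults); search-oracle equivalence uses 20 genomes of 20 kb;
exhaustive-likelihood verification uses 4–8 leaves × 100 sites;
placement verification uses 50 simulated queries against the 8-leaf
reference. These sizes were chosen so the complete suite exercises
every code path at desk scale; all of them grow with a single
parameter each if larger runs are wanted.

## Known limitations

- No frameshift-aware protein alignment: a frameshifted copy is only
  recoverable through pass 2, and only up to its longest in-frame
  block.
- No composition-based score adjustment or low-complexity masking;
  AT-rich genomes with long homopolymer stretches will produce more
  spurious seeds than the i.i.d. benchmark suggests.
- The similarity-network OTUs are a deterministic surrogate for a
  curated split-network; border-line lineages that a curator would
  split on reticulation evidence become single components here.
- Placement assumes the reference alignment is trustworthy and
  gap-free rows of equal information content; highly fragmentary
  queries (< ~200 bp aligned) carry little signal and tend to land
  on inner edges with diffuse like-weight ratios.
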