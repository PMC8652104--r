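---
title: "The linear pangenome model: presence/absence matrices, hollow areas and graph linearization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The linear pangenome model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpav)
```

## The model

A pangenome collects the sequence content of many genomes of one species. In
the linear representation, that content is divided into **pangenomic blocks**
— genes, or sequence segments such as variation-graph nodes — and every block
is placed exactly once on a flattened single-string **pan-reference**, one
axis per **panchromosome**. Each genome is then described by which blocks it
carries: a **presence/absence variation (PAV) matrix** of blocks × genomes.

`panpav` stores this as a tibble with one row per block. Six fixed columns
describe the block (`panchromosome`, `start`, `stop`, `block_id`, `similar`,
`function_note`), and one integer column per genome holds the **copy count**
of that block in that genome, 0 meaning absent. Copy counts rather than
booleans are kept because a genome's path through a variation graph can
traverse a segment several times; presence is defined as count ≥ 1
everywhere, and the counts above 1 feed only the repetition track.

Coordinates are BED-style throughout: 0-based, half-open, in base pairs on
the pan-reference. Blocks may leave gaps on the axis but never overlap within
a panchromosome; `recompute_coordinates()` produces the canonical contiguous
tiling (cumulative sums of block widths) when a gap-free axis is wanted.

The `similar` column records repeated occurrences of a block elsewhere in
the pangenome, as semicolon-joined `panchromosome:start` tokens (`"."` when
unique). This is deliberately a *pointer* track: the matrix does not try to
disambiguate paralogs, it only flags where repetition exists.

## Core versus variable genome

A block belongs to the **core genome** when the fraction of genomes carrying
it reaches a threshold τ, and to the **variable (dispensable) genome**
otherwise:

status(b) = CORE ⇔ |{g : c(b, g) ≥ 1}| / N ≥ τ.

Two dialect choices are fixed here and worth stating plainly, since either
convention exists in the wild:

* **The comparison is inclusive (≥).** This makes τ = 1 mean exactly
  "present in every genome", the strict-core definition, and makes the
  classification monotone in τ with no boundary surprises at rational
  fractions like 19/20 versus τ = 0.95.
* **The default is τ = 0.95**, the common "soft core" community default.
  Every function takes τ as an argument, so the default matters only as a
  starting point for exploration.

```{r}
classify_block(c(15, 14), 15, threshold = 0.95)
classify_block(19, 20, threshold = 0.95)   # boundary case: 0.95 >= 0.95 is CORE
```

Preconditions are checked: presence counts must lie in 1..N (a block absent
from every genome is invalid by construction), and τ in (0, 1].

## Hollow areas

The hollow area finder automates "jump to the places where genomes are
missing content". Its semantics needed fixing, because "an area of
consecutive absence" is ambiguous: we require the **same** set of at least
*g* genomes to be absent across the **whole** run. Formally, for an interval
of consecutive blocks *I*, let A(I) be the intersection of the per-block
absent-genome sets. A hollow area is an interval with |A(I)| ≥ g and at
least *L* blocks that is *maximal*: extending it one block on either side
drops the intersection below *g*. Two overlapping maximal intervals with
different absent sets are both real findings, and both are reported.

The intersection semantics (rather than "each block is missing from at
least g genomes, possibly different ones") makes the result unique,
order-independent and testable against exhaustive enumeration — the package
test suite checks exact equality with an O(n²) brute-force oracle on
hundreds of random matrices.

The threshold *L* counts **blocks**, not base pairs: blocks are the unit of
the linear model, and a bp threshold would make the finder sensitive to how
the upstream pangenome builder happened to split segments. The bp extent is
still reported per area (`span_bp`) so users can filter on it afterwards.

The scan itself is a two-pointer sweep, linear in blocks × genomes: as the
window grows the intersection can only shrink, so for each left end the
largest valid right end is found incrementally, and an interval is emitted
only when the previous left end could not already cover its right end
(left-maximality). This is what makes panel-scale matrices (hundreds of
genomes, tens of thousands of blocks) scan in about a second.

```{r}
pav <- simulate_pav(n_genomes = 8, n_blocks = 40, seed = 23,
                    planted_hollows = list(list(
                      panchromosome = "pan_1", first_block = 5, n_blocks = 8,
                      genomes = c("g01", "g05", "g06"))))
find_hollow_areas(pav, min_blocks = 8, min_genomes = 3)
```

## Genome orderings

Three deterministic orderings rearrange the rows of the matrix view. All of
them return a permutation tibble (`genome`, `key`) rather than silently
reordering, and all break ties by input (matrix) order so no ordering ever
depends on a seed.

* **Tree**: genomes follow the left-to-right leaf order of a Newick tree
  (read with `ape`); genomes missing from the tree are appended in matrix
  order, tree leaves naming no genome are ignored with a warning.
* **Region pattern**: presence vectors over a chosen block range are
  binarized and genomes are ranked by Hamming distance to a pivot genome.
  The pivot is always first with key 0 — even if another genome has an
  identical pattern — because "show me genomes like this one" must anchor on
  the pivot. A full clustering of the region was deliberately left out:
  a pivot distance is transparent, stable and sufficient for the browsing
  use case.
* **Gene list**: each listed gene is resolved through its annotation card to
  the blocks overlapping the card's span; a genome scores one point per gene
  whose blocks are all present. Descending score.

## Annotations and file formats

The PAV file dialect is tab-separated with a mandatory header:

```
#Chromosome  Start  Stop  BlockID  SimilarBlocks  Function  <genome> ...
```

The header-first design means genome names are never positional guesses, and
`write_pav()` always emits a canonical form (blocks sorted by panchromosome
and start, `\n` endings, plain integer counts) so that read∘write and
write∘read are identities — a property the test suite asserts on randomized
matrices. Validation is separated from reading: `validate_pangenome_file()`
returns every issue as a (severity, code, message, line) row and never
throws; the readers refuse exactly the files whose report contains an ERROR.

GFF3 annotations live in **pangenomic** coordinates (their `seqid` is a
panchromosome, never a genome-local chromosome). On disk GFF3 is 1-based
inclusive; in memory everything is 0-based half-open, and the conversion is
checked to be self-inverse. Features are grouped into **cards** — one per
gene, carrying the mRNA/exon substructure via `Parent` links and the
functional text — which is the unit the annotation track displays and the
gene-list sort consumes. Orphan children (a `Parent` that never appears) are
kept as their own cards with a warning rather than dropped: a half-broken
annotation file is still worth browsing.

## Linearizing a variation graph

A GFA1 graph with P-lines already contains everything the linear model
needs: segments are blocks, paths are genomes, and traversal counts are copy
counts (orientation is ignored for presence — a reverse traversal still
means the genome carries the segment). What the graph does not contain is a
*block order*, and no single correct order exists. The rule used here:

1. A chosen **backbone** path fixes the order of the segments it traverses.
2. Every other segment is inserted immediately after its **anchor**: the
   backbone segment that most recently precedes it, taken from the earliest
   path (in file order) in which a backbone segment does precede it.
   Segments never preceded by a backbone segment go before the first
   backbone block. Segments sharing an anchor keep their within-path order.

The anchor rule is one defensible choice among several (the earliest-path
tie-break in particular is ours); it is isolated inside `linearize_gfa()` so
an alternative ordering could be swapped in without touching the rest of the
package. What is *not* negotiable are the conservation laws the tests
enforce on every random graph: each genome's count column reproduces its
path's traversal multiset, Σ(count × segment length) equals the path's bp
total, the backbone column is everywhere ≥ 1, and the ordering is a pure
function of the file.

Path names of the form `genome#chrom` are split on the first `#` to group
several paths into one genome, each backbone path becoming one
panchromosome; plain path names mean one path per genome on a single
`pan_1` axis.

```{r}
gfa <- c("S\ts1\tACGT", "S\ts2\t*\tLN:i:3", "S\ts3\tAACCG",
         "P\tgA\ts1+,s2+,s3+\t*", "P\tgB\ts1+,s3+\t*")
linearize_gfa(read_gfa(gfa), backbone = "gA")
```

## Rendering

`render_pav()` computes the full geometry of the multi-track linear view and
writes SVG. The output is a pure function of (matrix, cards, config):
identical inputs give byte-identical documents, which is what makes the
renderer testable and its outputs diffable. Interactive behaviours of a
browser UI (hover cards, click-to-navigate) are replaced by static
equivalents: each annotation mark carries its card text as an SVG
`<title>`, and every cell rectangle carries `data-genome`/`data-block`
attributes so downstream tools (and the tests) can address cells.

Layout choices:

* Block width on screen is proportional to bp width — width is
  information-bearing in this model, so blocks are never drawn uniform.
  `px_per_bp` is the single zoom parameter; changing it rescales x extents
  linearly and nothing else.
* The annotation track is a **beeswarm**: marks sit at their true x centre
  and are pushed into the lowest vertical lane where they overlap nothing,
  processing marks in ascending x (ties by id). Greedy lowest-lane is the
  standard genome-browser packing; it is deterministic and provably
  overlap-free per lane.
* The palette is colour-blind safe: core `#E69F00` (orange), variable
  `#56B4E9` (blue), absent light grey. Orange-for-core / blue-for-variable
  is the established convention for this display.
* The whole-panchromosome **overview** strip shades each one-pixel bin by
  the mean presence fraction of the blocks overlapping it. The mean is a
  choice (the display needed *some* summary statistic and none is canonical);
  it is exposed numerically via `overview_bins()` so the shading is
  auditable.

For interactive work, `autoplot()` gives a ggplot2 heatmap of the same
matrix and `plot_overview()` the binned presence profile; the SVG path
remains the canonical, deterministic artifact.

## The synthetic generator

`simulate_pav()` and friends generate every format the readers consume, with
*planted, recoverable structure*: hollow intervals where exactly a chosen
genome subset is absent (flanks forced present so the planted interval is
recovered as maximal), repeat groups whose members cross-list each other,
and a core fraction forced present everywhere. Each artifact kind draws from
its own stream derived from (seed, kind), so generating a GFA between two
matrix draws never changes the matrices.

Defaults emulate a mid-sized plant resequencing panel: **15 genomes**, block
widths **1–10 kb** (the block resolution at which PAV browsing is typically
done), background presence probability **0.9**, and half the blocks forced
core. The 0.9 presence probability keeps chance runs of shared absence
short — the probability that two specific genomes are jointly absent over
five consecutive blocks by chance is 10⁻¹⁰ — so planted-structure recovery
tests are sharp rather than statistical.

What the generator does **not** emulate: phylogenetic correlation between
genomes (cells are independent), gene gain/loss dynamics along a tree,
length or GC structure in block widths, or sequence content of any kind.
Passing tests therefore demonstrate the *algorithms'* correctness on
matrices of realistic shape, not robustness to the correlation structure of
any particular real panel.

## Problem sizes, numerics and limitations

The test suite runs the hollow finder against exhaustive enumeration on 200
random matrices up to 8 genomes × 40 blocks, recovery on 50 planted
fixtures, 100 round trips, 100 random graph linearizations, exhaustive
classification laws up to 30 genomes, and one full-scale pass at 300
genomes × 50 000 blocks (write, read, classify, hollow-scan) — sizes chosen
so the whole suite completes in a few minutes while still covering the
interval-structure edge cases that small matrices expose best.

Numerical notes: all coordinates and counts are integers; the only floating
arithmetic is presence fractions and pixel geometry (formatted to 0.01 px,
which is what makes SVG output byte-stable). Degenerate inputs are defined,
not accidental: an empty block list yields an empty coordinate tiling, a
header-only PAV file is a valid empty matrix, a one-bin overview equals the
matrix-wide mean presence fraction.

Known limitations, by design: no statistical enrichment testing of hollow
areas; no clustering-based genome ordering; no tree inference; no GFA2/W
lines or cyclic-graph handling beyond traversal counts; no nucleotide-level
sequence storage; `.gz` streams are not read directly.
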