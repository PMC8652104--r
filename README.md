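# panpav

Tools for **linearized pangenomes**: the representation in which the content
of many genomes of one species is divided into *pangenomic blocks* (genes or
sequence segments), every block is placed once on a flattened single-string
*pan-reference* (one axis per *panchromosome*), and each genome is described
by a row of a **presence/absence variation (PAV) matrix** over those blocks.

It is written for people who analyse resequencing panels — dozens up to a
few hundred eukaryotic genomes — and need to answer questions like *which
blocks are core and which dispensable?*, *where are the regions that a group
of genomes is jointly missing?*, *how do I order genomes to make a pattern
visible?*, and *how do I get from a variation graph to this linear view at
all?*

## What it computes

Let `c(b, g)` be the copy count of block *b* in genome *g* (0 = absent,
counts above 1 arise when a genome's graph path traverses a segment more
than once). With *N* genomes and a threshold τ ∈ (0, 1]:

* **Core/variable classification** — block *b* is CORE iff
  `|{g : c(b,g) ≥ 1}| / N ≥ τ` (inclusive boundary, so τ = 1 is the strict
  core). Default τ = 0.95.
* **Hollow areas** — maximal runs of ≥ L consecutive blocks whose
  jointly-absent genome set (the intersection of per-block absent sets) has
  ≥ g genomes; the analogue of "jump to where content is missing".
* **Genome orderings** — by Newick tree leaf order, by Hamming distance of
  the binarized presence pattern in a region to a pivot genome, or by
  counting fully-present genes from a list. All deterministic.
* **GFA1 linearization** — paths become genomes, segments become blocks,
  traversal counts become copy counts; a backbone path fixes the block
  order and every off-backbone segment is inserted after the backbone
  segment that most recently precedes it.
* **Rendering** — the multi-track linear view (annotation beeswarm,
  core/variable, repetition and per-genome presence tracks) as
  deterministic SVG; ggplot2 `autoplot()` for interactive work.
* **Synthetic pangenomes** — seeded generators for PAV/GFF3/Newick/GFA with
  planted hollow areas and repeat groups, so everything above is testable
  with no external data.

Everything is a tibble in and a tibble out, so the functions compose with
dplyr and the pipe.

## Worked example

```r
library(panpav)

pav <- simulate_pav(n_genomes = 6, n_blocks = 40, seed = 11,
                    planted_hollows = list(list(panchromosome = "pan_1",
                                                first_block = 12, n_blocks = 6,
                                                genomes = c("g02", "g05"))))
glance(pav)
#> # A tibble: 1 × 7
#>   n_genomes n_blocks n_panchromosomes total_bp threshold n_core n_variable
#>       <int>    <int>            <int>    <int>     <dbl>  <int>      <int>
#> 1         6       40                1   211986      0.95     27         13
```

Six genomes, forty 1–10 kb blocks spanning 212 kb of pan-reference; at the
default 95% threshold 27 blocks are core and 13 variable (the planted
hollow plus background absence).

```r
find_hollow_areas(pav, min_blocks = 4, min_genomes = 2)
#> # A tibble: 1 × 9
#>   panchromosome first_block last_block start  stop n_blocks span_bp n_absent
#>   <chr>               <int>      <int> <int> <int>    <int>   <int>    <int>
#> 1 pan_1                  12         17 54532 84315        6   29783        2
#> # ℹ 1 more variable: absent_genomes <list>
```

The finder recovers exactly the planted interval — blocks 12–17, spanning
29.8 kb at pan-coordinates 54,532–84,315 — and reports the two genomes
(`g02`, `g05`) jointly absent across it. `hollow_as_bed()` turns this into
a BED line (`pan_1  54532  84315  g02,g05`) for use with bedtools and
friends.

```r
sort_genomes_by_region(pav, "pan_1", 12, 17, pivot = "g02")
#> # Genome ordering (REGION_PATTERN)
#> # A tibble: 6 × 2
#>   genome   key
#>   <chr>  <int>
#> 1 g02        0
#> 2 g05        0
#> 3 g01        6
#> 4 g03        6
#> 5 g04        6
#> 6 g06        6
```

Ordering by the presence pattern over that region puts the pivot first,
then `g05` (identical pattern, distance 0), then the four genomes that
differ at all six blocks — the ordering a reader would want before looking
at the rendered view:

```r
write_svg(render_pav(pav, config = view_config(px_per_bp = 0.002,
          genome_order = sort_genomes_by_region(pav, "pan_1", 12, 17, "g02"))),
          "view.svg")
```

A GFA1 graph goes the other way — from graph to matrix:

```r
gfa <- c("S\ts1\tACGT", "S\ts2\t*\tLN:i:3", "S\ts3\tAACCG",
         "P\tgA\ts1+,s2+,s3+\t*", "P\tgB\ts1+,s3+\t*")
linearize_gfa(read_gfa(gfa), backbone = "gA")
#> # A PAV table: 3 blocks x 2 genomes (1 panchromosome)
#> # A tibble: 3 × 8
#>   panchromosome start  stop block_id similar function_note    gA    gB
#>   <chr>         <int> <int> <chr>    <chr>   <chr>         <int> <int>
#> 1 pan_1             0     4 s1       .       ""                1     1
#> 2 pan_1             4     7 s2       .       ""                1     1
#> 3 pan_1             7    12 s3       .       ""                1     0
```

Segment lengths 4, 3, 5 tile the axis as (0,4), (4,7), (7,12); `gB`
skips `s2`, so its cell is 0.

## Command line

A thin wrapper over the same functions ships at `inst/cli/panpav`:

```sh
panpav validate matrix.tsv
panpav stats matrix.tsv --threshold 0.95
panpav hollow matrix.tsv --min-blocks 4 --min-genomes 2        # BED to stdout
panpav sort matrix.tsv --mode tree --tree panel.nwk
panpav render matrix.tsv --px-per-bp 0.01 --out view.svg
panpav gfa2pav graph.gfa --backbone ref --out matrix.tsv
panpav simulate --genomes 15 --blocks 500 --seed 1 --out matrix.tsv
```

Exit codes: 0 success, 1 input validation errors (the report is printed),
2 usage errors. Machine-readable output goes to stdout or `--out`; logs to
stderr.

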