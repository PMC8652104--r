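# Seeded synthetic pangenomes with planted, recoverable structure. These are
# first-class generators: every file format the readers consume can be
# produced here, deterministically, with hollows and repeat groups planted at
# known positions so the analysis operations can be checked against ground
# truth.
#
# Each artifact kind draws from its own stream, derived from (seed, kind), so
# adding one generator never perturbs another's output.

SEED_OFFSETS <- c(pav = 101L, gfa = 202L, gff = 303L, tree = 404L)

local_seed <- function(seed, kind) {
  sub_seed <- (as.integer(seed) %% 1000000L) * 1000L + SEED_OFFSETS[[kind]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(sub_seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a PAV table with planted structure
#'
#' Generates a deterministic synthetic pangenome: blocks with 1-10 kb widths
#' tiled over panchromosomes, a chosen fraction of blocks forced core (present
#' in every genome), background presence drawn at probability
#' `presence_prob`, and optionally planted hollow areas (intervals where
#' exactly a listed genome subset is absent) and planted repeat groups
#' (blocks cross-listing each other as similar positions).
#'
#' Defaults mirror a mid-sized plant panel: 15 genomes and 1-10 kb blocks,
#' the block resolution at which PAV browsing is usually done.
#'
#' @param n_genomes Number of genomes (>= 2). Default 15.
#' @param n_blocks Total number of blocks across all panchromosomes. Default
#'   100.
#' @param n_panchromosomes Number of panchromosomes; blocks are split into
#'   contiguous chunks. Default 1.
#' @param core_fraction Fraction of blocks forced present in all genomes.
#'   Default 0.5.
#' @param planted_hollows List of `list(panchromosome =, first_block =,
#'   n_blocks =, genomes =)` entries (1-based block index within the
#'   panchromosome): within each, exactly the listed genomes are absent on
#'   exactly the listed blocks, all other genomes are present there and the
#'   listed genomes are present on the flanking blocks, so the planted
#'   interval is recovered as a maximal hollow area.
#' @param planted_repeats List of character vectors of block ids (or integer
#'   vectors of global block indices); members of a group cross-list each
#'   other in their `similar` field.
#' @param block_length_range Integer `c(min, max)` block width in bp. Default
#'   `c(1000, 10000)`.
#' @param presence_prob Background presence probability for non-core cells.
#'   Default 0.9, low enough absence that long shared-absence runs essentially
#'   never arise by chance.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `pav_df` object.
#' @export
simulate_pav <- function(n_genomes = 15, n_blocks = 100, n_panchromosomes = 1,
                         core_fraction = 0.5, planted_hollows = NULL,
                         planted_repeats = NULL,
                         block_length_range = c(1000, 10000),
                         presence_prob = 0.9, seed = 1) {
  if (n_genomes < 2) abort_pav("n_genomes must be >= 2")
  if (n_blocks < 1 || n_panchromosomes < 1 || n_panchromosomes > n_blocks) {
    abort_pav("need 1 <= n_panchromosomes <= n_blocks")
  }
  restore <- local_seed(seed, "pav"); on.exit(restore())

  genomes <- sprintf("g%02d", seq_len(n_genomes))
  pc_sizes <- diff(round(seq(0, n_blocks, length.out = n_panchromosomes + 1)))
  pc_names <- sprintf("pan_%d", seq_len(n_panchromosomes))
  pc_of <- rep(pc_names, pc_sizes)
  idx_in_pc <- unlist(lapply(pc_sizes, seq_len))
  block_id <- sprintf("%s_b%04d", pc_of, idx_in_pc)
  lengths <- sample(block_length_range[1]:block_length_range[2], n_blocks,
                    replace = TRUE)
  coords <- dplyr::bind_rows(lapply(split(lengths, factor(pc_of, pc_names)),
                                    recompute_coordinates))

  is_core <- rep(FALSE, n_blocks)
  if (core_fraction > 0) {
    is_core[sample.int(n_blocks, round(core_fraction * n_blocks))] <- TRUE
  }
  present <- matrix(stats::rbinom(n_blocks * n_genomes, 1, presence_prob) == 1,
                    nrow = n_blocks, dimnames = list(block_id, genomes))
  present[is_core, ] <- TRUE

  for (h in planted_hollows %||% list()) {
    rows <- which(pc_of == h$panchromosome &
                    idx_in_pc %in% (h$first_block + seq_len(h$n_blocks) - 1L))
    if (length(rows) != h$n_blocks) abort_pav("planted hollow out of bounds")
    if (length(h$genomes) >= n_genomes) {
      abort_pav("a planted hollow may not cover every genome")
    }
    if (!all(h$genomes %in% genomes)) abort_pav("unknown genome in planted hollow")
    present[rows, ] <- TRUE
    present[rows, h$genomes] <- FALSE
    # flanks: listed genomes present so the planted interval stays maximal
    flank <- which(pc_of == h$panchromosome &
                     idx_in_pc %in% c(h$first_block - 1L,
                                      h$first_block + h$n_blocks))
    present[flank, h$genomes] <- TRUE
  }

  # repair blocks rendered absent everywhere by the background draw
  empty <- which(rowSums(present) == 0)
  if (length(empty) > 0) {
    fix <- sample.int(n_genomes, length(empty), replace = TRUE)
    present[cbind(empty, fix)] <- TRUE
  }

  counts <- matrix(0L, n_blocks, n_genomes, dimnames = list(block_id, genomes))
  counts[present] <- 1L + stats::rbinom(sum(present), 1, 0.03)

  similar <- rep(".", n_blocks)
  for (grp in planted_repeats %||% list()) {
    rows <- if (is.numeric(grp)) as.integer(grp) else match(grp, block_id)
    if (anyNA(rows) || any(rows < 1 | rows > n_blocks)) {
      abort_pav("unknown block in planted repeat group")
    }
    for (r in rows) {
      partners <- setdiff(rows, r)
      similar[r] <- paste(sprintf("%s:%d", pc_of[partners],
                                  coords$start[partners]), collapse = ";")
    }
  }

  df <- tibble::tibble(panchromosome = pc_of, start = coords$start,
                       stop = coords$stop, block_id = block_id,
                       similar = similar, function_note = "")
  for (j in seq_along(genomes)) df[[genomes[j]]] <- counts[, j]
  as_pav(df, genomes)
}

#' Simulate a GFA1 variation graph
#'
#' Builds a graph whose first path (`g01`, the natural backbone) traverses all
#' segments in order, while every other path drops segments with probability
#' 0.15 and duplicates (traverses twice) with probability 0.1, with random
#' orientations. Deterministic given the seed, and always parseable by
#' [read_gfa()].
#'
#' @param n_segments Number of segments (>= 2); lengths drawn from 50-500 bp.
#' @param n_paths Number of paths/genomes (>= 1).
#' @param seed Integer seed.
#' @return Character vector of GFA1 lines.
#' @export
simulate_gfa <- function(n_segments, n_paths, seed = 1) {
  if (n_segments < 2 || n_paths < 1) {
    abort_pav("need n_segments >= 2 and n_paths >= 1")
  }
  restore <- local_seed(seed, "gfa"); on.exit(restore())
  seg <- sprintf("s%d", seq_len(n_segments))
  len <- sample(50:500, n_segments, replace = TRUE)
  s_lines <- sprintf("S\t%s\t*\tLN:i:%d", seg, len)
  p_lines <- character(n_paths)
  p_lines[1] <- sprintf("P\tg01\t%s\t*", paste0(seg, "+", collapse = ","))
  for (k in seq_len(n_paths)[-1]) {
    keep <- stats::runif(n_segments) > 0.15
    if (!any(keep)) keep[1] <- TRUE
    times <- 1L + stats::rbinom(n_segments, 1, 0.1)
    steps <- unlist(lapply(which(keep), function(i) {
      rep(paste0(seg[i], sample(c("+", "-"), 1)), times[i])
    }))
    p_lines[k] <- sprintf("P\tg%02d\t%s\t*", k, paste(steps, collapse = ","))
  }
  c("H\tVN:Z:1.0", s_lines, p_lines)
}

#' Simulate GFF3 annotations over a PAV table
#'
#' Picks `n_genes` random blocks and writes a gene -> mRNA -> exon hierarchy
#' inside each, on pangenomic coordinates, so annotation cards and the
#' gene-list genome sort can be exercised without external data.
#'
#' @param pav A `pav_df` object.
#' @param n_genes Number of genes to place.
#' @param seed Integer seed.
#' @return Character vector of GFF3 lines.
#' @export
simulate_annotations <- function(pav, n_genes, seed = 1) {
  restore <- local_seed(seed, "gff"); on.exit(restore())
  rows <- sample.int(nrow(pav), min(n_genes, nrow(pav)))
  lines <- "##gff-version 3"
  for (k in seq_along(rows)) {
    b <- pav[rows[k], ]
    gid <- sprintf("gene%03d", k)
    g_start <- b$start + 1L              # to 1-based inclusive
    g_end <- b$stop
    mid <- b$start + (b$stop - b$start) %/% 2L
    strand <- sample(c("+", "-"), 1)
    lines <- c(
      lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Note=synthetic gene %d",
              b$panchromosome, g_start, g_end, strand, gid, k),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.m1;Parent=%s",
              b$panchromosome, g_start, g_end, strand, gid, gid),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e1;Parent=%s.m1",
              b$panchromosome, g_start, mid, strand, gid, gid),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e2;Parent=%s.m1",
              b$panchromosome, mid + 1L, g_end, strand, gid, gid))
  }
  lines
}

#' Simulate a random genome phylogeny in Newick
#'
#' @param genomes Character vector of genome names to use as leaves.
#' @param seed Integer seed.
#' @return A single-element character vector holding a Newick string.
#' @export
simulate_tree <- function(genomes, seed = 1) {
  restore <- local_seed(seed, "tree"); on.exit(restore())
  tree <- ape::rtree(length(genomes), tip.label = sample(genomes))
  ape::write.tree(tree)
}
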