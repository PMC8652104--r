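# Genome orderings: phylogeny-driven, by presence pattern in a region, or by
# a list of genes. Every ordering is a true permutation of the matrix's
# genomes, deterministic (ties break by matrix order), and returned as a
# tibble so it can be inspected before being applied.

new_genome_ordering <- function(genome, key, mode) {
  structure(tibble::tibble(genome = genome, key = key),
            mode = mode,
            class = c("genome_ordering", class(tibble::tibble())))
}

#' Order genomes by a phylogenetic tree
#'
#' Genomes found in the tree come first, in leaf order; genomes absent from
#' the tree are appended in matrix order. Tree leaves naming no genome of the
#' matrix are ignored with a warning.
#'
#' @param pav A `pav_df` object.
#' @param leaf_order Character vector of leaf names, e.g. from
#'   [read_genome_tree()].
#' @return A `genome_ordering` tibble: `genome` in the new order and `key`
#'   (the leaf rank; `NA` for appended genomes).
#' @export
sort_genomes_by_tree <- function(pav, leaf_order) {
  g <- pav_genomes(pav)
  extra <- setdiff(leaf_order, g)
  if (length(extra) > 0) {
    rlang::warn(sprintf("ignored tree leaf/leaves naming no genome: %s",
                        paste(extra, collapse = ", ")))
  }
  in_tree <- leaf_order[leaf_order %in% g]
  rest <- g[!g %in% in_tree]
  new_genome_ordering(
    genome = c(in_tree, rest),
    key = c(seq_along(in_tree), rep(NA_integer_, length(rest))),
    mode = "TREE")
}

#' Order genomes by presence pattern in a region
#'
#' Binarizes the copy counts (present = count >= 1) of every genome over a
#' block range and orders genomes by ascending Hamming distance to a pivot
#' genome's pattern. The pivot comes first (distance 0); ties keep matrix
#' order.
#'
#' @param pav A `pav_df` object.
#' @param panchromosome Panchromosome holding the region.
#' @param first_block,last_block 1-based inclusive indices into that
#'   panchromosome's block order.
#' @param pivot Genome whose pattern anchors the ordering.
#' @return A `genome_ordering` tibble with `key` = Hamming distance.
#' @export
sort_genomes_by_region <- function(pav, panchromosome, first_block, last_block,
                                   pivot) {
  g <- pav_genomes(pav)
  if (!pivot %in% g) abort_pav(sprintf("unknown pivot genome '%s'", pivot))
  if (!panchromosome %in% pav$panchromosome) {
    abort_pav(sprintf("unknown panchromosome '%s'", panchromosome))
  }
  sub <- pav[pav$panchromosome == panchromosome, , drop = FALSE]
  if (first_block > last_block || first_block < 1 || last_block > nrow(sub)) {
    abort_pav("empty or out-of-bounds block range")
  }
  pres <- pav_counts(sub)[first_block:last_block, , drop = FALSE] >= 1L
  dist <- colSums(pres != pres[, pivot])
  # pivot always first, then ascending distance, remaining ties matrix order
  ord <- order(dist, g != pivot, seq_along(g))
  new_genome_ordering(genome = g[ord], key = as.integer(dist[ord]),
                      mode = "REGION_PATTERN")
}

#' Order genomes by presence of a gene list
#'
#' Each gene is resolved to its annotation card and to the blocks overlapping
#' the card span; a genome scores one point per gene whose selected blocks are
#' all present in it. Genomes are ordered by descending score; ties keep
#' matrix order.
#'
#' @param pav A `pav_df` object.
#' @param cards Annotation cards from [read_annotations()].
#' @param gene_ids Character vector of `gene_id`s to score.
#' @return A `genome_ordering` tibble with `key` = genes fully present.
#' @export
sort_genomes_by_gene_list <- function(pav, cards, gene_ids) {
  g <- pav_genomes(pav)
  missing <- setdiff(gene_ids, cards$gene_id)
  if (length(missing) > 0) {
    abort_pav(sprintf("gene id(s) not found in the annotation cards: %s",
                      paste(missing, collapse = ", ")))
  }
  score <- integer(length(g)); names(score) <- g
  for (id in gene_ids) {
    card <- cards[cards$gene_id == id, , drop = FALSE][1, ]
    sel <- pav$panchromosome == card$panchromosome &
      pav$start < card$stop & pav$stop > card$start
    if (!any(sel)) {
      abort_pav(sprintf("gene '%s' overlaps no block of the PAV table", id))
    }
    pres <- pav_counts(pav[sel, , drop = FALSE]) >= 1L
    score <- score + as.integer(colSums(pres) == nrow(pres))
  }
  ord <- order(-score, match(g, g))
  new_genome_ordering(genome = g[ord], key = as.integer(score[ord]),
                      mode = "GENE_LIST")
}

#' Apply a genome ordering to a PAV table
#'
#' @param pav A `pav_df` object.
#' @param ordering A `genome_ordering` (or a character permutation of the
#'   genome names).
#' @return `pav` with its genome columns reordered.
#' @export
apply_genome_order <- function(pav, ordering) {
  ord <- if (is.data.frame(ordering)) ordering$genome else as.character(ordering)
  g <- pav_genomes(pav)
  if (!setequal(ord, g) || length(ord) != length(g)) {
    abort_pav("ordering must be a permutation of the genome names")
  }
  out <- pav[, c(PAV_FIXED_COLS, ord)]
  new_pav(out, ord)
}

#' @export
print.genome_ordering <- function(x, ...) {
  cat(sprintf("# Genome ordering (%s)\n", attr(x, "mode")))
  NextMethod()
}
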