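# Hollow areas: maximal runs of consecutive blocks that the SAME set of at
# least g genomes is absent from. The shared-absentee set of an interval is
# the intersection of the per-block absent sets; an interval is reported when
# that intersection still has >= g genomes, it spans >= L blocks, and growing
# it one block on either side would shrink the intersection below g.

#' Find hollow areas in a PAV table
#'
#' Scans each panchromosome for maximal intervals of at least `min_blocks`
#' consecutive blocks whose jointly-absent genome set (the intersection of the
#' per-block absent sets) contains at least `min_genomes` genomes. Overlapping
#' maximal intervals with different absent sets are all reported.
#'
#' @param pav A `pav_df` object.
#' @param min_blocks Minimum number of consecutive blocks (L, >= 1).
#' @param min_genomes Minimum number of jointly absent genomes (g, >= 1 and
#'   <= the number of genomes).
#' @return A tibble sorted by (panchromosome, first_block): one row per hollow
#'   area with `panchromosome`, `first_block` / `last_block` (1-based,
#'   inclusive indices into that panchromosome's block order), `start` /
#'   `stop` (pan-coordinates of the interval), `n_blocks`, `span_bp` (summed
#'   block widths), `n_absent` and an `absent_genomes` list-column of genome
#'   names.
#'
#' @details The two-pointer scan is linear in blocks x genomes: for each left
#'   end the largest right end keeping the intersection at `min_genomes` is
#'   found incrementally (the intersection only shrinks as the window grows),
#'   and an interval is kept only when the previous left end could not already
#'   cover its right end (left-maximality).
#' @export
find_hollow_areas <- function(pav, min_blocks = 1, min_genomes = 1) {
  g_all <- pav_genomes(pav)
  if (min_blocks < 1) abort_pav("min_blocks must be >= 1")
  if (min_genomes < 1 || min_genomes > length(g_all)) {
    abort_pav("min_genomes must be between 1 and the number of genomes")
  }
  out <- lapply(pav_panchromosomes(pav), function(pc) {
    sub <- pav[pav$panchromosome == pc, , drop = FALSE]
    hollow_scan_one(sub, g_all, as.integer(min_blocks), as.integer(min_genomes))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(panchromosome = character(), first_block = integer(),
                          last_block = integer(), start = integer(),
                          stop = integer(), n_blocks = integer(),
                          span_bp = integer(), n_absent = integer(),
                          absent_genomes = list()))
  }
  res[order(res$panchromosome, res$first_block), , drop = FALSE]
}

hollow_scan_one <- function(sub, genomes, L, g) {
  n <- nrow(sub)
  if (n == 0) return(NULL)
  absent <- pav_counts(sub) == 0L          # n x G logical
  widths <- sub$stop - sub$start
  res <- list()
  cnt <- integer(length(genomes))
  j <- 0L          # right end of the current window [i, j]
  prev_j <- 0L     # j of the previous left end (0 = none)
  for (i in seq_len(n)) {
    if (j < i - 1L) { j <- i - 1L; cnt[] <- 0L }
    repeat {
      if (j >= n) break
      cand <- cnt + absent[j + 1L, ]
      if (sum(cand == (j + 1L - i + 1L)) >= g) { cnt <- cand; j <- j + 1L }
      else break
    }
    if (j >= i && j > prev_j) {           # valid and left-maximal
      len <- j - i + 1L
      if (len >= L) {
        shared <- genomes[cnt == len]
        res[[length(res) + 1L]] <- tibble::tibble(
          panchromosome = sub$panchromosome[1],
          first_block = i, last_block = j,
          start = sub$start[i], stop = sub$stop[j],
          n_blocks = len, span_bp = as.integer(sum(widths[i:j])),
          n_absent = length(shared), absent_genomes = list(shared))
      }
    }
    prev_j <- max(prev_j, j)
    if (j >= i) cnt <- cnt - absent[i, ]
  }
  dplyr::bind_rows(res)
}

#' Export hollow areas as BED intervals
#'
#' @param hollows Result of [find_hollow_areas()].
#' @return A tibble in BED order: `chrom`, `start` (pan-start of the first
#'   block), `end` (pan-stop of the last block), `name` (comma-joined absent
#'   genomes).
#' @export
hollow_as_bed <- function(hollows) {
  tibble::tibble(
    chrom = hollows$panchromosome,
    start = hollows$start,
    end = hollows$stop,
    name = vapply(hollows$absent_genomes, paste, character(1), collapse = ",")
  )
}
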