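# Core/variable classification and pan-coordinate arithmetic.

#' Classify blocks as core or variable from presence counts
#'
#' A block belongs to the core genome when the fraction of genomes carrying it
#' reaches the threshold; otherwise it is variable (dispensable). The
#' comparison is inclusive, so `threshold = 1` means "present in every genome"
#' (the strict core).
#'
#' @param presence_count Integer vector: number of genomes with copy count
#'   >= 1 for each block. Must be >= 1 (a block absent everywhere is invalid).
#' @param n_genomes Number of genomes in the pangenome (scalar, >= 1).
#' @param threshold Presence fraction in (0, 1] above which (inclusive) a
#'   block is CORE. Default 0.95.
#'
#' @return A tibble with columns `presence_count`, `n_genomes`,
#'   `presence_fraction` and `status` (`"CORE"` or `"VARIABLE"`).
#'
#' @examples
#' classify_block(c(15, 14), 15, threshold = 0.95)
#' @export
classify_block <- function(presence_count, n_genomes, threshold = 0.95) {
  check_threshold(threshold)
  if (length(n_genomes) != 1 || is.na(n_genomes) || n_genomes < 1) {
    abort_pav("n_genomes must be a single integer >= 1")
  }
  presence_count <- as.integer(presence_count)
  if (anyNA(presence_count) || any(presence_count < 1)) {
    abort_pav("presence_count must be >= 1 (a block absent everywhere is invalid)")
  }
  if (any(presence_count > n_genomes)) {
    abort_pav("presence_count cannot exceed n_genomes")
  }
  frac <- presence_count / n_genomes
  tibble::tibble(
    presence_count = presence_count,
    n_genomes = as.integer(n_genomes),
    presence_fraction = frac,
    status = ifelse(frac >= threshold, "CORE", "VARIABLE")
  )
}

#' Classify every block of a PAV table
#'
#' @param pav A `pav_df` object (see [as_pav()]).
#' @param threshold Presence fraction in (0, 1]; inclusive boundary. Default
#'   0.95.
#' @return A tibble with one row per block, in block order: `block_id`,
#'   `panchromosome`, `presence_count`, `presence_fraction`, `status`.
#' @examples
#' pav <- simulate_pav(n_genomes = 5, n_blocks = 20, seed = 1)
#' classify_pav(pav, threshold = 0.8)
#' @export
classify_pav <- function(pav, threshold = 0.95) {
  check_threshold(threshold)
  cm <- pav_counts(pav)
  pc <- as.integer(rowSums(cm >= 1L))
  calls <- classify_block(pc, length(pav_genomes(pav)), threshold)
  dplyr::bind_cols(
    tibble::tibble(block_id = pav$block_id, panchromosome = pav$panchromosome),
    calls
  )
}

check_threshold <- function(threshold) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0 || threshold > 1) {
    abort_pav("threshold must be a single value in (0, 1]")
  }
  invisible(threshold)
}

#' Lay blocks out contiguously on the pan-reference
#'
#' Given block widths in bp, computes the canonical contiguous tiling of the
#' flattened pan-reference: starts are cumulative sums beginning at 0, stops
#' are start + length (0-based, half-open).
#'
#' @param block_lengths Ordered vector of positive integer block widths (bp).
#' @return A tibble with columns `start` and `stop`, one row per block; empty
#'   input gives an empty tibble.
#' @examples
#' recompute_coordinates(c(4, 3, 5))
#' @export
recompute_coordinates <- function(block_lengths) {
  if (length(block_lengths) == 0) {
    return(tibble::tibble(start = integer(), stop = integer()))
  }
  block_lengths <- as.integer(block_lengths)
  if (anyNA(block_lengths) || any(block_lengths < 1)) {
    abort_pav("block lengths must be positive integers")
  }
  stop <- cumsum(block_lengths)
  tibble::tibble(start = c(0L, stop[-length(stop)]), stop = stop)
}

#' Per-block repetition counts
#'
#' The repeat count of a block is the number of other positions in the
#' pangenome listed in its `similar` field (0 when the block is unique). This
#' feeds the repetition summary track.
#'
#' @param pav A `pav_df` object.
#' @return A tibble `block_id`, `panchromosome`, `n_repeats`, in block order.
#' @export
repetition_profile <- function(pav) {
  tibble::tibble(
    block_id = pav$block_id,
    panchromosome = pav$panchromosome,
    n_repeats = vapply(parse_similar(pav$similar), nrow, integer(1))
  )
}

# "." or "" -> empty; else semicolon-joined "panchromosome:start" tokens.
parse_similar <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || cell == "." || cell == "") {
      return(tibble::tibble(panchromosome = character(), start = integer()))
    }
    toks <- strsplit(cell, ";", fixed = TRUE)[[1]]
    parts <- strsplit(toks, ":", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2
    if (any(bad)) abort_pav(sprintf("malformed similar-position token: %s",
                                    toks[bad][1]))
    tibble::tibble(
      panchromosome = vapply(parts, `[[`, character(1), 1),
      start = as.integer(vapply(parts, `[[`, character(1), 2))
    )
  })
}

serialize_similar <- function(positions) {
  vapply(positions, function(p) {
    if (nrow(p) == 0) "." else paste(sprintf("%s:%d", p$panchromosome, p$start),
                                     collapse = ";")
  }, character(1))
}
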