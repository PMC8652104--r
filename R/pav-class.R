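# The pav table: a tibble with one row per pangenomic block.
#
# Fixed leading columns describe the block on the flattened pan-reference
# (0-based, half-open coordinates); every remaining column is a genome whose
# cells are non-negative integer copy counts (0 = absent).

PAV_FIXED_COLS <- c("panchromosome", "start", "stop", "block_id",
                    "similar", "function_note")

#' Build a pangenome presence/absence (PAV) table
#'
#' A PAV table holds one row per pangenomic block, ordered along the flattened
#' pan-reference, plus one integer column per genome giving the copy count of
#' that block in that genome (0 meaning absent). It is a tibble subclass, so
#' all dplyr/tidyr verbs work on it; use [as_pav()] to restore the class after
#' reshaping.
#'
#' @param x A data frame with the six fixed block columns (`panchromosome`,
#'   `start`, `stop`, `block_id`, `similar`, `function_note`) plus one column
#'   per genome. Missing `similar`/`function_note` columns are filled with
#'   `"."` and `""` respectively.
#' @param genomes Character vector naming the genome columns. Defaults to all
#'   non-fixed columns, in order.
#'
#' @return A `pav_df` tibble, rows sorted by (panchromosome, start), with the
#'   genome names recorded in the `"genomes"` attribute.
#'
#' @details Coordinates follow the BED convention: `start` is 0-based
#'   inclusive, `stop` exclusive. Blocks must not overlap within a
#'   panchromosome (gaps are allowed). Every block must be present (count
#'   >= 1) in at least one genome. The `similar` column records repeated
#'   occurrences of the block elsewhere in the pangenome as semicolon-joined
#'   `panchromosome:start` tokens, `"."` when the block is unique.
#'
#' @examples
#' pav <- as_pav(tibble::tibble(
#'   panchromosome = "pan_1", start = c(0L, 4L), stop = c(4L, 7L),
#'   block_id = c("b1", "b2"), similar = ".", function_note = "",
#'   gA = c(1L, 1L), gB = c(1L, 0L)
#' ))
#' pav_genomes(pav)
#' @export
as_pav <- function(x, genomes = NULL) {
  x <- tibble::as_tibble(x)
  if (!"similar" %in% names(x)) x$similar <- "."
  if (!"function_note" %in% names(x)) x$function_note <- ""
  missing_cols <- setdiff(PAV_FIXED_COLS, names(x))
  if (length(missing_cols) > 0) {
    abort_pav(sprintf("missing required block column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  if (is.null(genomes)) genomes <- setdiff(names(x), PAV_FIXED_COLS)
  x <- x[, c(PAV_FIXED_COLS, genomes)]
  x$panchromosome <- as.character(x$panchromosome)
  x$start <- as.integer(x$start)
  x$stop <- as.integer(x$stop)
  x$block_id <- as.character(x$block_id)
  x$similar <- as.character(x$similar)
  x$function_note <- as.character(x$function_note)
  for (g in genomes) x[[g]] <- as.integer(x[[g]])
  x <- x[order(x$panchromosome, x$start), , drop = FALSE]
  out <- new_pav(x, genomes)
  validate_pav(out)
  out
}

new_pav <- function(x, genomes) {
  structure(tibble::as_tibble(x),
            genomes = as.character(genomes),
            class = c("pav_df", class(tibble::tibble())))
}

#' @rdname as_pav
#' @param pav A `pav_df` object (or any data frame with the fixed columns).
#' @export
pav_genomes <- function(pav) {
  g <- attr(pav, "genomes")
  if (is.null(g)) g <- setdiff(names(pav), PAV_FIXED_COLS)
  g
}

#' @rdname as_pav
#' @export
pav_panchromosomes <- function(pav) unique(pav$panchromosome)

# Counts as an integer matrix, blocks x genomes.
pav_counts <- function(pav) {
  g <- pav_genomes(pav)
  m <- as.matrix(as.data.frame(pav[, g, drop = FALSE]))
  storage.mode(m) <- "integer"
  rownames(m) <- pav$block_id
  m
}

#' Validate the invariants of a PAV table
#'
#' Checks coordinates (positive width, no overlap within a panchromosome),
#' block identifiers (unique, non-empty), genome names (unique, non-empty,
#' distinct from the fixed columns) and counts (non-negative integers, no
#' missing values, every block present in at least one genome). Aborts with an
#' informative message on the first violated invariant.
#'
#' @param pav A `pav_df` object.
#' @return `pav`, invisibly, if valid.
#' @export
validate_pav <- function(pav) {
  g <- pav_genomes(pav)
  if (length(g) == 0) abort_pav("a PAV table needs at least one genome column")
  if (anyDuplicated(g) || any(!nzchar(g))) {
    abort_pav("genome names must be unique and non-empty")
  }
  if (any(g %in% PAV_FIXED_COLS)) {
    abort_pav("genome names may not collide with the fixed block columns")
  }
  if (any(!nzchar(pav$block_id)) || anyNA(pav$block_id)) {
    abort_pav("block_id must be non-empty")
  }
  if (anyDuplicated(pav$block_id)) {
    dup <- unique(pav$block_id[duplicated(pav$block_id)])
    abort_pav(sprintf("duplicate block_id: %s", paste(dup, collapse = ", ")))
  }
  if (anyNA(pav$start) || anyNA(pav$stop) || any(pav$stop <= pav$start)) {
    abort_pav("every block needs stop > start")
  }
  by_pc <- split(seq_len(nrow(pav)), pav$panchromosome)
  for (idx in by_pc) {
    s <- pav$start[idx]; e <- pav$stop[idx]
    o <- order(s)
    if (length(idx) > 1 && any(s[o][-1] < e[o][-length(o)])) {
      abort_pav("blocks overlap within a panchromosome")
    }
  }
  cm <- pav_counts(pav)
  if (anyNA(cm) || any(cm < 0)) {
    abort_pav("counts must be non-negative integers")
  }
  if (nrow(cm) > 0 && any(rowSums(cm >= 1L) == 0)) {
    bad <- pav$block_id[rowSums(cm >= 1L) == 0]
    abort_pav(sprintf("block absent from every genome: %s",
                      paste(bad, collapse = ", ")))
  }
  invisible(pav)
}

abort_pav <- function(message, class = "panpav_error", ...) {
  rlang::abort(message, class = class, ...)
}

#' @export
print.pav_df <- function(x, ...) {
  g <- pav_genomes(x)
  cat(sprintf("# A PAV table: %d blocks x %d genomes (%d panchromosome%s)\n",
              nrow(x), length(g), length(unique(x$panchromosome)),
              if (length(unique(x$panchromosome)) == 1) "" else "s"))
  NextMethod()
}

#' Tidy a PAV table into one row per (block, genome) cell
#'
#' @param x A `pav_df` object.
#' @param ... Unused.
#' @return A tibble with columns `panchromosome`, `block_id`, `start`, `stop`,
#'   `genome`, `count` and logical `present` (`count >= 1`).
#' @export
tidy.pav_df <- function(x, ...) {
  g <- pav_genomes(x)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("panchromosome", "block_id", "start", "stop", g)],
    cols = dplyr::all_of(g), names_to = "genome", values_to = "count"
  )
  long$present <- long$count >= 1L
  long
}

#' One-row summary of a PAV table
#'
#' @param x A `pav_df` object.
#' @param threshold Core/variable presence-fraction threshold used for the
#'   core and variable block counts (default 0.95).
#' @param ... Unused.
#' @return A one-row tibble: genome, block and panchromosome counts, total
#'   pan-reference span in bp, and core/variable block counts at `threshold`.
#' @export
glance.pav_df <- function(x, threshold = 0.95, ...) {
  calls <- classify_pav(x, threshold = threshold)
  tibble::tibble(
    n_genomes = length(pav_genomes(x)),
    n_blocks = nrow(x),
    n_panchromosomes = length(unique(x$panchromosome)),
    total_bp = sum(x$stop - x$start),
    threshold = threshold,
    n_core = sum(calls$status == "CORE"),
    n_variable = sum(calls$status == "VARIABLE")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
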