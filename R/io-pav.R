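# PAV matrix file dialect: tab-separated, mandatory header
#   #Chromosome  Start  Stop  BlockID  SimilarBlocks  Function  <genome...>
# then one row per block; genome cells are integer copy counts (0 = absent).
# Coordinates on disk are the same 0-based half-open values held in memory.

PAV_HEADER_FIXED <- c("#Chromosome", "Start", "Stop", "BlockID",
                      "SimilarBlocks", "Function")

issue_tbl <- function(severity = character(), code = character(),
                      message = character(), line = integer()) {
  tibble::tibble(severity = severity, code = code, message = message,
                 line = as.integer(line))
}

add_issue <- function(issues, severity, code, message, line = NA_integer_) {
  dplyr::bind_rows(issues, issue_tbl(severity, code, message, line))
}

# Parse PAV lines into list(pav = <pav_df or NULL>, issues = <tibble>).
# All problems are reported, never thrown, so the same core serves both
# read_pav() (which aborts on ERRORs) and validate_pangenome_file().
parse_pav <- function(lines) {
  issues <- issue_tbl()
  lines <- sub("\r$", "", lines)
  if (length(lines) > 0 && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) {
    return(list(pav = NULL,
                issues = add_issue(issues, "ERROR", "EMPTY_FILE",
                                   "file holds no lines")))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < length(PAV_HEADER_FIXED) + 1 ||
      !identical(header[seq_along(PAV_HEADER_FIXED)], PAV_HEADER_FIXED)) {
    return(list(pav = NULL, issues = add_issue(
      issues, "ERROR", "BAD_HEADER",
      sprintf("header must start '%s' followed by genome names",
              paste(PAV_HEADER_FIXED, collapse = "\\t")), 1L)))
  }
  genomes <- header[-seq_along(PAV_HEADER_FIXED)]
  if (anyDuplicated(genomes) || any(!nzchar(genomes))) {
    issues <- add_issue(issues, "ERROR", "BAD_GENOME_NAMES",
                        "genome names must be unique and non-empty", 1L)
  }
  body <- lines[-1]
  ncol_expect <- length(header)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad_ncol <- which(nf != ncol_expect)
  for (i in bad_ncol) {
    issues <- add_issue(issues, "ERROR", "BAD_COLUMN_COUNT",
                        sprintf("expected %d fields, found %d",
                                ncol_expect, nf[i]), i + 1L)
  }
  keep <- setdiff(seq_along(fields), bad_ncol)
  if (length(keep) == 0) {
    if (length(body) == 0 && nrow(issues) == 0) {
      # header-only file: a valid, empty matrix is not representable (it
      # needs >= 1 genome presence per block, vacuously true with 0 blocks)
      empty <- tibble::as_tibble(
        stats::setNames(rep(list(integer()), length(genomes)), genomes))
      pav <- dplyr::bind_cols(
        tibble::tibble(panchromosome = character(), start = integer(),
                       stop = integer(), block_id = character(),
                       similar = character(), function_note = character()),
        empty)
      return(list(pav = new_pav(pav, genomes), issues = issues))
    }
    return(list(pav = NULL, issues = issues))
  }
  m <- matrix(unlist(fields[keep], use.names = FALSE),
              nrow = length(keep), byrow = TRUE)
  line_no <- keep + 1L
  start <- suppressWarnings(as.integer(m[, 2]))
  stop_ <- suppressWarnings(as.integer(m[, 3]))
  for (i in which(is.na(start) | is.na(stop_))) {
    issues <- add_issue(issues, "ERROR", "BAD_COORDINATE",
                        "Start/Stop must be integers", line_no[i])
  }
  for (i in which(!is.na(start) & !is.na(stop_) & stop_ <= start)) {
    issues <- add_issue(issues, "ERROR", "BAD_INTERVAL",
                        sprintf("stop (%d) must exceed start (%d)",
                                stop_[i], start[i]), line_no[i])
  }
  ids <- m[, 4]
  for (i in which(!nzchar(ids))) {
    issues <- add_issue(issues, "ERROR", "EMPTY_BLOCK_ID",
                        "BlockID must be non-empty", line_no[i])
  }
  for (i in which(duplicated(ids))) {
    issues <- add_issue(issues, "ERROR", "DUPLICATE_BLOCK_ID",
                        sprintf("block_id '%s' already seen", ids[i]),
                        line_no[i])
  }
  cnt_chr <- m[, -seq_len(6), drop = FALSE]
  cnt <- suppressWarnings(matrix(as.integer(cnt_chr), nrow = nrow(cnt_chr)))
  bad_cells <- which(is.na(cnt) | cnt < 0, arr.ind = TRUE)
  for (r in unique(bad_cells[, 1])) {
    issues <- add_issue(issues, "ERROR", "BAD_COUNT",
                        sprintf("genome cells must be non-negative integers (genome '%s')",
                                genomes[bad_cells[bad_cells[, 1] == r, 2][1]]),
                        line_no[r])
  }
  ok_rows <- !seq_len(nrow(m)) %in% bad_cells[, 1]
  if (any(ok_rows)) {
    allzero <- which(ok_rows & rowSums(cnt >= 1L) == 0)
    for (i in allzero) {
      issues <- add_issue(issues, "ERROR", "ABSENT_EVERYWHERE",
                          sprintf("block '%s' is absent from every genome", ids[i]),
                          line_no[i])
    }
  }
  # overlap check per panchromosome, on rows with sane coordinates
  coord_ok <- !is.na(start) & !is.na(stop_) & stop_ > start
  for (pc in unique(m[coord_ok, 1])) {
    sel <- which(coord_ok & m[, 1] == pc)
    o <- sel[order(start[sel])]
    if (length(o) > 1) {
      ov <- which(start[o][-1] < stop_[o][-length(o)])
      for (k in ov) {
        issues <- add_issue(issues, "ERROR", "BLOCK_OVERLAP",
                            sprintf("block '%s' overlaps the previous block on %s",
                                    ids[o[k + 1]], pc), line_no[o[k + 1]])
      }
    }
  }
  if (any(issues$severity == "ERROR")) return(list(pav = NULL, issues = issues))
  df <- tibble::tibble(
    panchromosome = m[, 1], start = start, stop = stop_, block_id = ids,
    similar = m[, 5], function_note = m[, 6]
  )
  for (j in seq_along(genomes)) df[[genomes[j]]] <- cnt[, j]
  df <- df[order(df$panchromosome, df$start), , drop = FALSE]
  list(pav = new_pav(df, genomes), issues = issues)
}

#' Read a PAV matrix file
#'
#' Reads the tab-separated, BED-like presence/absence matrix: six fixed
#' columns (`#Chromosome`, `Start`, `Stop`, `BlockID`, `SimilarBlocks`,
#' `Function`) followed by one integer copy-count column per genome. Genome
#' order is taken from the header. See [write_pav()] for the canonical form.
#'
#' @param file Path to the file (or a connection readable by
#'   [readr::read_lines()]).
#' @return A `pav_df` tibble (see [as_pav()]).
#' @seealso [validate_pangenome_file()] to obtain the full issue report
#'   without aborting.
#' @export
read_pav <- function(file) {
  parsed <- parse_pav(input_lines(file))
  report_or_abort(parsed$issues, "PAV")
  parsed$pav
}

#' Write a PAV matrix file in canonical form
#'
#' Canonical form: blocks sorted by (panchromosome, start); dialect column
#' order; counts as plain integers; `"\n"` line endings; UTF-8. Reading the
#' output back with [read_pav()] recovers an identical table.
#'
#' @param pav A `pav_df` object.
#' @param file Output path.
#' @return `pav`, invisibly.
#' @export
write_pav <- function(pav, file) {
  readr::write_lines(format_pav(pav), file)
  invisible(pav)
}

#' @rdname write_pav
#' @return For `format_pav`, a character vector of file lines.
#' @export
format_pav <- function(pav) {
  validate_pav(pav)
  g <- pav_genomes(pav)
  pav <- pav[order(pav$panchromosome, pav$start), , drop = FALSE]
  header <- paste(c(PAV_HEADER_FIXED, g), collapse = "\t")
  cols <- c(list(pav$panchromosome, as.character(pav$start),
                 as.character(pav$stop), pav$block_id, pav$similar,
                 pav$function_note),
            lapply(g, function(x) as.character(pav[[x]])))
  if (nrow(pav) == 0) return(header)
  c(header, do.call(paste, c(cols, sep = "\t")))
}

report_or_abort <- function(issues, what) {
  err <- issues[issues$severity == "ERROR", , drop = FALSE]
  if (nrow(err) > 0) {
    msg <- paste(sprintf("[%s%s] %s", err$code,
                         ifelse(is.na(err$line), "",
                                sprintf(" line %d", err$line)),
                         err$message),
                 collapse = "\n")
    abort_pav(sprintf("invalid %s input:\n%s", what, msg),
              class = "panpav_validation_error", issues = issues)
  }
  invisible(issues)
}
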