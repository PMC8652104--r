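# GFF3 annotations on pangenomic coordinates, grouped into "cards":
# one card per gene (or orphan feature), carrying its mRNA/exon children and
# functional text. GFF3 is 1-based inclusive on disk; internally everything
# is 0-based half-open, like the PAV table.

# Parse GFF3 lines into list(features = tibble, issues = tibble).
parse_gff3 <- function(lines) {
  issues <- issue_tbl()
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0 || !grepl("^##gff-version", lines[1])) {
    issues <- add_issue(issues, "ERROR", "MISSING_GFF_VERSION",
                        "first line must be a ##gff-version directive", 1L)
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  feats <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      issues <- add_issue(issues, "ERROR", "BAD_GFF_LINE",
                          sprintf("expected 9 tab-separated columns, found %d",
                                  length(f)), i)
      next
    }
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || end1 < start1) {
      issues <- add_issue(issues, "ERROR", "BAD_GFF_COORDS",
                          "start/end must be integers with end >= start", i)
      next
    }
    if (!f[7] %in% c("+", "-", ".")) {
      issues <- add_issue(issues, "ERROR", "BAD_STRAND",
                          sprintf("strand '%s' not one of +, -, .", f[7]), i)
      next
    }
    attrs <- parse_gff3_attributes(f[9])
    feats[[k]] <- tibble::tibble(
      feature_id = attrs[["ID"]] %||% sprintf("feature_line_%d", i),
      panchromosome = f[1],
      start = start1 - 1L,      # to 0-based half-open
      stop = end1,
      strand = f[7],
      feature_type = f[3],
      parent_id = attrs[["Parent"]] %||% "",
      function_text = attrs[["Note"]] %||% attrs[["product"]] %||% "",
      attributes = list(attrs),
      line = i
    )
  }
  feats <- dplyr::bind_rows(feats)
  if (nrow(feats) > 0 && anyDuplicated(feats$feature_id)) {
    dup <- unique(feats$feature_id[duplicated(feats$feature_id)])
    issues <- add_issue(issues, "ERROR", "DUPLICATE_FEATURE_ID",
                        sprintf("duplicate ID attribute: %s",
                                paste(dup, collapse = ", ")))
  }
  list(features = feats, issues = issues)
}

parse_gff3_attributes <- function(x) {
  if (is.na(x) || x == "." || !nzchar(x)) return(list())
  pairs <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  pairs <- pairs[lengths(pairs) == 2]
  vals <- lapply(pairs, function(p) utils::URLdecode(p[[2]]))
  stats::setNames(vals, vapply(pairs, `[[`, character(1), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read GFF3 annotations into cards on pangenomic coordinates
#'
#' Parses a GFF3 file whose `seqid` column names panchromosomes of the PAV
#' table, converts coordinates from 1-based inclusive to 0-based half-open,
#' and groups features into annotation cards: one per gene, holding its
#' mRNA/exon descendants (via `Parent` attributes) and functional text.
#'
#' Features on panchromosomes absent from `pav` are dropped with a warning.
#' A child whose `Parent` is missing from the file is kept as an orphan card,
#' with a warning.
#'
#' @param file Path to a GFF3 file.
#' @param pav A `pav_df` object giving the known panchromosomes.
#' @return A tibble of cards: `gene_id`, `panchromosome`, `start`, `stop`
#'   (card span, covering all children), `strand`, `function_text`,
#'   `n_children` and a `children` list-column of feature tibbles.
#' @export
read_annotations <- function(file, pav) {
  parsed <- parse_gff3(input_lines(file))
  report_or_abort(parsed$issues, "GFF3")
  feats <- parsed$features
  if (nrow(feats) == 0) return(empty_cards())

  known <- pav_panchromosomes(pav)
  drop <- !feats$panchromosome %in% known
  if (any(drop)) {
    rlang::warn(sprintf(
      "dropped %d feature(s) on panchromosome(s) not in the PAV table: %s",
      sum(drop), paste(unique(feats$panchromosome[drop]), collapse = ", ")))
    feats <- feats[!drop, , drop = FALSE]
  }
  if (nrow(feats) == 0) return(empty_cards())

  # resolve each feature to its top-level ancestor
  parent_of <- stats::setNames(feats$parent_id, feats$feature_id)
  known_ids <- feats$feature_id
  orphans <- character()
  top_of <- vapply(feats$feature_id, function(id) {
    cur <- id
    repeat {
      p <- parent_of[[cur]]
      if (!nzchar(p)) return(cur)
      if (!p %in% known_ids) {
        orphans <<- c(orphans, cur)
        return(cur)
      }
      cur <- p
    }
  }, character(1))
  if (length(orphans) > 0) {
    rlang::warn(sprintf("feature(s) with missing Parent kept as orphan card(s): %s",
                        paste(unique(orphans), collapse = ", ")))
  }

  top_of <- unname(top_of)
  cards <- lapply(split(seq_len(nrow(feats)), top_of), function(idx) {
    root_id <- top_of[idx][1]
    root <- feats[feats$feature_id == root_id, , drop = FALSE][1, ]
    kids <- feats[idx, , drop = FALSE]
    kids <- kids[kids$feature_id != root_id, , drop = FALSE]
    fn <- root$function_text
    if (!nzchar(fn) && nrow(kids) > 0) {
      fn <- c(kids$function_text[nzchar(kids$function_text)], "")[1]
    }
    tibble::tibble(
      gene_id = root_id,
      panchromosome = root$panchromosome,
      start = min(root$start, kids$start),
      stop = max(root$stop, kids$stop),
      strand = root$strand,
      function_text = fn,
      n_children = nrow(kids),
      children = list(kids[, c("feature_id", "feature_type", "panchromosome",
                               "start", "stop", "strand", "parent_id")])
    )
  })
  out <- dplyr::bind_rows(cards)
  out[order(out$panchromosome, out$start, out$gene_id), , drop = FALSE]
}

empty_cards <- function() {
  tibble::tibble(gene_id = character(), panchromosome = character(),
                 start = integer(), stop = integer(), strand = character(),
                 function_text = character(), n_children = integer(),
                 children = list())
}
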