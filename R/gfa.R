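# GFA1 variation graphs: S lines declare segments (sequence or LN:i length),
# P lines declare genome paths through them. Linearization flattens the graph
# onto a pan-reference: the backbone path fixes the block order and every
# other segment is inserted after its anchor (the backbone segment that most
# recently precedes it in the earliest path carrying it).

# Parse GFA1 lines into list(graph = <gfa_graph or NULL>, issues = tibble).
parse_gfa_lines <- function(lines) {
  issues <- issue_tbl()
  lines <- sub("\r$", "", lines)
  seg_ids <- character(); seg_len <- integer()
  path_names <- character(); path_steps <- list(); path_lines <- integer()
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rec <- f[1]
    if (rec == "S") {
      if (length(f) < 3) {
        issues <- add_issue(issues, "ERROR", "BAD_S_LINE",
                            "S line needs a name and a sequence field", i)
        next
      }
      len <- NA_integer_
      if (f[3] != "*") {
        len <- nchar(f[3])
      } else {
        ln_tag <- grep("^LN:i:", f[-(1:3)], value = TRUE)
        if (length(ln_tag) > 0) {
          len <- suppressWarnings(as.integer(sub("^LN:i:", "", ln_tag[1])))
        }
      }
      if (is.na(len)) {
        issues <- add_issue(issues, "ERROR", "NO_SEGMENT_LENGTH",
                            sprintf("segment '%s' has neither a sequence nor an LN:i tag",
                                    f[2]), i)
        next
      }
      if (f[2] %in% seg_ids) {
        issues <- add_issue(issues, "ERROR", "DUPLICATE_SEGMENT",
                            sprintf("segment '%s' declared twice", f[2]), i)
        next
      }
      seg_ids <- c(seg_ids, f[2]); seg_len <- c(seg_len, len)
    } else if (rec == "P") {
      if (length(f) < 3 || !nzchar(f[3])) {
        issues <- add_issue(issues, "ERROR", "BAD_P_LINE",
                            "P line needs a name and a segment list", i)
        next
      }
      steps <- strsplit(f[3], ",", fixed = TRUE)[[1]]
      ok <- grepl("^.+[+-]$", steps)
      if (!all(ok)) {
        issues <- add_issue(issues, "ERROR", "BAD_P_LINE",
                            sprintf("malformed path step '%s' (need <segment><+/->)",
                                    steps[!ok][1]), i)
        next
      }
      if (f[2] %in% path_names) {
        issues <- add_issue(issues, "ERROR", "DUPLICATE_PATH",
                            sprintf("path '%s' declared twice", f[2]), i)
        next
      }
      path_names <- c(path_names, f[2])
      path_steps <- c(path_steps, list(tibble::tibble(
        segment_id = sub("[+-]$", "", steps),
        orientation = substring(steps, nchar(steps))
      )))
      path_lines <- c(path_lines, i)
    }
    # H, L, C and other records are tolerated and ignored for ordering
  }
  for (k in seq_along(path_names)) {
    missing <- setdiff(path_steps[[k]]$segment_id, seg_ids)
    if (length(missing) > 0) {
      issues <- add_issue(issues, "ERROR", "UNDECLARED_SEGMENT",
                          sprintf("path '%s' references undeclared segment(s): %s",
                                  path_names[k], paste(missing, collapse = ", ")),
                          path_lines[k])
    }
  }
  if (any(issues$severity == "ERROR")) return(list(graph = NULL, issues = issues))
  graph <- structure(
    list(segments = tibble::tibble(segment_id = seg_ids, length = seg_len),
         paths = tibble::tibble(path_name = path_names, steps = path_steps)),
    class = "gfa_graph")
  list(graph = graph, issues = issues)
}

#' Read a GFA1 variation graph
#'
#' Reads S (segment) and P (path) records from a GFA1 file. Segment lengths
#' come from the sequence field or, when the sequence is `*`, from the `LN:i`
#' tag. L lines are tolerated and ignored: block ordering is derived from
#' paths alone.
#'
#' @param file Path to a GFA1 file.
#' @return A `gfa_graph` object: a list with a `segments` tibble
#'   (`segment_id`, `length`) and a `paths` tibble (`path_name`, `steps`
#'   list-column of (`segment_id`, `orientation`) tibbles).
#' @export
read_gfa <- function(file) {
  parsed <- parse_gfa_lines(input_lines(file))
  report_or_abort(parsed$issues, "GFA")
  parsed$graph
}

#' @export
print.gfa_graph <- function(x, ...) {
  cat(sprintf("# A GFA1 graph: %d segments, %d paths\n",
              nrow(x$segments), nrow(x$paths)))
  invisible(x)
}

#' Linearize a GFA variation graph into a PAV table
#'
#' Flattens a path-annotated variation graph onto a linear pan-reference. The
#' backbone path(s) fix the block order; every segment not on the backbone is
#' inserted immediately after its anchor — the backbone segment that most
#' recently precedes it, taken from the earliest path (in file order) in which
#' a backbone segment does precede it. Segments never preceded by a backbone
#' segment go in front of the first backbone block. Several segments sharing
#' an anchor keep their within-path order. Pan-coordinates are the contiguous
#' tiling of the ordered block lengths ([recompute_coordinates()]).
#'
#' Genomes are the path names. When path names contain `#`, the prefix before
#' the first `#` is the genome and each backbone path becomes one
#' panchromosome (labelled by the path name); `backbone` then names the
#' genome. Without `#`, `backbone` names a single path and the lone
#' panchromosome is called `"pan_1"`.
#'
#' The cell for (block, genome) counts how many times the genome's path(s)
#' traverse that segment, in either orientation.
#'
#' @param graph A `gfa_graph` from [read_gfa()].
#' @param backbone Name of the backbone genome (or path, when names carry no
#'   `#`).
#' @return A `pav_df` with one block per traversed segment
#'   (`block_id` = segment id). The segment-to-coordinate sidecar table is
#'   attached and available through [segment_map()].
#' @export
linearize_gfa <- function(graph, backbone) {
  paths <- graph$paths
  if (nrow(paths) == 0) abort_pav("graph declares no paths")
  if (any(vapply(paths$steps, nrow, integer(1)) == 0)) {
    abort_pav("path traversing zero segments")
  }
  has_hash <- grepl("#", paths$path_name, fixed = TRUE)
  if (any(has_hash)) {
    genome_of <- sub("#.*$", "", paths$path_name)
    backbone_paths <- which(genome_of == backbone)
    pc_label <- paths$path_name
  } else {
    genome_of <- paths$path_name
    backbone_paths <- which(paths$path_name == backbone)
    pc_label <- rep("pan_1", nrow(paths))
  }
  if (length(backbone_paths) == 0) {
    abort_pav(sprintf("backbone '%s' names no path of the graph", backbone))
  }
  genomes <- unique(genome_of)

  seg_len <- stats::setNames(graph$segments$length, graph$segments$segment_id)
  traversed <- unique(unlist(lapply(paths$steps, `[[`, "segment_id")))

  # backbone blocks, per panchromosome, first occurrence wins
  bb_segments <- character(); bb_pc <- character()
  for (k in backbone_paths) {
    segs <- unique(paths$steps[[k]]$segment_id)
    segs <- setdiff(segs, bb_segments)
    bb_segments <- c(bb_segments, segs)
    bb_pc <- c(bb_pc, rep(pc_label[k], length(segs)))
  }
  is_bb <- traversed %in% bb_segments

  # anchor of each non-backbone segment: earliest path (file order) in which
  # a backbone segment precedes it; within that path, the first occurrence
  anchor <- list()
  for (k in seq_len(nrow(paths))) {
    segs <- paths$steps[[k]]$segment_id
    last_bb <- NA_character_
    for (pos in seq_along(segs)) {
      s <- segs[pos]
      if (s %in% bb_segments) {
        last_bb <- s
      } else if (is.null(anchor[[s]]) || is.na(anchor[[s]]$anchor)) {
        cand <- list(anchor = last_bb, path = k, pos = pos)
        if (is.null(anchor[[s]]) || !is.na(cand$anchor)) anchor[[s]] <- cand
      }
    }
  }
  floating <- names(anchor)
  anchor_seg <- vapply(anchor, function(a) a$anchor, character(1))
  anchor_path <- vapply(anchor, function(a) a$path, integer(1))
  anchor_pos <- vapply(anchor, function(a) a$pos, integer(1))
  ord <- order(anchor_path, anchor_pos)
  floating <- floating[ord]; anchor_seg <- anchor_seg[ord]

  block_order <- character(); block_pc <- character()
  front <- floating[is.na(anchor_seg)]
  if (length(front) > 0) {
    block_order <- front
    block_pc <- rep(bb_pc[1], length(front))
  }
  for (b in seq_along(bb_segments)) {
    block_order <- c(block_order, bb_segments[b])
    block_pc <- c(block_pc, bb_pc[b])
    after <- floating[!is.na(anchor_seg) & anchor_seg == bb_segments[b]]
    block_order <- c(block_order, after)
    block_pc <- c(block_pc, rep(bb_pc[b], length(after)))
  }
  stopifnot(setequal(block_order, traversed),
            !anyDuplicated(block_order))

  # counts: traversals per genome, orientation ignored
  cnt <- matrix(0L, nrow = length(block_order), ncol = length(genomes),
                dimnames = list(block_order, genomes))
  for (k in seq_len(nrow(paths))) {
    tab <- table(paths$steps[[k]]$segment_id)
    cnt[names(tab), genome_of[k]] <- cnt[names(tab), genome_of[k]] +
      as.integer(tab)
  }

  # contiguous pan-coordinates within each panchromosome
  df_list <- lapply(unique(block_pc), function(pc) {
    sel <- block_pc == pc
    ids <- block_order[sel]
    coords <- recompute_coordinates(seg_len[ids])
    tibble::tibble(panchromosome = pc, start = coords$start,
                   stop = coords$stop, block_id = ids,
                   similar = ".", function_note = "")
  })
  df <- dplyr::bind_rows(df_list)
  for (g in genomes) df[[g]] <- as.integer(cnt[df$block_id, g])
  pav <- as_pav(df, genomes)
  attr(pav, "segment_map") <- tibble::tibble(
    segment_id = df$block_id, panchromosome = df$panchromosome,
    start = df$start)
  pav
}

#' Segment-to-coordinate sidecar of a linearized graph
#'
#' @param pav A `pav_df` produced by [linearize_gfa()].
#' @return A tibble mapping `segment_id` to (`panchromosome`, `start`).
#' @export
segment_map <- function(pav) {
  sm <- attr(pav, "segment_map")
  if (is.null(sm)) {
    abort_pav("no segment map attached; was this table made by linearize_gfa()?")
  }
  sm
}
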