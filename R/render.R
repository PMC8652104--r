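# Static rendering of the linear multi-track view: an SVG document with (top
# to bottom) an optional panchromosome overview, the annotation beeswarm, a
# coordinate/width track, the core-vs-variable track, the repetition track and
# one presence/absence row per genome. Rendering is a pure function of its
# inputs: identical calls produce byte-identical SVG.

#' View configuration for the linear track rendering
#'
#' @param panchromosome Panchromosome to draw.
#' @param region Numeric `c(start, stop)` in pan-bp, or `NULL` for the whole
#'   panchromosome.
#' @param px_per_bp Horizontal zoom, pixels per base pair (> 0). Default 0.01
#'   (1 px per 100 bp).
#' @param threshold Core/variable presence-fraction threshold (default 0.95).
#' @param genome_order Optional `genome_ordering` (or character permutation);
#'   default matrix order.
#' @param show_overview,show_annotations,show_coordinates,show_repeats Track
#'   toggles.
#' @param core_col,variable_col,absent_col Fill colours: core blocks orange,
#'   variable blue (colour-blind-safe defaults), absent cells light grey.
#' @param cell_height Genome row height in px.
#' @param label_px Width of the left genome-label gutter in px.
#' @return A `view_config` list.
#' @export
view_config <- function(panchromosome = NULL, region = NULL, px_per_bp = 0.01,
                        threshold = 0.95, genome_order = NULL,
                        show_overview = FALSE, show_annotations = TRUE,
                        show_coordinates = TRUE, show_repeats = TRUE,
                        core_col = "#E69F00", variable_col = "#56B4E9",
                        absent_col = "#DDDDDD", cell_height = 14,
                        label_px = 100) {
  if (px_per_bp <= 0) abort_pav("px_per_bp must be > 0")
  check_threshold(threshold)
  structure(list(panchromosome = panchromosome, region = region,
                 px_per_bp = px_per_bp, threshold = threshold,
                 genome_order = genome_order, show_overview = show_overview,
                 show_annotations = show_annotations,
                 show_coordinates = show_coordinates,
                 show_repeats = show_repeats, core_col = core_col,
                 variable_col = variable_col, absent_col = absent_col,
                 cell_height = cell_height, label_px = label_px),
            class = "view_config")
}

fmt_px <- function(x) sprintf("%.2f", x)

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

svg_rect <- function(x, y, w, h, fill, extra = "") {
  sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
          fmt_px(x), fmt_px(y), fmt_px(w), fmt_px(h), fill,
          if (nzchar(extra)) paste0(" ", extra) else "")
}

svg_text <- function(x, y, text, size = 10) {
  sprintf('<text x="%s" y="%s" font-size="%d" font-family="monospace">%s</text>',
          fmt_px(x), fmt_px(y), size, svg_esc(text))
}

#' Greedy beeswarm lane assignment
#'
#' Places marks at their true x positions while pushing them into the lowest
#' vertical lane where their horizontal extent `[x_center - width/2,
#' x_center + width/2]` overlaps nothing already placed. Marks are processed
#' in ascending `x_center` order (ties by `id`).
#'
#' @param features A data frame with columns `id`, `x_center`, `width`
#'   (pixels, widths > 0).
#' @return A tibble `id`, `x_center`, `width`, `lane` (0-based), one row per
#'   input feature, in placement order.
#' @export
layout_beeswarm <- function(features) {
  features <- tibble::as_tibble(features)
  if (nrow(features) == 0) {
    return(tibble::tibble(id = character(), x_center = numeric(),
                          width = numeric(), lane = integer()))
  }
  if (any(features$width <= 0)) abort_pav("mark widths must be > 0")
  features <- features[order(features$x_center, features$id), , drop = FALSE]
  lane_right <- numeric()   # rightmost occupied x per lane
  lanes <- integer(nrow(features))
  for (i in seq_len(nrow(features))) {
    left <- features$x_center[i] - features$width[i] / 2
    right <- features$x_center[i] + features$width[i] / 2
    placed <- FALSE
    for (l in seq_along(lane_right)) {
      if (left >= lane_right[l]) {
        lanes[i] <- l - 1L; lane_right[l] <- right; placed <- TRUE; break
      }
    }
    if (!placed) {
      lane_right <- c(lane_right, right)
      lanes[i] <- length(lane_right) - 1L
    }
  }
  features$lane <- lanes
  features
}

#' Shading bins for the panchromosome overview strip
#'
#' Splits the panchromosome extent `[0, max stop)` into `width_px` equal bp
#' bins and computes, per bin, the mean presence fraction of the blocks
#' overlapping it (0 where no block overlaps).
#'
#' @param pav A `pav_df` object.
#' @param panchromosome Panchromosome to summarize.
#' @param width_px Number of one-pixel bins (>= 1).
#' @return A tibble `bin` (1-based), `bp_start`, `bp_stop`, `value` (mean
#'   presence fraction in `[0, 1]`).
#' @export
overview_bins <- function(pav, panchromosome, width_px) {
  if (!panchromosome %in% pav$panchromosome) {
    abort_pav(sprintf("unknown panchromosome '%s'", panchromosome))
  }
  if (width_px < 1) abort_pav("width_px must be >= 1")
  sub <- pav[pav$panchromosome == panchromosome, , drop = FALSE]
  frac <- rowSums(pav_counts(sub) >= 1L) / length(pav_genomes(sub))
  total <- max(sub$stop)
  edges <- total * (0:width_px) / width_px
  value <- vapply(seq_len(width_px), function(b) {
    hit <- sub$start < edges[b + 1] & sub$stop > edges[b]
    if (!any(hit)) 0 else mean(frac[hit])
  }, numeric(1))
  tibble::tibble(bin = seq_len(width_px),
                 bp_start = edges[-length(edges)], bp_stop = edges[-1],
                 value = value)
}

#' Render the miniature panchromosome overview
#'
#' A fixed-width strip of one-pixel bins, each shaded by the mean presence
#' fraction of the blocks overlapping it (darker = more present; see
#' [overview_bins()]).
#'
#' @inheritParams overview_bins
#' @param height_px Strip height in px.
#' @param x,y Offset of the fragment inside an enclosing SVG.
#' @return A character scalar holding an SVG `<g>` fragment.
#' @export
render_overview <- function(pav, panchromosome, width_px, height_px = 16,
                            x = 0, y = 0) {
  bins <- overview_bins(pav, panchromosome, width_px)
  shade <- function(v) grDevices::rgb(1 - v, 1 - v, 1 - v)
  rects <- vapply(seq_len(nrow(bins)), function(b) {
    svg_rect(x + b - 1, y, 1, height_px, shade(bins$value[b]),
             sprintf('data-bin="%d"', b))
  }, character(1))
  paste0('<g class="overview">', paste(rects, collapse = ""), "</g>")
}

#' Render the linear multi-track presence/absence view as SVG
#'
#' Draws, top to bottom: an optional whole-panchromosome overview strip, the
#' gene-annotation beeswarm (marks centred on their pan-position, pushed into
#' lanes so they never overlap; the card's function text rides along as a
#' `<title>`), a coordinate/width track, the core-vs-variable track, the
#' repetition track, then one row per genome with one rectangle per visible
#' block — present cells filled with the block's core/variable colour, absent
#' cells in the absent colour. Every cell rectangle carries `data-genome` and
#' `data-block` attributes.
#'
#' @param pav A `pav_df` object.
#' @param cards Annotation cards from [read_annotations()], or `NULL`.
#' @param config A [view_config()]. Its `panchromosome` defaults to the first
#'   of the table.
#' @return A character scalar holding a complete standalone SVG 1.1 document.
#' @export
render_pav <- function(pav, cards = NULL, config = view_config()) {
  pc <- config$panchromosome %||% pav_panchromosomes(pav)[1]
  if (!pc %in% pav$panchromosome) {
    abort_pav(sprintf("unknown panchromosome '%s'", pc))
  }
  sub <- pav[pav$panchromosome == pc, , drop = FALSE]
  extent <- c(0, max(sub$stop))
  region <- config$region %||% extent
  if (region[1] >= region[2] || region[1] < 0 || region[2] > extent[2]) {
    abort_pav("region must be a non-empty interval within the panchromosome")
  }
  vis <- sub[sub$start < region[2] & sub$stop > region[1], , drop = FALSE]
  genomes <- if (is.null(config$genome_order)) pav_genomes(pav) else {
    ord <- config$genome_order
    if (is.data.frame(ord)) ord$genome else as.character(ord)
  }
  scale_x <- function(bp) config$label_px + (bp - region[1]) * config$px_per_bp
  width_track <- (region[2] - region[1]) * config$px_per_bp

  calls <- classify_pav(pav, config$threshold)
  status <- stats::setNames(calls$status, calls$block_id)
  reps <- repetition_profile(pav)
  nrep <- stats::setNames(reps$n_repeats, reps$block_id)

  body <- character()
  y <- 2

  if (isTRUE(config$show_overview)) {
    body <- c(body, render_overview(pav, pc, width_px = max(1L, round(width_track)),
                                    height_px = 14, x = config$label_px, y = y))
    y <- y + 18
  }

  if (isTRUE(config$show_annotations) && !is.null(cards) && nrow(cards) > 0) {
    cc <- cards[cards$panchromosome == pc &
                  cards$start < region[2] & cards$stop > region[1], ,
                drop = FALSE]
    if (nrow(cc) > 0) {
      marks <- layout_beeswarm(tibble::tibble(
        id = cc$gene_id,
        x_center = scale_x((cc$start + cc$stop) / 2),
        width = pmax(4, (cc$stop - cc$start) * config$px_per_bp)))
      mark_h <- 6
      n_lanes <- max(marks$lane) + 1
      fn <- stats::setNames(cards$function_text, cards$gene_id)
      swarm <- vapply(seq_len(nrow(marks)), function(i) {
        lane_y <- y + (n_lanes - 1 - marks$lane[i]) * (mark_h + 1)
        paste0(
          sprintf('<rect x="%s" y="%s" width="%s" height="%d" fill="#333333" data-gene="%s">',
                  fmt_px(marks$x_center[i] - marks$width[i] / 2),
                  fmt_px(lane_y), fmt_px(marks$width[i]), mark_h,
                  svg_esc(marks$id[i])),
          sprintf("<title>%s</title>", svg_esc(paste0(marks$id[i], ": ",
                                                      fn[[marks$id[i]]]))),
          "</rect>")
      }, character(1))
      body <- c(body, paste0('<g class="annotations">',
                             paste(swarm, collapse = ""), "</g>"))
      y <- y + n_lanes * (mark_h + 1) + 4
    }
  }

  if (isTRUE(config$show_coordinates)) {
    ticks <- vapply(seq_len(nrow(vis)), function(i) {
      paste0(svg_rect(scale_x(vis$start[i]), y, 1, 10, "#999999"),
             svg_text(scale_x(vis$start[i]) + 2, y + 9,
                      as.character(vis$start[i]), size = 7))
    }, character(1))
    body <- c(body, paste0('<g class="coordinates">',
                           paste(ticks, collapse = ""), "</g>"))
    y <- y + 14
  }

  cv <- vapply(seq_len(nrow(vis)), function(i) {
    col <- if (status[[vis$block_id[i]]] == "CORE") config$core_col else config$variable_col
    svg_rect(scale_x(vis$start[i]), y, (vis$stop[i] - vis$start[i]) * config$px_per_bp,
             8, col, sprintf('class="corevar" data-block="%s"', svg_esc(vis$block_id[i])))
  }, character(1))
  body <- c(body, paste0('<g class="core-variable">',
                         paste(cv, collapse = ""), "</g>"))
  y <- y + 12

  if (isTRUE(config$show_repeats)) {
    max_rep <- max(1, nrep)
    rp <- vapply(seq_len(nrow(vis)), function(i) {
      v <- nrep[[vis$block_id[i]]] / max_rep
      svg_rect(scale_x(vis$start[i]), y,
               (vis$stop[i] - vis$start[i]) * config$px_per_bp, 8,
               grDevices::rgb(1 - v, 1 - v, 1 - v),
               sprintf('class="repeat" data-block="%s" data-repeats="%d"',
                       svg_esc(vis$block_id[i]), nrep[[vis$block_id[i]]]))
    }, character(1))
    body <- c(body, paste0('<g class="repeats">', paste(rp, collapse = ""), "</g>"))
    y <- y + 12
  }

  ch <- config$cell_height
  for (gname in genomes) {
    cells <- vapply(seq_len(nrow(vis)), function(i) {
      present <- vis[[gname]][i] >= 1L
      col <- if (!present) config$absent_col
      else if (status[[vis$block_id[i]]] == "CORE") config$core_col
      else config$variable_col
      svg_rect(scale_x(vis$start[i]), y,
               (vis$stop[i] - vis$start[i]) * config$px_per_bp, ch - 2, col,
               sprintf('class="cell" data-genome="%s" data-block="%s"',
                       svg_esc(gname), svg_esc(vis$block_id[i])))
    }, character(1))
    body <- c(body, paste0('<g class="genome-row">',
                           svg_text(2, y + ch - 5, gname, size = 9),
                           paste(cells, collapse = ""), "</g>"))
    y <- y + ch
  }

  total_w <- config$label_px + width_track + 2
  paste0(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                        'width="%s" height="%s" data-panchromosome="%s">'),
                 fmt_px(total_w), fmt_px(y + 2), svg_esc(pc)),
         paste(body, collapse = ""), "</svg>")
}

#' Write an SVG document to a file
#'
#' @param svg Character scalar from [render_pav()] (or any SVG text).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_svg <- function(svg, file) {
  readr::write_lines(svg, file)
  invisible(file)
}
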