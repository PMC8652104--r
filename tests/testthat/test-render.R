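count_matches <- function(svg, pattern) {
  sum(lengths(regmatches(svg, gregexpr(pattern, svg, fixed = TRUE))))
}

test_that("beeswarm lane assignment is greedy lowest-lane", {
  # three disjoint marks share lane 0
  disjoint <- tibble::tibble(id = c("a", "b", "c"),
                             x_center = c(0, 20, 40), width = 5)
  expect_equal(layout_beeswarm(disjoint)$lane, c(0L, 0L, 0L))

  # three mutually overlapping marks stack up
  stacked <- tibble::tibble(id = c("a", "b", "c"),
                            x_center = c(0, 1, 2), width = 10)
  expect_equal(layout_beeswarm(stacked)$lane, c(0L, 1L, 2L))

  # chain: a-b overlap, b-c overlap, a-c disjoint -> lanes 0,1,0
  chain <- tibble::tibble(id = c("a", "b", "c"),
                          x_center = c(0, 6, 12), width = 8)
  out <- layout_beeswarm(chain)
  expect_equal(stats::setNames(out$lane, out$id),
               c(a = 0L, b = 1L, c = 0L))
})

test_that("beeswarm placements never overlap within a lane", {
  set.seed(31)
  feats <- tibble::tibble(id = sprintf("f%03d", 1:80),
                          x_center = runif(80, 0, 300),
                          width = runif(80, 2, 25))
  out <- layout_beeswarm(feats)
  for (l in unique(out$lane)) {
    m <- out[out$lane == l, ]
    m <- m[order(m$x_center), ]
    if (nrow(m) > 1) {
      left <- m$x_center - m$width / 2
      right <- m$x_center + m$width / 2
      expect_true(all(left[-1] >= right[-nrow(m)] - 1e-9))
    }
  }
})

test_that("cell rectangle count is blocks x genomes with tracks off", {
  pav <- read_pav(c(
    "#Chromosome\tStart\tStop\tBlockID\tSimilarBlocks\tFunction\tgA\tgB",
    "pan_1\t0\t100\tb1\t.\t\t1\t1",
    "pan_1\t100\t250\tb2\t.\t\t1\t0",
    "pan_1\t250\t300\tb3\t.\t\t0\t1"))
  cfg <- view_config(show_overview = FALSE, show_annotations = FALSE,
                     show_coordinates = FALSE, show_repeats = FALSE)
  svg <- render_pav(pav, NULL, cfg)
  expect_equal(count_matches(svg, 'class="cell"'), 6)
  expect_equal(count_matches(svg, 'data-genome="gA"'), 3)
  expect_equal(count_matches(svg, 'data-block="b2"'), 2 + 1)  # 2 cells + core/variable track
})

test_that("a fully present matrix draws every mark in the core colour", {
  df <- tibble::tibble(panchromosome = "pan_1",
                       start = c(0L, 10L), stop = c(10L, 20L),
                       block_id = c("b1", "b2"),
                       gA = 1L, gB = 1L)
  pav <- as_pav(df)
  svg <- render_pav(pav, NULL, view_config(threshold = 0.95,
                                           show_coordinates = FALSE,
                                           show_repeats = FALSE))
  expect_equal(count_matches(svg, "#E69F00"), 6)   # 2 core-track + 4 cells
  expect_equal(count_matches(svg, "#56B4E9"), 0)
  expect_equal(count_matches(svg, "#DDDDDD"), 0)
})

test_that("rendering is deterministic and annotations appear as titled marks", {
  pav <- simulate_pav(n_genomes = 6, n_blocks = 30, seed = 9)
  cards <- read_annotations(simulate_annotations(pav, 5, seed = 2), pav)
  cfg <- view_config(show_overview = TRUE)
  svg1 <- render_pav(pav, cards, cfg)
  svg2 <- render_pav(pav, cards, cfg)
  expect_identical(svg1, svg2)
  expect_equal(count_matches(svg1, "<title>"), 5)
  expect_equal(count_matches(svg1, 'class="cell"'), 30 * 6)

  # empty annotation set: zero swarm marks
  svg0 <- render_pav(pav, NULL, cfg)
  expect_equal(count_matches(svg0, "data-gene="), 0)
})

test_that("zoom rescales x extents linearly and nothing else", {
  pav <- simulate_pav(n_genomes = 3, n_blocks = 10, seed = 4)
  svg1 <- render_pav(pav, NULL, view_config(px_per_bp = 0.01))
  svg2 <- render_pav(pav, NULL, view_config(px_per_bp = 0.02))
  w1 <- as.numeric(regmatches(svg1, gregexpr('(?<=width=")[0-9.]+', svg1, perl = TRUE))[[1]])
  w2 <- as.numeric(regmatches(svg2, gregexpr('(?<=width=")[0-9.]+', svg2, perl = TRUE))[[1]])
  expect_equal(length(w1), length(w2))
  scale <- w2[-1] / w1[-1]           # first width is the document (has margin)
  expect_true(all(abs(scale[w1[-1] > 1.5] - 2) < 0.02))
  # same number of rectangles either way
  expect_equal(count_matches(svg1, "<rect"), count_matches(svg2, "<rect"))
})

test_that("region selection restricts the visible blocks and validates bounds", {
  pav <- toy_pav()
  svg <- render_pav(pav, NULL, view_config(region = c(10, 40), px_per_bp = 1,
                                           show_coordinates = FALSE,
                                           show_repeats = FALSE))
  expect_equal(count_matches(svg, 'class="cell"'), 3 * 3)  # blocks 2-4 only
  expect_error(render_pav(pav, NULL, view_config(region = c(0, 1e6))), "region")
  expect_error(render_pav(pav, NULL, view_config(panchromosome = "nope")),
               "panchromosome")
})

test_that("overview bins equal a brute-force per-bin recount", {
  pav <- toy_pav()
  # degenerate binning: one bin holds the matrix-wide mean presence fraction
  one <- overview_bins(pav, "pan_1", 1)
  frac <- rowSums(as.matrix(as.data.frame(pav[, c("A", "B", "C")])) >= 1) / 3
  expect_equal(one$value, mean(frac))

  # all-present matrix: all bins at the maximal shade value
  allp <- pav
  for (g in c("A", "B", "C")) allp[[g]] <- 1L
  allp <- as_pav(allp)
  expect_true(all(overview_bins(allp, "pan_1", 30)$value == 1))

  # random fixture vs direct recount at several widths
  sim <- simulate_pav(n_genomes = 5, n_blocks = 40, seed = 13)
  fr <- rowSums(as.matrix(as.data.frame(sim[, pav_genomes(sim)])) >= 1) / 5
  total <- max(sim$stop)
  for (w in c(7, 50, 128)) {
    bins <- overview_bins(sim, "pan_1", w)
    for (b in c(1, w %/% 2, w)) {
      lo <- total * (b - 1) / w; hi <- total * b / w
      hit <- sim$start < hi & sim$stop > lo
      expect_equal(bins$value[b], if (any(hit)) mean(fr[hit]) else 0)
    }
  }

  frag <- render_overview(pav, "pan_1", 25)
  expect_equal(count_matches(frag, "<rect"), 25)
})
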