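test_that("hollow areas on the toy pangenome match hand-derived intervals", {
  pav <- toy_pav()

  h1 <- find_hollow_areas(pav, min_blocks = 2, min_genomes = 1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$first_block, 2L)
  expect_equal(h1$last_block, 4L)
  expect_equal(h1$absent_genomes[[1]], "B")
  expect_equal(h1$span_bp, 30L)
  expect_equal(h1$start, 10L)
  expect_equal(h1$stop, 40L)

  h2 <- find_hollow_areas(pav, min_blocks = 2, min_genomes = 2)
  expect_equal(nrow(h2), 1)
  expect_equal(c(h2$first_block, h2$last_block), c(2L, 3L))
  expect_setequal(h2$absent_genomes[[1]], c("B", "C"))
})

test_that("a matrix with no absent cell has no hollow areas", {
  pav <- toy_pav()
  for (g in c("A", "B", "C")) pav[[g]] <- 1L
  pav <- as_pav(pav)
  expect_equal(nrow(find_hollow_areas(pav, 1, 1)), 0)
})

test_that("invalid L and g are rejected", {
  pav <- toy_pav()
  expect_error(find_hollow_areas(pav, min_blocks = 0, min_genomes = 1), "min_blocks")
  expect_error(find_hollow_areas(pav, min_blocks = 1, min_genomes = 4), "min_genomes")
})

test_that("hollow finder equals the exhaustive interval oracle", {
  cases <- expand.grid(n_genomes = c(2, 4, 8), n_blocks = c(10, 25, 40),
                       p_absent = c(0.15, 0.35, 0.5))
  seed <- 0
  for (r in seq_len(nrow(cases))) {
    for (rep in 1:3) {
      seed <- seed + 1
      pav <- random_small_pav(cases$n_genomes[r], cases$n_blocks[r],
                              cases$p_absent[r], seed = seed)
      for (L in c(1, 2, 4)) {
        for (g in unique(c(1, 2, cases$n_genomes[r] %/% 2))) {
          got <- hollow_comparable(find_hollow_areas(pav, L, g))
          want <- hollow_comparable(oracle_hollow(pav, L, g))
          expect_equal(got, want,
                       info = sprintf("seed %d L %d g %d", seed, L, g))
        }
      }
    }
  }
})

test_that("reported areas satisfy the definition and maximality directly", {
  pav <- random_small_pav(6, 30, 0.4, seed = 999)
  cm <- as.matrix(as.data.frame(pav[, pav_genomes(pav)]))
  h <- find_hollow_areas(pav, min_blocks = 2, min_genomes = 2)
  for (r in seq_len(nrow(h))) {
    idx <- h$first_block[r]:h$last_block[r]
    shared <- h$absent_genomes[[r]]
    absent_all <- colSums(cm[idx, , drop = FALSE] == 0) == length(idx)
    # the absent set is the full intersection, not a subset
    expect_setequal(shared, pav_genomes(pav)[absent_all])
    expect_gte(length(shared), 2)
    expect_gte(length(idx), 2)
    # extending one block either side drops the intersection below g
    if (h$first_block[r] > 1) {
      ext <- (h$first_block[r] - 1):h$last_block[r]
      expect_lt(sum(colSums(cm[ext, , drop = FALSE] == 0) == length(ext)), 2)
    }
    if (h$last_block[r] < nrow(pav)) {
      ext <- h$first_block[r]:(h$last_block[r] + 1)
      expect_lt(sum(colSums(cm[ext, , drop = FALSE] == 0) == length(ext)), 2)
    }
  }
})

test_that("planted hollow areas are recovered exactly", {
  plant <- list(panchromosome = "pan_1", first_block = 10L, n_blocks = 10L,
                genomes = c("g02", "g03"))
  pav <- simulate_pav(n_genomes = 6, n_blocks = 40, seed = 77,
                      planted_hollows = list(plant))
  h <- find_hollow_areas(pav, min_blocks = 10, min_genomes = 2)
  expect_equal(nrow(h), 1)
  expect_equal(h$first_block, 10L)
  expect_equal(h$last_block, 19L)
  expect_setequal(h$absent_genomes[[1]], c("g02", "g03"))
})

test_that("hollow areas export as BED on pan-coordinates", {
  bed <- hollow_as_bed(find_hollow_areas(toy_pav(), 2, 2))
  expect_equal(bed$chrom, "pan_1")
  expect_equal(bed$start, 10L)
  expect_equal(bed$end, 30L)
  expect_equal(bed$name, "B,C")
})

test_that("hollow scan handles several panchromosomes independently", {
  pav <- simulate_pav(n_genomes = 5, n_blocks = 60, n_panchromosomes = 3,
                      seed = 5,
                      planted_hollows = list(
                        list(panchromosome = "pan_2", first_block = 3L,
                             n_blocks = 6L, genomes = c("g01", "g04"))))
  h <- find_hollow_areas(pav, min_blocks = 6, min_genomes = 2)
  expect_equal(nrow(h), 1)
  expect_equal(h$panchromosome, "pan_2")
  expect_equal(h$first_block, 3L)
  got <- hollow_comparable(h)
  want <- hollow_comparable(oracle_hollow(pav, 6, 2))
  expect_equal(got, want)
})
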