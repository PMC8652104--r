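test_that("tree ordering follows leaf order with the append rule", {
  pav <- toy_pav()
  expect_equal(sort_genomes_by_tree(pav, c("C", "A", "B"))$genome,
               c("C", "A", "B"))
  # genome missing from the tree is appended in matrix order
  expect_equal(sort_genomes_by_tree(pav, c("C", "A"))$genome, c("C", "A", "B"))
  # extra leaf is ignored (with a warning), order unchanged
  expect_warning(ord <- sort_genomes_by_tree(pav, c("C", "X", "A", "B")), "X")
  expect_equal(ord$genome, c("C", "A", "B"))
})

test_that("region ordering ranks by Hamming distance to the pivot", {
  pav <- toy_pav()
  # blocks 2-4: A=(1,1,1), B=(0,0,0), C=(0,0,1)
  ordA <- sort_genomes_by_region(pav, "pan_1", 2, 4, pivot = "A")
  expect_equal(ordA$genome, c("A", "C", "B"))
  expect_equal(ordA$key, c(0L, 2L, 3L))

  ordB <- sort_genomes_by_region(pav, "pan_1", 2, 4, pivot = "B")
  expect_equal(ordB$genome, c("B", "C", "A"))
  expect_equal(ordB$key, c(0L, 1L, 3L))
})

test_that("region ordering keeps matrix order when all genomes tie", {
  pav <- toy_pav()
  ord <- sort_genomes_by_region(pav, "pan_1", 1, 1, pivot = "A")  # block 1 all present
  expect_equal(ord$genome, c("A", "B", "C"))
  expect_equal(ord$key, c(0L, 0L, 0L))
})

test_that("region ordering rejects bad input", {
  pav <- toy_pav()
  expect_error(sort_genomes_by_region(pav, "pan_1", 2, 4, pivot = "Z"), "pivot")
  expect_error(sort_genomes_by_region(pav, "pan_9", 2, 4, pivot = "A"),
               "panchromosome")
  expect_error(sort_genomes_by_region(pav, "pan_1", 4, 2, pivot = "A"), "range")
})

test_that("gene-list ordering counts genes fully present per genome", {
  pav <- toy_pav()
  # cards placed on block spans: gene1 over block 2 (A only), gene2 over
  # block 6 (A and B), gene3 over block 1 (everyone)
  gff <- c("##gff-version 3",
           "pan_1\tsrc\tgene\t11\t20\t.\t+\t.\tID=gene1",
           "pan_1\tsrc\tgene\t51\t60\t.\t+\t.\tID=gene2",
           "pan_1\tsrc\tgene\t1\t10\t.\t+\t.\tID=gene3")
  cards <- read_annotations(gff, pav)

  ord <- sort_genomes_by_gene_list(pav, cards, c("gene1", "gene2", "gene3"))
  # brute-force recount: A carries all 3, B gene2+gene3, C gene3 only
  expect_equal(ord$genome, c("A", "B", "C"))
  expect_equal(ord$key, c(3L, 2L, 1L))

  # a gene present everywhere gives all genomes key 1, matrix order kept
  ord3 <- sort_genomes_by_gene_list(pav, cards, "gene3")
  expect_equal(ord3$genome, c("A", "B", "C"))
  expect_equal(ord3$key, c(1L, 1L, 1L))

  # genomes missing the blocks of both listed genes come last with key 0
  ord12 <- sort_genomes_by_gene_list(pav, cards, c("gene1", "gene2"))
  expect_equal(ord12$genome[3], "C")
  expect_equal(ord12$key[3], 0L)

  expect_error(sort_genomes_by_gene_list(pav, cards, "nope"), "nope")
})

test_that("orderings are permutations and idempotent", {
  pav <- simulate_pav(n_genomes = 8, n_blocks = 40, seed = 21)
  ord <- sort_genomes_by_region(pav, "pan_1", 5, 20, pivot = "g03")
  expect_setequal(ord$genome, pav_genomes(pav))
  expect_equal(ord$genome[1], "g03")
  expect_equal(ord$key[1], 0L)

  sorted <- apply_genome_order(pav, ord)
  expect_equal(pav_genomes(sorted), ord$genome)
  # re-sorting the sorted matrix reproduces the same order
  ord2 <- sort_genomes_by_region(sorted, "pan_1", 5, 20, pivot = "g03")
  expect_equal(ord2$genome, ord$genome)
  expect_identical(as.data.frame(apply_genome_order(sorted, ord2)),
                   as.data.frame(sorted))

  tree <- simulate_tree(pav_genomes(pav), seed = 4)
  ordt <- sort_genomes_by_tree(pav, read_genome_tree(tree))
  expect_setequal(ordt$genome, pav_genomes(pav))
})
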