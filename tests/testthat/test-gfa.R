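toy_gfa <- c(
  "H\tVN:Z:1.0",
  "S\ts1\tACGT",
  "S\ts2\t*\tLN:i:3",
  "S\ts3\tAACCG",
  "P\tgA\ts1+,s2+,s3+\t*",
  "P\tgB\ts1+,s3+\t*"
)

test_that("parse_gfa reads segments and paths with lengths from sequence or LN", {
  g <- read_gfa(toy_gfa)
  expect_equal(nrow(g$segments), 3)
  expect_equal(nrow(g$paths), 2)
  expect_equal(g$segments$length[g$segments$segment_id == "s1"], 4L)
  expect_equal(g$segments$length[g$segments$segment_id == "s2"], 3L)
  expect_equal(g$paths$steps[[1]]$orientation, c("+", "+", "+"))
})

test_that("GFA errors carry line numbers and stable codes", {
  bad_ref <- c(toy_gfa, "P\tgC\ts9+\t*")
  err <- tryCatch(read_gfa(bad_ref), error = function(e) e)
  expect_s3_class(err, "panpav_validation_error")
  expect_match(conditionMessage(err), "UNDECLARED_SEGMENT")
  expect_match(conditionMessage(err), "s9")

  no_len <- c("S\ts1\t*", "P\tg\ts1+\t*")
  expect_error(read_gfa(no_len), "NO_SEGMENT_LENGTH")

  bad_step <- c("S\ts1\tAC", "P\tg\ts1\t*")
  expect_error(read_gfa(bad_step), "BAD_P_LINE")

  f <- withr::local_tempfile(); readr::write_lines(bad_ref, f)
  rep <- validate_pangenome_file(f, "gfa")
  expect_equal(rep$code[rep$severity == "ERROR"], "UNDECLARED_SEGMENT")
  expect_equal(rep$line[rep$severity == "ERROR"], 7L)
})

test_that("the toy graph linearizes to the expected coordinates and counts", {
  pav <- linearize_gfa(read_gfa(toy_gfa), "gA")
  expect_equal(pav$block_id, c("s1", "s2", "s3"))
  expect_equal(pav$start, c(0L, 4L, 7L))
  expect_equal(pav$stop, c(4L, 7L, 12L))
  expect_equal(pav$panchromosome, rep("pan_1", 3))
  expect_equal(pav$gA, c(1L, 1L, 1L))
  expect_equal(pav$gB, c(1L, 0L, 1L))
  expect_equal(segment_map(pav)$start, c(0L, 4L, 7L))
})

test_that("repeated traversals raise the copy count", {
  gfa <- c(toy_gfa, "P\tgC\ts1+,s2+,s2-,s3+\t*")
  pav <- linearize_gfa(read_gfa(gfa), "gA")
  expect_equal(pav$gC[pav$block_id == "s2"], 2L)
})

test_that("a non-backbone segment is inserted after its anchor", {
  gfa <- c("S\ts1\tACGT", "S\ts2\t*\tLN:i:3", "S\ts3\tAACCG",
           "S\ts4\t*\tLN:i:7",
           "P\tgA\ts1+,s2+,s3+\t*",
           "P\tgB\ts1+,s4+,s3+\t*")
  pav <- linearize_gfa(read_gfa(gfa), "gA")
  expect_equal(pav$block_id, c("s1", "s4", "s2", "s3"))
  expect_equal(pav$gB, c(1L, 1L, 0L, 1L))
  # a segment with no backbone predecessor goes before the first block
  gfa2 <- c(gfa[1:5], "P\tgB\ts4+,s1+,s3+\t*")
  pav2 <- linearize_gfa(read_gfa(gfa2), "gA")
  expect_equal(pav2$block_id, c("s4", "s1", "s2", "s3"))
})

test_that("unknown backbone and empty paths are refused", {
  expect_error(linearize_gfa(read_gfa(toy_gfa), "gZ"), "backbone")
})

test_that("path names with '#' split into genome and panchromosome", {
  gfa <- c("S\ts1\tAAAA", "S\ts2\tCC", "S\ts3\tGGG",
           "P\tref#chr1\ts1+,s2+\t*",
           "P\tref#chr2\ts3+\t*",
           "P\talt#chr1\ts1+\t*",
           "P\talt#chr2\ts3+,s3+\t*")
  pav <- linearize_gfa(read_gfa(gfa), "ref")
  expect_setequal(pav_genomes(pav), c("ref", "alt"))
  expect_equal(sort(unique(pav$panchromosome)), c("ref#chr1", "ref#chr2"))
  expect_equal(pav$alt[pav$block_id == "s3"], 2L)
  expect_equal(pav$start[pav$block_id == "s3"], 0L)
})

test_that("linearization conserves path content on random graphs", {
  for (seed in 1:25) {
    n_seg <- 5 + seed %% 10
    n_paths <- 2 + seed %% 4
    gfa <- simulate_gfa(n_seg, n_paths, seed = seed)
    g <- read_gfa(gfa)
    pav <- linearize_gfa(g, "g01")
    cm <- as.matrix(as.data.frame(pav[, pav_genomes(pav)]))
    rownames(cm) <- pav$block_id
    len <- stats::setNames(pav$stop - pav$start, pav$block_id)
    for (k in seq_len(nrow(g$paths))) {
      genome <- g$paths$path_name[k]
      segs <- g$paths$steps[[k]]$segment_id
      # the count column reproduces the traversal multiset
      expect_equal(unname(cm[, genome]),
                   as.integer(table(factor(segs, levels = rownames(cm)))),
                   info = sprintf("seed %d path %s", seed, genome))
      expect_equal(sum(cm[, genome]), length(segs))
      # bp conservation: sum(count x segment length) = path bp total
      expect_equal(sum(cm[, genome] * len),
                   sum(stats::setNames(len[segs], NULL)))
    }
    # backbone column covers every backbone block
    expect_true(all(cm[, "g01"] >= 1))
    # determinism: same file, same block order
    expect_identical(linearize_gfa(read_gfa(gfa), "g01")$block_id,
                     pav$block_id)
  }
})
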