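# Independent brute-force oracles and shared toy fixtures.

# Toy pangenome used across analysis tests: genomes A, B, C and six blocks
# whose per-block absent sets are {}, {B,C}, {B,C}, {B}, {}, {C}.
toy_pav <- function() {
  absent <- list(character(), c("B", "C"), c("B", "C"), "B", character(), "C")
  df <- tibble::tibble(
    panchromosome = "pan_1",
    start = seq(0L, 50L, by = 10L), stop = seq(10L, 60L, by = 10L),
    block_id = paste0("b", 1:6), similar = ".", function_note = ""
  )
  for (g in c("A", "B", "C")) {
    df[[g]] <- vapply(absent, function(a) if (g %in% a) 0L else 1L, integer(1))
  }
  as_pav(df)
}

# Exhaustive hollow-area oracle: enumerate every interval, keep those whose
# jointly-absent set has >= g genomes, filter for maximality (growing one
# block either side drops the intersection below g), then for >= L blocks.
oracle_hollow <- function(pav, L, g) {
  genomes <- pav_genomes(pav)
  out <- list()
  for (pc in unique(pav$panchromosome)) {
    sub <- pav[pav$panchromosome == pc, , drop = FALSE]
    cm <- as.matrix(as.data.frame(sub[, genomes]))
    absent_sets <- lapply(seq_len(nrow(sub)), function(i) genomes[cm[i, ] == 0])
    inter <- function(i, j) Reduce(intersect, absent_sets[i:j])
    n <- nrow(sub)
    for (i in seq_len(n)) {
      for (j in i:n) {
        shared <- inter(i, j)
        if (length(shared) < g) next
        if (i > 1 && length(inter(i - 1, j)) >= g) next
        if (j < n && length(inter(i, j + 1)) >= g) next
        if (j - i + 1 < L) next
        out[[length(out) + 1]] <- tibble::tibble(
          panchromosome = pc, first_block = i, last_block = j,
          n_absent = length(shared),
          absent_genomes = list(sort(shared)))
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(res)
  res[order(res$panchromosome, res$first_block), , drop = FALSE]
}

# Random small PAV table with uniform absence probability (denser absence
# than the generator's defaults, to stress interval structure).
random_small_pav <- function(n_genomes, n_blocks, p_absent, seed) {
  set.seed(seed)
  repeat {
    cnt <- matrix(rbinom(n_blocks * n_genomes, 1, 1 - p_absent),
                  nrow = n_blocks)
    if (all(rowSums(cnt) >= 1)) break
  }
  df <- tibble::tibble(
    panchromosome = "pan_1",
    start = as.integer((seq_len(n_blocks) - 1) * 5),
    stop = as.integer(seq_len(n_blocks) * 5),
    block_id = sprintf("b%03d", seq_len(n_blocks)),
    similar = ".", function_note = ""
  )
  for (k in seq_len(n_genomes)) df[[sprintf("g%02d", k)]] <- as.integer(cnt[, k])
  as_pav(df)
}

hollow_comparable <- function(h) {
  if (nrow(h) == 0) {
    return(tibble::tibble(panchromosome = character(), first_block = integer(),
                          last_block = integer(), n_absent = integer(),
                          absent_genomes = list()))
  }
  h <- h[, c("panchromosome", "first_block", "last_block", "n_absent",
             "absent_genomes")]
  h$absent_genomes <- lapply(h$absent_genomes, sort)
  h
}
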