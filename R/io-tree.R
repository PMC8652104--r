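# Newick trees supply a phylogeny-driven genome ordering: the leaf names in
# the left-to-right order in which the tree was written.

#' Read a Newick tree and return its leaf order
#'
#' Parses a single (rooted or unrooted) Newick tree and returns the leaf
#' names in the left-to-right traversal order of the written tree — the order
#' a phylogeny figure would display them. Branch lengths and internal node
#' labels are ignored.
#'
#' @param file Path to a Newick file, or a literal Newick string (detected by
#'   a terminal `;`).
#' @return Character vector of leaf names, in traversal order.
#' @export
read_genome_tree <- function(file) {
  text <- if (length(file) == 1 && grepl(";\\s*$", file) && !file.exists(file)) {
    file
  } else {
    paste(readr::read_lines(file), collapse = "")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort_pav("unbalanced parentheses in Newick input",
              class = "panpav_validation_error")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) {
    abort_pav("could not parse Newick tree", class = "panpav_validation_error")
  }
  leaves <- tree$tip.label
  if (anyDuplicated(leaves)) {
    abort_pav(sprintf("duplicate leaf name(s): %s",
                      paste(unique(leaves[duplicated(leaves)]), collapse = ", ")),
              class = "panpav_validation_error")
  }
  leaves
}
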