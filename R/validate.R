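# Uniform validation entry point: every supported format can be checked
# without aborting. The report is ERROR-free exactly when the corresponding
# reader succeeds; codes are stable strings suitable for scripting.

#' Validate a pangenome input file
#'
#' Runs the format-specific checks and returns every detected issue instead of
#' throwing. A file whose report contains at least one ERROR will be refused
#' by the corresponding reader ([read_pav()], [read_annotations()],
#' [read_genome_tree()], [read_gfa()]).
#'
#' @param file Path to the file.
#' @param kind One of `"pav"`, `"gff3"`, `"newick"`, `"gfa"`.
#' @return A tibble with columns `severity` (`"ERROR"` or `"WARNING"`),
#'   `code` (stable string), `message` and `line` (`NA` when not tied to a
#'   line).
#' @export
validate_pangenome_file <- function(file,
                                    kind = c("pav", "gff3", "newick", "gfa")) {
  kind <- match.arg(kind)
  lines <- input_lines(file)
  switch(kind,
         pav = parse_pav(lines)$issues,
         gff3 = parse_gff3(lines)$issues,
         gfa = parse_gfa_lines(lines)$issues,
         newick = {
           issues <- issue_tbl()
           tryCatch({
             read_genome_tree(paste(lines, collapse = ""))
             issues
           }, error = function(e) {
             add_issue(issues, "ERROR", "BAD_NEWICK", conditionMessage(e))
           })
         })
}
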