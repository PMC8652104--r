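# Readers accept either a file path or in-memory text: a character vector of
# lines, or a single string containing newlines.
input_lines <- function(x) {
  if (!is.character(x)) abort_pav("expected a file path or character lines")
  if (length(x) > 1) return(x)
  if (grepl("\n", x, fixed = TRUE)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  if (grepl("\t", x, fixed = TRUE)) return(x)   # inline single-line content
  readr::read_lines(x)
}
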