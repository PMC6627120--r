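# Small in-code fixtures shared across test files.

make_table <- function(counts, roles = NULL, replicate_of = NULL,
                       features = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- features %||% paste0("OTU_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- samples %||% paste0("S", seq_len(ncol(counts)))
  count_table(counts, roles = roles, replicate_of = replicate_of)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

random_count_table <- function(nf = 6, ns = 4, max_count = 50) {
  m <- matrix(sample(0:max_count, nf * ns, replace = TRUE), nf, ns)
  make_table(m)
}

# strictly positive random composition (column)
random_composition <- function(D) {
  x <- stats::rgamma(D, shape = 1) + 1e-3
  x / sum(x)
}

small_taxonomy <- function() {
  path <- write_tsv_lines(c(
    "OTU_1\tk__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Streptococcaceae;g__Streptococcus",
    "OTU_2\tk__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Streptococcaceae;g__Streptococcus",
    "OTU_3\tk__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__Staphylococcaceae;g__Staphylococcus",
    "OTU_4\tk__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacterales;f__Enterobacteriaceae;g__",
    "OTU_5\tk__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Pseudomonadales;f__Moraxellaceae;g__"
  ))
  read_taxonomy(path)
}
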