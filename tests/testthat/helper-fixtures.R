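# In-code fixtures shared across test files.

example_gbk <- function() {
  system.file("extdata", "synthetic_contig.gbk", package = "hgtsignal")
}

# small annotated contig built directly in code: two plus-strand genes and
# one minus-strand gene with known CDS
toy_contig <- function() {
  # gene1 + : ATGGCGTGA at 5..14 ; gene2 - : ATGAAATAA placed revcomp at
  # 20..29 ; gene3 + : ATGTGCTAG at 33..42   (0-based half-open)
  g1 <- "ATGGCGTGA"
  g2 <- "ATGAAATAA"
  g3 <- "ATGTGCTAG"
  res <- paste0("CCCCC", g1, "TTTTTT",
                as.character(reverse_complement(g2)), "AAAA", g3, "GG")
  record <- seq_record("toy", res)
  features <- gene_features("toy",
                            start = c(5L, 20L, 33L),
                            end = c(14L, 29L, 42L),
                            strand = c("+", "-", "+"),
                            locus_tag = c("gene1", "gene2", "gene3"),
                            product = c("p1", "p2", "p3"))
  list(record = record, features = features,
       cds = c(gene1 = g1, gene2 = g2, gene3 = g3))
}

# mirror an annotated replicon onto the opposite strand (features included)
flip_replicon <- function(record, features) {
  L <- length(record)
  f <- features
  new_start <- L - f$end
  f$end <- L - f$start
  f$start <- new_start
  f$strand <- ifelse(f$strand == "+", "-", "+")
  f$exons <- paste0(f$start, ":", f$end)
  list(record = reverse_complement(record), features = f[order(f$start), ])
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".gbk")
  writeLines(lines, path)
  path
}
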