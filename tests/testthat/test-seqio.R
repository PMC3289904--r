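test_that("FASTA parsing preserves records, order and case normalisation", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">x some desc", "acgt", ">y", "TTAA"), p)
  recs <- read_fasta(p)
  expect_length(recs, 2)
  expect_equal(names(recs), c("x", "y"))
  expect_equal(recs$x$residues, "ACGT")
  expect_equal(recs$x$desc, "some desc")
  expect_equal(recs$y$residues, "TTAA")
})

test_that("FASTA rejects empty files and names illegal characters by position", {
  p <- tempfile(fileext = ".fasta")
  file.create(p)
  expect_error(read_fasta(p), "no records|cannot parse")
  writeLines(c(">x", "AC!T"), p)
  expect_error(read_fasta(p, moltype = "nucleotide"), "'x'.*position 3")
})

test_that("FASTA writer round-trips bit-exactly", {
  set.seed(11)
  recs <- list(seq_record("a", rand_dna(151), desc = "first"),
               seq_record("b", rand_protein(90), moltype = "protein"))
  p1 <- tempfile(fileext = ".fasta")
  write_fasta(recs, p1)
  back <- read_fasta(p1)
  expect_equal(back$a$residues, recs[[1]]$residues)
  expect_equal(back$b$residues, recs[[2]]$residues)
  p2 <- tempfile(fileext = ".fasta")
  write_fasta(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("seq_record validates alphabet per moltype", {
  expect_error(seq_record("x", ""), "non-empty")
  expect_error(seq_record("x", "ACGU", moltype = "nucleotide"), "position 4")
  expect_silent(seq_record("x", "MKNV", moltype = "protein"))
  # auto mode treats pure ACGTN as nucleotide
  expect_equal(seq_record("x", "ACGTN")$moltype, "nucleotide")
  expect_equal(seq_record("x", "MKWR")$moltype, "protein")
})

test_that("extract_cds honours strand and bounds", {
  toy <- toy_contig()
  expect_equal(extract_cds(toy$record, toy$features[1, ])$residues,
               toy$cds[["gene1"]])
  expect_equal(extract_cds(toy$record, toy$features[2, ])$residues,
               toy$cds[["gene2"]])
  # reverse-complement relation between the two strands of one interval
  f_plus <- toy$features[2, ]
  f_plus$strand <- "+"
  expect_equal(extract_cds(toy$record, f_plus)$residues,
               as.character(reverse_complement(toy$cds[["gene2"]])))
  bad <- gene_features("toy", 40L, 100L, "+", "oob")
  expect_error(extract_cds(toy$record, bad), "beyond")
})

test_that("reverse complement of a forward stop-reading frame", {
  # "ATGAAATAA" placed on the minus strand reads TTATTTCAT forward
  expect_equal(as.character(reverse_complement("ATGAAATAA")), "TTATTTCAT")
})

test_that("translation drops terminal stop and flags internal stops", {
  expect_equal(translate_cds("ATGGCGTAA")$residues, "MA")
  expect_error(translate_cds("ATGTAAGCG"), "codon 2")
  expect_error(translate_cds("ATGGC"), "multiple of 3")
  # GTG start only with the flag
  expect_equal(substr(translate_cds("GTGGCGTAA")$residues, 1, 1), "V")
  expect_equal(substr(translate_cds("GTGGCGTAA", allow_alt_start = TRUE)$residues,
                      1, 1), "M")
  # 456 nt CDS -> 151 aa after removing the stop
  set.seed(3)
  body <- paste(replicate(151, {
    repeat {
      cd <- rand_dna(3)
      if (!cd %in% c("TAA", "TAG", "TGA")) break
    }
    cd
  }), collapse = "")
  expect_equal(nchar(translate_cds(paste0(body, "TGA"))$residues), 151)
})

test_that("GenBank reader converts coordinates, strand and join()", {
  gb <- read_genbank(example_gbk())
  expect_equal(length(gb$record), 60)
  f <- gb$features
  expect_equal(nrow(f), 3)
  # 1-based inclusive 4..9 becomes 0-based half-open (3, 9)
  expect_equal(f$start[f$locus_tag == "gA"], 3L)
  expect_equal(f$end[f$locus_tag == "gA"], 9L)
  expect_equal(f$strand[f$locus_tag == "gA"], "+")
  expect_equal(f$strand[f$locus_tag == "gB"], "-")
  # extracted CDS all translate and end in stops
  expect_equal(extract_cds(gb$record, f[f$locus_tag == "gA", ])$residues,
               "ATGTAA")
  expect_equal(extract_cds(gb$record, f[f$locus_tag == "gB", ])$residues,
               "ATGGCGTGA")
  expect_equal(extract_cds(gb$record, f[f$locus_tag == "gC", ])$residues,
               "ATGAAATAG")
  expect_equal(translate_cds(extract_cds(gb$record,
                                         f[f$locus_tag == "gC", ]))$residues,
               "MK")
})

test_that("GenBank reader rejects malformed files", {
  no_origin <- write_lines_tmp(c("LOCUS       x 10 bp", "FEATURES", "//"))
  expect_error(read_genbank(no_origin), "ORIGIN")
  oob <- write_lines_tmp(c(
    "LOCUS       x                    10 bp    DNA",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..40",
    "                     /locus_tag=\"g\"",
    "ORIGIN",
    "        1 acgtacgtac",
    "//"))
  expect_error(read_genbank(oob), "beyond")
})

test_that("GenBank/internal coordinate conversion is a bijection", {
  withr::with_seed(5, {
    for (r in 1:50) {
      a <- sample.int(10000, 1)
      b <- a + sample.int(500, 1)
      int <- genbank_to_internal(a, b)
      expect_equal(int[["start"]], a - 1L)
      expect_equal(int[["end"]], b)
      back <- internal_to_genbank(int[["start"]], int[["end"]])
      expect_identical(unname(back), c(a, b))
      expect_equal(int[["end"]] - int[["start"]], b - a + 1L)
    }
  })
})

test_that("Newick writer round-trips and carries supports", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  p <- tempfile(fileext = ".nwk")
  write_newick(star, p)
  expect_match(readLines(p), "A:1")
  # random tree with supports round-trips topology, lengths and labels
  withr::with_seed(9, {
    tr <- ape::rtree(6)
    tr$node.label <- c("", "87", "99", "55", "12")
  })
  write_newick(tr, p)
  back <- read_newick(p)
  expect_equal(back$node.label[2], "87")
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-6)
  bad <- tr
  bad$tip.label[2] <- ""
  expect_error(write_newick(bad, p), "named")
})

test_that("TSV writer round-trips tables and records parameters", {
  tab <- data.frame(locus_tag = c("a", "b"), gc = c(0.5, 0.25))
  p <- tempfile(fileext = ".tsv")
  write_tsv_table(tab, p, comments = c(window = 500, step = 40))
  lines <- readLines(p)
  expect_equal(lines[1], "# window=500")
  expect_equal(read_tsv_table(p), tab)
})
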