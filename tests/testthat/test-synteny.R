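test_that("gene-pair orientation follows the convergent/divergent convention", {
  up <- function(s) gene_features("c", 0L, 90L, s, "up")
  down <- function(s) gene_features("c", 100L, 190L, s, "down")
  expect_equal(classify_orientation(up("+"), down("-")), "face-to-face")
  expect_equal(classify_orientation(up("-"), down("+")), "back-to-back")
  expect_equal(classify_orientation(up("+"), down("+")), "co-directional")
  expect_equal(classify_orientation(up("-"), down("-")), "co-directional")
  # symmetric in argument order
  expect_equal(classify_orientation(down("-"), up("+")), "face-to-face")
  ov <- gene_features("c", 50L, 150L, "+", "ov")
  expect_error(classify_orientation(up("+"), ov), "overlap by 40")
})

test_that("neighborhood extraction truncates at contig edges and respects k", {
  trio <- gen_synteny_trio(n_core = 6, n_private = 0, seed = 5)
  g <- trio$genomes[[1]]
  nbr <- extract_neighborhood(g$record, g$features, trio$anchor_tag, k = 1)
  expect_equal(nrow(nbr$features), 3)
  expect_true(trio$anchor_tag %in% nbr$features$locus_tag)
  edge <- extract_neighborhood(g$record, g$features, "core01", k = 8)
  expect_equal(nrow(edge$features), 6)   # nothing upstream of the first gene
  expect_error(extract_neighborhood(g$record, g$features, "nope"), "not found")
})

test_that("normalisation orients the anchor rightward and flips are involutions", {
  toy <- toy_contig()
  nbr <- extract_neighborhood(toy$record, toy$features, "gene2", k = 8)
  anchor <- nbr$features[nbr$features$locus_tag == "gene2", ]
  expect_equal(anchor$strand, "+")
  # the anchor CDS text is preserved by the mirroring
  expect_equal(extract_cds(nbr$record, anchor)$residues, toy$cds[["gene2"]])
  # flipping twice returns the original neighborhood
  raw <- extract_neighborhood(toy$record, toy$features, "gene1",
                              normalize = FALSE)
  twice <- flip_neighborhood(flip_neighborhood(raw))
  expect_equal(twice$record$residues, raw$record$residues)
  expect_equal(twice$features$start, raw$features$start)
  expect_equal(twice$features$strand, raw$features$strand)
})

test_that("ortholog matching is reciprocal, complete on identity, empty on noise", {
  trio <- gen_synteny_trio(n_core = 5, n_private = 0, seed = 9)
  g1 <- trio$genomes[[1]]; g2 <- trio$genomes[[2]]
  n1 <- extract_neighborhood(g1$record, g1$features, "anchor",
                             genome_id = "A")
  n2 <- extract_neighborhood(g2$record, g2$features, "anchor",
                             genome_id = "B")
  m12 <- match_orthologs(n1, n2)
  expect_equal(nrow(m12), 5)
  expect_setequal(m12$a, m12$b)       # same tags on both genomes
  # symmetry of the pair set
  m21 <- match_orthologs(n2, n1)
  expect_equal(m12[order(m12$a), c("a", "b")],
               stats::setNames(m21[order(m21$b), c("b", "a")], c("a", "b")),
               ignore_attr = TRUE)
  # identical neighborhoods -> perfect 1:1 matching
  m11 <- match_orthologs(n1, n1)
  expect_equal(nrow(m11), 5)
  expect_equal(m11$a, m11$b)
})

test_that("unrelated random neighborhoods yield no orthologs", {
  withr::with_seed(63, {
    for (r in 1:5) {
      t1 <- gen_synteny_trio(n_core = 4, n_private = 0,
                             seed = sample.int(1e6, 1))
      t2 <- gen_synteny_trio(n_core = 4, n_private = 0,
                             seed = sample.int(1e6, 1))
      na <- extract_neighborhood(t1$genomes[[1]]$record,
                                 t1$genomes[[1]]$features, "anchor",
                                 genome_id = "X")
      nb <- extract_neighborhood(t2$genomes[[2]]$record,
                                 t2$genomes[[2]]$features, "anchor",
                                 genome_id = "Y")
      expect_equal(nrow(match_orthologs(na, nb)), 0)
    }
  })
})

test_that("a deleted gene drops out of the matching, the rest persists", {
  trio <- gen_synteny_trio(n_core = 6, n_private = 0, seed = 13)
  g1 <- trio$genomes[[1]]; g2 <- trio$genomes[[2]]
  n1 <- extract_neighborhood(g1$record, g1$features, "anchor",
                             genome_id = "A")
  f2 <- g2$features[g2$features$locus_tag != "core02", ]
  n2 <- extract_neighborhood(g2$record, f2, "anchor", genome_id = "B")
  m <- match_orthologs(n1, n2)
  expect_setequal(m$b, setdiff(trio$core_tags, "core02"))
})

test_that("synteny table recovers exactly the planted conserved block", {
  trio <- gen_synteny_trio(n_core = 5, n_private = 2, seed = 21)
  nbrs <- lapply(trio$genomes, function(g)
    extract_neighborhood(g$record, g$features, trio$anchor_tag,
                         genome_id = g$genome_id))
  st <- synteny_table(nbrs)
  expect_error(synteny_table(nbrs[1]), "at least 2")
  conserved <- st[st$conserved, ]
  # precision and recall 1: conserved tags are the core block in all genomes
  for (gid in unique(st$genome_id))
    expect_setequal(conserved$locus_tag[conserved$genome_id == gid],
                    trio$core_tags)
  # each conserved group holds one gene per genome with a consistent tag
  for (grp in unique(conserved$group)) {
    rows <- conserved[conserved$group == grp, ]
    expect_equal(nrow(rows), 3)
    expect_equal(length(unique(rows$locus_tag)), 1)
    expect_equal(sort(rows$genome_id), c("genomeA", "genomeB", "genomeC"))
  }
  # anchor sits at offset 0 everywhere
  expect_true(all(st$offset[st$locus_tag == "anchor"] == 0))
  # private genes are unplaced
  expect_true(all(is.na(st$group[grepl("priv", st$locus_tag)])))
})

test_that("two identical 5-gene neighborhoods give 5 conserved groups", {
  trio <- gen_synteny_trio(n_core = 5, n_private = 0, seed = 33)
  g <- trio$genomes[[1]]
  n1 <- extract_neighborhood(g$record, g$features, "anchor", genome_id = "A")
  n2 <- extract_neighborhood(g$record, g$features, "anchor", genome_id = "B")
  st <- synteny_table(list(n1, n2))
  expect_equal(length(unique(st$group[st$conserved])), 5)
  expect_true(all(st$conserved))
})
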