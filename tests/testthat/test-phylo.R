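test_that("pairwise alignment scores and mismatch fraction behave", {
  p <- rand_protein(30)
  self <- align_pair(p, p)
  expect_equal(self$mismatch, 0)
  expect_equal(self$score, sum(blosum62[cbind(strsplit(p, "")[[1]],
                                              strsplit(p, "")[[1]])]))
  one <- align_pair("A", "R")
  expect_equal(one$mismatch, 1.0)
  expect_error(align_pair("", "A"), "empty")
  # degapped rows reproduce the inputs
  withr::with_seed(17, {
    a <- rand_protein(25); b <- rand_protein(18)
    al <- align_pair(a, b)
    expect_equal(gsub("-", "", al$a_aln), a)
    expect_equal(gsub("-", "", al$b_aln), b)
  })
})

test_that("alignment score equals exhaustive enumeration on short pairs", {
  withr::with_seed(23, {
    for (r in 1:25) {
      a <- rand_protein(sample(1:8, 1))
      b <- rand_protein(sample(1:8, 1))
      expect_equal(align_pair(a, b)$score, brute_align_score(a, b),
                   tolerance = 1e-9)
    }
  })
})

test_that("Kimura correction matches its closed form and domain", {
  expect_equal(kimura_distance(0), 0)
  expect_equal(kimura_distance(0.5), -log(0.45))
  expect_error(kimura_distance(0.9), "correction domain")
  expect_equal(kimura_distance(0.9, fallback_raw = TRUE), 0.9)
  D <- seq(0, 0.84, by = 0.06)
  expect_true(all(kimura_distance(D) >= D))
})

test_that("distance matrices are symmetric with validated labels", {
  withr::with_seed(29, {
    base <- strsplit(rand_protein(60), "")[[1]]
    mutate_at <- function(k) {
      s <- base
      p <- sample(60, k)
      s[p] <- vapply(s[p], function(x) sample(setdiff(AA20, x), 1), "")
      paste(s, collapse = "")
    }
    prots <- stats::setNames(lapply(c(0, 6, 12), mutate_at),
                             c("a", "b", "c"))
    d <- protein_distance_matrix(prots)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_error(protein_distance_matrix(prots[c(1, 2)]), "at least 3")
    names(prots)[2] <- "a"
    expect_error(protein_distance_matrix(prots), "duplicate")
  })
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["B"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["C"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d[1, 2] <- d[2, 1] <- Inf
  expect_error(nj_tree(d), "non-finite")
})

test_that("NJ recovers random additive trees exactly", {
  for (r in 1:30) {
    n <- sample(4:12, 1)
    gen <- random_additive_matrix(n, seed = 1000 + r)
    tr <- nj_tree(gen$d)
    path <- tree_path_lengths(tr)[rownames(gen$d), colnames(gen$d)]
    expect_lt(max(abs(path - gen$d)), 1e-9)
  }
})

test_that("NJ agrees with the reference implementation off additivity", {
  withr::with_seed(402, {
    for (r in 1:10) {
      n <- sample(5:9, 1)
      base <- random_additive_matrix(n, seed = 500 + r)$d
      noise <- matrix(stats::runif(n * n, 0, 0.05), n)
      noise <- (noise + t(noise)) / 2
      diag(noise) <- 0
      d <- base + noise
      mine <- nj_tree(d)
      ref <- ape::nj(d)
      expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
    }
  })
})

test_that("NJ output is invariant under taxon order", {
  gen <- random_additive_matrix(8, seed = 77)
  perm <- sample(8)
  t1 <- nj_tree(gen$d)
  t2 <- nj_tree(gen$d[perm, perm])
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
  expect_equal(tree_path_lengths(t2)[rownames(gen$d), colnames(gen$d)],
               tree_path_lengths(t1)[rownames(gen$d), colnames(gen$d)],
               tolerance = 1e-12)
})

test_that("degenerate all-equal distances still produce a tree deterministically", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_setequal(t1$tip.label, letters[1:4])
})

test_that("bootstrap supports are deterministic and taxon-order invariant", {
  aln <- structured_alignment(seed = 31)
  b1 <- bootstrap_support(aln, n_reps = 50, seed = 42)
  b2 <- bootstrap_support(aln, n_reps = 50, seed = 42)
  expect_identical(b1$support, b2$support)
  b3 <- bootstrap_support(aln[c(4, 2, 6, 1, 3, 5)], n_reps = 50, seed = 42)
  # same bipartition supports regardless of input order: compare the
  # support attached to the A-clade split
  part1 <- ape::prop.part(b1$tree)
  part3 <- ape::prop.part(b3$tree)
  clade1 <- vapply(part1, function(p)
    setequal(attr(part1, "labels")[p], c("A1", "A2", "A3")), logical(1))
  clade3 <- vapply(part3, function(p)
    setequal(attr(part3, "labels")[p], c("A1", "A2", "A3")), logical(1))
  expect_equal(unname(b1$support[which(clade1)]),
               unname(b3$support[which(clade3)]))
  expect_error(bootstrap_support(aln, n_reps = 0, seed = 1), ">= 1")
  expect_error(bootstrap_support(aln, n_reps = 10), "seed")
})

test_that("a strongly structured clade gets near-total bootstrap support", {
  aln <- structured_alignment(seed = 3)
  bs <- bootstrap_support(aln, n_reps = 100, seed = 11)
  part <- ape::prop.part(bs$tree)
  labels <- attr(part, "labels")
  is_clade <- vapply(part, function(p)
    setequal(labels[p], c("A1", "A2", "A3")) ||
      setequal(labels[p], c("B1", "B2", "B3")), logical(1))
  expect_true(any(is_clade))
  expect_gte(max(bs$support[which(is_clade)]), 95)
})

test_that("outgroup rooting splits the pendant edge and preserves leaves", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  rt <- root_with_outgroup(tr, "C")
  expect_true(ape::is.rooted(rt))
  root_node <- length(rt$tip.label) + 1L
  kids <- which(rt$edge[, 1] == root_node)
  expect_length(kids, 2)
  # midpoint split: both root edges equal
  expect_equal(rt$edge.length[kids[1]], rt$edge.length[kids[2]])
  expect_setequal(rt$tip.label, tr$tip.label)
  expect_error(root_with_outgroup(tr, "Z"), "not a leaf")
})

test_that("re-rooting at another leaf and back recovers the topology", {
  gen <- random_additive_matrix(7, seed = 55)
  tr <- nj_tree(gen$d)
  lab <- tr$tip.label
  r1 <- root_with_outgroup(tr, lab[1])
  r2 <- root_with_outgroup(root_with_outgroup(r1, lab[3]), lab[1])
  expect_equal(phangorn::RF.dist(r1, r2, rooted = TRUE), 0)
  # path lengths between leaves unchanged by rooting
  expect_equal(tree_path_lengths(r1)[lab, lab],
               tree_path_lengths(tr)[lab, lab], tolerance = 1e-12)
})
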