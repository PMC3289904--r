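# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately use naive loops / exhaustive
# enumeration and share no code with the package internals.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# exhaustive enumeration of every global alignment under affine gaps
# (gap of length L costs go + L * ge); feasible for sequences up to ~8
brute_align_score <- compiler::cmpfun(function(a, b, mat = blosum62,
                                               go = 10, ge = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  rec <- function(i, j, state, sc) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= na && j <= nb) rec(i + 1L, j + 1L, 0L, sc + mat[A[i], B[j]])
    if (i <= na) rec(i + 1L, j, 1L, sc - ge - if (state == 1L) 0 else go)
    if (j <= nb) rec(i, j + 1L, 2L, sc - ge - if (state == 2L) 0 else go)
  }
  rec(1L, 1L, -1L, 0)
  best
})

# per-character loop GC, N excluded
brute_gc <- function(s) {
  ch <- strsplit(s, "")[[1]]
  gc <- 0L; tot <- 0L
  for (c in ch) {
    if (c == "N") next
    tot <- tot + 1L
    if (c == "G" || c == "C") gc <- gc + 1L
  }
  gc / tot
}

# naive per-window recomputation of the sliding nucleotide GC profile
brute_windowed_gc <- function(s, window, step) {
  L <- nchar(s)
  starts <- seq(0L, L - window, by = step)
  vapply(starts, function(st) brute_gc(substr(s, st + 1L, st + window)),
         numeric(1))
}

# naive codon-position GC with explicit codon loop
brute_codon_gc <- function(cds, drop_stop = TRUE) {
  n <- nchar(cds) / 3
  codons <- substring(cds, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
  if (drop_stop && n > 1 && codons[n] %in% c("TAA", "TAG", "TGA"))
    codons <- codons[-length(codons)]
  out <- numeric(3)
  for (k in 1:3) {
    gc <- 0L; tot <- 0L
    for (cd in codons) {
      b <- substr(cd, k, k)
      if (b == "N") next
      tot <- tot + 1L
      if (b == "G" || b == "C") gc <- gc + 1L
    }
    out[k] <- gc / tot
  }
  out
}

# random tree with positive branch lengths and its additive path matrix
random_additive_matrix <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}

rand_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

rand_dna <- function(len, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alpha, len, TRUE), collapse = "")
}

# strongly structured two-clade protein alignment: clades differ at half of
# the columns, each taxon carries a few private substitutions
structured_alignment <- function(n_per_clade = 3, n_cols = 200, seed = 1) {
  withr::with_seed(seed, {
    base <- sample(AA20, n_cols, TRUE)
    other <- base
    flip <- sample.int(n_cols, n_cols / 2)
    other[flip] <- vapply(other[flip],
                          function(a) sample(setdiff(AA20, a), 1), "")
    taxa <- list()
    for (i in seq_len(n_per_clade)) {
      s <- base
      p <- sample.int(n_cols, 5)
      s[p] <- vapply(s[p], function(a) sample(setdiff(AA20, a), 1), "")
      taxa[[paste0("A", i)]] <- paste(s, collapse = "")
    }
    for (i in seq_len(n_per_clade)) {
      s <- other
      p <- sample.int(n_cols, 5)
      s[p] <- vapply(s[p], function(a) sample(setdiff(AA20, a), 1), "")
      taxa[[paste0("B", i)]] <- paste(s, collapse = "")
    }
    unlist(taxa)
  })
}
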