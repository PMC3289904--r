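#' Specification of a synthetic annotated genome
#'
#' Describes a synthetic bacterial contig: protein-coding genes whose
#' codon-position GC is controlled independently at positions 1+2 and 3
#' (the minimal model that decouples GC12 from GC3, the signature exploited
#' by amelioration analysis), stop codons drawn from explicit weights, and
#' intergenic spacers. Defaults emulate a high-GC actinobacterial contig of
#' 27 genes whose overall GC is about 0.69 (GC12 0.62, GC3 0.85), with the
#' TGA-dominated stop usage typical of high-GC genomes.
#'
#' @param n_genes Number of genes.
#' @param mean_gene_len Mean gene length in codons (start and stop included);
#'   lengths are Poisson-distributed with a floor of 20 codons.
#' @param target_gc3 Expected GC fraction at codon position 3.
#' @param target_gc12 Expected GC fraction at codon positions 1 and 2.
#' @param stop_weights Named non-negative weights for `TAA`, `TAG`, `TGA`.
#' @param intergenic_mean Mean intergenic spacer length (bp, Poisson, floor
#'   10 bp so insertion space always exists).
#' @param seed Integer seed; generation is a pure function of spec + seed.
#' @param contig_id Identifier for the generated record.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_genes = 27L, mean_gene_len = 150L,
                        target_gc3 = 0.85, target_gc12 = 0.62,
                        stop_weights = c(TAA = 0.05, TAG = 0.30, TGA = 0.65),
                        intergenic_mean = 80L, seed = 1L,
                        contig_id = "syn_contig") {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (mean_gene_len < 20L) stop("mean_gene_len must be >= 20 codons")
  for (v in c(target_gc3, target_gc12))
    if (is.na(v) || v < 0 || v > 1) stop("GC targets must be fractions in [0, 1]")
  if (!all(c("TAA", "TAG", "TGA") %in% names(stop_weights)))
    stop("stop_weights must name TAA, TAG and TGA")
  stop_weights <- stop_weights[c("TAA", "TAG", "TGA")]
  if (any(stop_weights < 0) || sum(stop_weights) <= 0)
    stop("stop_weights must be non-negative with positive sum")
  structure(list(n_genes = as.integer(n_genes),
                 mean_gene_len = as.integer(mean_gene_len),
                 target_gc3 = target_gc3, target_gc12 = target_gc12,
                 stop_weights = stop_weights,
                 intergenic_mean = as.integer(intergenic_mean),
                 seed = as.integer(seed), contig_id = contig_id),
            class = "genome_spec")
}

.sample_bases <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

# n sense-strand codons with the given positional GC, none of them stops
.sample_codons <- function(n, gc12, gc3) {
  if (n == 0L) return(character())
  codons <- paste0(.sample_bases(n, gc12), .sample_bases(n, gc12),
                   .sample_bases(n, gc3))
  repeat {
    bad <- which(codons %in% .STOP_CODONS)
    if (length(bad) == 0L) break
    codons[bad] <- paste0(.sample_bases(length(bad), gc12),
                          .sample_bases(length(bad), gc12),
                          .sample_bases(length(bad), gc3))
  }
  codons
}

# one synthetic CDS (sense strand): ATG start, body codons, weighted stop
.sample_gene <- function(len_codons, gc12, gc3, stop_weights,
                         force_stop = NULL) {
  body <- .sample_codons(max(0L, len_codons - 2L), gc12, gc3)
  stop_codon <- if (!is.null(force_stop)) force_stop
  else sample(names(stop_weights), 1L, prob = stop_weights)
  paste(c("ATG", body, stop_codon), collapse = "")
}

#' Generate a synthetic annotated genome
#'
#' Genes are sampled per the spec's positional GC targets (realised values
#' converge to the targets as gene count and length grow), placed on random
#' strands and separated by intergenic spacers whose GC matches the genome
#' average. The returned truth table records each gene's realised GC1/GC2/GC3
#' (terminal stop excluded) and stop codon, sufficient to score every
#' downstream analysis without re-deriving ground truth. Byte-identical
#' reruns for a fixed spec.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `synthetic_genome`: list with `record`,
#'   `features`, `truth` (data frame with `locus_tag`, `strand`, `gc1`,
#'   `gc2`, `gc3`, `stop`, `foreign`), and `spec`.
#' @export
gen_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, .gen_genome_impl(spec))
}

.gen_genome_impl <- function(spec) {
  overall_gc <- (2 * spec$target_gc12 + spec$target_gc3) / 3
  lens <- pmax(20L, stats::rpois(spec$n_genes, spec$mean_gene_len))
  genes <- vapply(lens, .sample_gene, character(1),
                  gc12 = spec$target_gc12, gc3 = spec$target_gc3,
                  stop_weights = spec$stop_weights)
  strands <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
  spacer_lens <- pmax(10L, stats::rpois(spec$n_genes + 1L,
                                        spec$intergenic_mean))
  pieces <- character(0)
  start <- integer(spec$n_genes); end <- integer(spec$n_genes)
  pos <- 0L
  for (i in seq_len(spec$n_genes)) {
    sp <- paste(.sample_bases(spacer_lens[i], overall_gc), collapse = "")
    pieces <- c(pieces, sp)
    pos <- pos + spacer_lens[i]
    g <- genes[i]
    placed <- if (strands[i] == "-") reverse_complement(g) else g
    pieces <- c(pieces, placed)
    start[i] <- pos
    end[i] <- pos + nchar(g)
    pos <- end[i]
  }
  pieces <- c(pieces, paste(.sample_bases(spacer_lens[spec$n_genes + 1L],
                                          overall_gc), collapse = ""))
  record <- seq_record(spec$contig_id, paste(pieces, collapse = ""),
                       moltype = "nucleotide")
  tags <- sprintf("g%03d", seq_len(spec$n_genes))
  features <- gene_features(spec$contig_id, start, end, strands, tags,
                            product = "synthetic gene")
  pos_gc <- t(vapply(genes, codon_position_gc, numeric(3)))
  truth <- data.frame(locus_tag = tags, strand = strands,
                      gc1 = unname(pos_gc[, 1]), gc2 = unname(pos_gc[, 2]),
                      gc3 = unname(pos_gc[, 3]),
                      stop = substring(genes, nchar(genes) - 2L),
                      foreign = FALSE, stringsAsFactors = FALSE)
  structure(list(record = record, features = features, truth = truth,
                 spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome %s> %d bp, %d genes (GC %.3f)\n",
              x$record$id, length(x$record), nrow(x$features),
              gc_content(x$record)))
  invisible(x)
}

#' Insert a compositionally foreign gene into a synthetic genome
#'
#' Adds one gene with near-saturated GC3, depressed GC1/GC2 and a TAA stop
#' codon -- the compositional signature of a horizontally acquired gene that
#' ameliorated its third codon positions toward a high-GC host -- at a
#' random intergenic position. Downstream, the inserted gene should attain
#' the contig's maximum GC3 z-score in [outlier_report()] and be its only
#' TAA gene when the host's stop weights exclude TAA.
#'
#' @param genome A `synthetic_genome` from [gen_genome()].
#' @param foreign_gc3 GC target at codon position 3 of the foreign gene.
#' @param foreign_gc12 GC target at positions 1 and 2.
#' @param gene_len Length in codons (defaults to the host spec's mean).
#' @param seed Integer seed for the insertion.
#' @return The updated `synthetic_genome`; the new gene carries locus tag
#'   `"foreign_001"` and `foreign = TRUE` in the truth table.
#' @export
insert_foreign_gene <- function(genome, foreign_gc3 = 0.95,
                                foreign_gc12 = 0.35, gene_len = NULL,
                                seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (is.null(gene_len)) gene_len <- genome$spec$mean_gene_len
  withr::with_seed(seed, {
    f <- genome$features
    L <- length(genome$record)
    # candidate insertion points: any coordinate not inside a gene
    occupied <- rep(FALSE, L + 1L)
    for (i in seq_len(nrow(f)))
      occupied[(f$start[i] + 1L):f$end[i]] <- TRUE
    free <- which(!occupied) - 1L        # 0-based insertion offsets
    if (length(free) == 0L) stop("no intergenic space left for insertion")
    p <- free[sample.int(length(free), 1L)]
    gene <- .sample_gene(gene_len, foreign_gc12, foreign_gc3,
                         genome$spec$stop_weights, force_stop = "TAA")
    strand <- sample(c("+", "-"), 1L)
    placed <- if (strand == "-") reverse_complement(gene) else gene
    res <- genome$record$residues
    new_res <- paste0(substr(res, 1L, p), placed,
                      substr(res, p + 1L, nchar(res)))
    shift <- f$start >= p
    f$start[shift] <- f$start[shift] + nchar(gene)
    f$end[shift] <- f$end[shift] + nchar(gene)
    f$exons <- paste0(f$start, ":", f$end)   # synthetic CDS are single-exon
    newf <- gene_features(genome$spec$contig_id, p, p + nchar(gene), strand,
                          "foreign_001", product = "foreign insertion")
    f <- rbind(f, newf)
    f <- f[order(f$start), , drop = FALSE]
    rownames(f) <- NULL
    pg <- codon_position_gc(gene)
    genome$record <- seq_record(genome$record$id, new_res,
                                moltype = "nucleotide")
    genome$features <- f
    genome$truth <- rbind(genome$truth,
                          data.frame(locus_tag = "foreign_001",
                                     strand = strand, gc1 = pg[["gc1"]],
                                     gc2 = pg[["gc2"]], gc3 = pg[["gc3"]],
                                     stop = "TAA", foreign = TRUE,
                                     stringsAsFactors = FALSE))
    genome
  })
}

#' Generate a multi-genome panel with a stop-codon/GC trend
#'
#' Genomes are spread across `gc_range`; stop-codon weights follow the
#' canonical bacterial pattern with tunable strength `s`: with `t` the
#' genome's relative position in the GC range, `TAA ~ exp(s (0.5 - t))`,
#' `TGA ~ exp(s (t - 0.5))`, `TAG` flat and low. `trend_strength = 0` gives
#' exchangeable stop usage (the permutation null); the default 3 is a strong
#' trend under which the TAA and TGA rank correlations with GC approach -1
#' and +1. The classical survey scale of 30 genomes is the default.
#'
#' @param n_genomes Number of genomes (>= 4).
#' @param gc_range Length-2 increasing vector of genome GC bounds in `[0,1]`.
#' @param trend_strength Non-negative trend strength `s`.
#' @param n_genes,mean_gene_len,intergenic_mean Per-genome size parameters.
#' @param seed Integer seed.
#' @return List of `synthetic_genome`s with record ids `genome01`, ...
#' @export
gen_genome_panel <- function(n_genomes = 30L, gc_range = c(0.30, 0.75),
                             trend_strength = 3, n_genes = 40L,
                             mean_gene_len = 120L, intergenic_mean = 60L,
                             seed = 1L) {
  if (n_genomes < 4L) stop("n_genomes must be >= 4")
  if (length(gc_range) != 2L || any(gc_range < 0) || any(gc_range > 1) ||
      gc_range[1] >= gc_range[2])
    stop("gc_range must be an increasing pair of fractions in [0, 1]")
  if (trend_strength < 0) stop("trend_strength must be >= 0")
  subseeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, n_genomes))
  t <- seq(0, 1, length.out = n_genomes)
  g <- gc_range[1] + t * diff(gc_range)
  lapply(seq_len(n_genomes), function(i) {
    w <- c(TAA = exp(trend_strength * (0.5 - t[i])), TAG = 0.3,
           TGA = exp(trend_strength * (t[i] - 0.5)))
    gen_genome(genome_spec(n_genes = n_genes, mean_gene_len = mean_gene_len,
                           target_gc3 = g[i], target_gc12 = g[i],
                           stop_weights = w,
                           intergenic_mean = intergenic_mean,
                           seed = subseeds[i],
                           contig_id = sprintf("genome%02d", i)))
  })
}

#' Specification of a simulated protein family
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param bl_range Branch-length range (substitutions per site per unit
#'   rate), drawn uniformly per edge.
#' @param rate Substitution rate multiplier.
#' @param seq_length Protein length in residues.
#' @param seed Integer seed.
#' @return An object of class `tree_spec`.
#' @export
tree_spec <- function(n_taxa = 8L, bl_range = c(0.02, 0.2), rate = 1,
                      seq_length = 1000L, seed = 1L) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  if (length(bl_range) != 2L || any(bl_range <= 0) ||
      bl_range[1] > bl_range[2])
    stop("bl_range must be a positive increasing pair")
  if (rate <= 0 || seq_length < 1L) stop("rate and seq_length must be positive")
  structure(list(n_taxa = as.integer(n_taxa), bl_range = bl_range,
                 rate = rate, seq_length = as.integer(seq_length),
                 seed = as.integer(seed)),
            class = "tree_spec")
}

.AA20 <- setdiff(.AA_ALPHABET, "X")

#' Simulate a protein family on a random tree
#'
#' A uniform-root, Poisson-substitution model: on each branch the number of
#' substitution events is `Poisson(rate * length * seq_length)`, each event
#' hits a uniform site and replaces the residue with a uniform draw from the
#' other 19 amino acids (a 20-state Jukes-Cantor-type process, so the
#' expected mismatch fraction between two leaves at total path length `t` is
#' `19/20 (1 - exp(-20/19 rate t))`). No indels are simulated, so the leaf
#' sequences are a true multiple alignment.
#'
#' @param ts A [tree_spec()].
#' @return List with `tree` (the true `ape::phylo`, leaves `t1...`),
#'   `proteins` (named character vector of leaf sequences) and `alignment`
#'   (identical to `proteins`; kept separate for interface symmetry).
#' @export
simulate_protein_family <- function(ts) {
  stopifnot(inherits(ts, "tree_spec"))
  withr::with_seed(ts$seed, {
    tree <- ape::rtree(ts$n_taxa, br = NULL)
    tree$edge.length <- stats::runif(nrow(tree$edge), ts$bl_range[1],
                                     ts$bl_range[2])
    ntip <- length(tree$tip.label)
    L <- ts$seq_length
    seqs <- vector("list", ntip + tree$Nnode)
    root <- ntip + 1L
    seqs[[root]] <- sample(.AA20, L, replace = TRUE)
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; kid <- edges[e, 2]
      s <- seqs[[par]]
      nsub <- stats::rpois(1L, ts$rate * lens[e] * L)
      if (nsub > 0L) {
        sites <- sample.int(L, nsub, replace = TRUE)
        for (ev in seq_len(nsub)) {
          cur <- s[sites[ev]]
          s[sites[ev]] <- sample(setdiff(.AA20, cur), 1L)
        }
      }
      seqs[[kid]] <- s
    }
    proteins <- vapply(seq_len(ntip), function(i)
      paste(seqs[[i]], collapse = ""), character(1))
    names(proteins) <- tree$tip.label
    list(tree = tree, proteins = proteins, alignment = proteins)
  })
}

#' Generate three genomes sharing a planted conserved gene block
#'
#' A core block of genes (including the anchor, transcribed on fixed strands
#' in a fixed order) is shared by all three genomes, with each genome's copy
#' diverged by random codon replacement at rate `mut_codon_rate`; each
#' genome additionally receives private random genes inserted between core
#' genes. Conserved-group recovery on this fixture should return exactly the
#' core block.
#'
#' @param n_core Number of shared core genes (>= 3; the middle one is the
#'   anchor, locus tag `"anchor"`, core tags `core01`, ...).
#' @param n_private Private genes per genome.
#' @param mut_codon_rate Per-codon replacement probability per genome.
#' @param mean_gene_len Gene length in codons.
#' @param gc GC fraction used for all positions and spacers.
#' @param seed Integer seed.
#' @return List with `genomes` (three `synthetic_genome`-like lists) and
#'   `anchor_tag`, `core_tags`.
#' @export
gen_synteny_trio <- function(n_core = 6L, n_private = 2L,
                             mut_codon_rate = 0.05, mean_gene_len = 120L,
                             gc = 0.6, seed = 1L) {
  if (n_core < 3L) stop("n_core must be >= 3")
  withr::with_seed(seed, {
    core_lens <- pmax(20L, stats::rpois(n_core, mean_gene_len))
    core <- lapply(core_lens, function(l)
      .codons(.sample_gene(l, gc, gc, c(TAA = 1, TAG = 1, TGA = 1))))
    core_strands <- sample(c("+", "-"), n_core, replace = TRUE)
    anchor_idx <- (n_core + 1L) %/% 2L
    tags <- sprintf("core%02d", seq_len(n_core))
    tags[anchor_idx] <- "anchor"

    mutate <- function(codons) {
      n <- length(codons)
      hit <- which(stats::runif(n - 2L) < mut_codon_rate) + 1L  # keep start/stop
      if (length(hit) > 0L)
        codons[hit] <- .sample_codons(length(hit), gc, gc)
      codons
    }
    genomes <- lapply(c("genomeA", "genomeB", "genomeC"), function(gid) {
      gene_seqs <- vapply(core, function(cd)
        paste(mutate(cd), collapse = ""), character(1))
      strands <- core_strands
      gtags <- tags
      # interleave private genes at random inter-core slots
      if (n_private > 0L) {
        priv <- vapply(pmax(20L, stats::rpois(n_private, mean_gene_len)),
                       function(l)
                         .sample_gene(l, gc, gc, c(TAA = 1, TAG = 1, TGA = 1)),
                       character(1))
        slots <- sample.int(n_core + 1L, n_private, replace = TRUE) - 1L
        ord <- order(slots)
        for (s in seq_along(ord)) {
          at <- slots[ord[s]] + (s - 1L)   # account for earlier insertions
          gene_seqs <- append(gene_seqs, priv[ord[s]], after = at)
          strands <- append(strands, sample(c("+", "-"), 1L), after = at)
          gtags <- append(gtags, sprintf("%s_priv%02d", gid, s), after = at)
        }
      }
      n <- length(gene_seqs)
      spacers <- pmax(10L, stats::rpois(n + 1L, 60L))
      pieces <- character(0); pos <- 0L
      start <- integer(n); end <- integer(n)
      for (i in seq_len(n)) {
        pieces <- c(pieces, paste(.sample_bases(spacers[i], gc),
                                  collapse = ""))
        pos <- pos + spacers[i]
        placed <- if (strands[i] == "-") reverse_complement(gene_seqs[i])
        else gene_seqs[i]
        pieces <- c(pieces, placed)
        start[i] <- pos; end[i] <- pos + nchar(gene_seqs[i]); pos <- end[i]
      }
      pieces <- c(pieces, paste(.sample_bases(spacers[n + 1L], gc),
                                collapse = ""))
      record <- seq_record(gid, paste(pieces, collapse = ""),
                           moltype = "nucleotide")
      list(record = record,
           features = gene_features(gid, start, end, strands, gtags,
                                    product = "synthetic gene"),
           genome_id = gid)
    })
    list(genomes = genomes, anchor_tag = "anchor",
         core_tags = tags)
  })
}
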