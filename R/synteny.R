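#' Extract a gene neighborhood around an anchor gene
#'
#' Returns up to `k` genes on each side of the anchor, in genomic order.
#' With `normalize = TRUE` (the default) the neighborhood is oriented so the
#' anchor is transcribed rightwards -- the convention used when drawing
#' synteny figures -- by reverse-complementing the contig and mirroring all
#' coordinates and strands when the anchor lies on the minus strand.
#'
#' @param record Nucleotide [seq_record()] of the replicon.
#' @param features Feature table (see [gene_features()]).
#' @param anchor_tag Locus tag of the anchor gene.
#' @param k Maximum number of flanking genes on each side.
#' @param genome_id Identifier of the genome (defaults to the record id).
#' @param normalize Orient the neighborhood anchor-rightwards.
#' @return An object of class `neighborhood`: list with `genome_id`,
#'   `record`, `features` (anchor + flank, sorted by start), `anchor_tag`,
#'   `normalized`.
#' @export
extract_neighborhood <- function(record, features, anchor_tag, k = 8L,
                                 genome_id = record$id, normalize = TRUE) {
  if (!(anchor_tag %in% features$locus_tag))
    stop("anchor '", anchor_tag, "' not found among features")
  features <- features[order(features$start), , drop = FALSE]
  idx <- which(features$locus_tag == anchor_tag)
  keep <- max(1L, idx - k):min(nrow(features), idx + k)
  nbr <- structure(list(genome_id = genome_id, record = record,
                        features = features[keep, , drop = FALSE],
                        anchor_tag = anchor_tag, normalized = FALSE),
                   class = "neighborhood")
  anchor <- nbr$features[nbr$features$locus_tag == anchor_tag, ]
  if (normalize && anchor$strand == "-") nbr <- flip_neighborhood(nbr)
  if (normalize) nbr$normalized <- TRUE
  nbr
}

#' Mirror a neighborhood onto the opposite strand
#'
#' Reverse-complements the underlying record and mirrors every feature
#' (`start' = L - end`, `end' = L - start`, strand flipped), re-sorting by
#' start. Applying the flip twice returns the original neighborhood.
#'
#' @param nbr A `neighborhood`.
#' @return The mirrored `neighborhood`.
#' @export
flip_neighborhood <- function(nbr) {
  stopifnot(inherits(nbr, "neighborhood"))
  L <- length(nbr$record)
  f <- nbr$features
  new_start <- L - f$end
  new_end <- L - f$start
  # mirror each exon interval as well
  f$exons <- vapply(seq_len(nrow(f)), function(i) {
    ex <- .feature_exons(f[i, , drop = FALSE])
    ex2 <- cbind(start = L - rev(ex[, "end"]), end = L - rev(ex[, "start"]))
    paste(paste0(ex2[, "start"], ":", ex2[, "end"]), collapse = ",")
  }, character(1))
  f$start <- new_start
  f$end <- new_end
  f$strand <- ifelse(f$strand == "+", "-", "+")
  f <- f[order(f$start), , drop = FALSE]
  nbr$record <- reverse_complement(nbr$record)
  nbr$features <- f
  nbr
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("<neighborhood %s> anchor %s, %d genes%s\n", x$genome_id,
              x$anchor_tag, nrow(x$features),
              if (x$normalized) " (anchor-rightward)" else ""))
  invisible(x)
}

#' Translated proteins of a neighborhood
#'
#' Translates every complete CDS of the neighborhood (partial CDS -- length
#' not a multiple of 3 or lacking a canonical stop -- are skipped).
#'
#' @param nbr A `neighborhood`.
#' @return Named list of protein [seq_record()]s (names are locus tags).
#' @export
neighborhood_proteins <- function(nbr) {
  stopifnot(inherits(nbr, "neighborhood"))
  out <- list()
  for (i in seq_len(nrow(nbr$features))) {
    f <- nbr$features[i, , drop = FALSE]
    if (gene_stop(f, nbr$record) == "partial") next
    out[[f$locus_tag]] <- translate_cds(extract_cds(nbr$record, f),
                                        allow_alt_start = TRUE)
  }
  out
}

#' Match orthologs between two neighborhoods
#'
#' Reciprocal best hits by global alignment score, accepted only when the
#' score reaches `min_score_frac` of the self-alignment score of the shorter
#' protein of the pair. Each gene appears in at most one pair, and the result
#' is symmetric in its arguments.
#'
#' @param nbrA,nbrB Two `neighborhood`s.
#' @param min_score_frac Acceptance threshold relative to the shorter
#'   protein's self-score.
#' @param ... Passed to [align_pair()].
#' @return Data frame with columns `a`, `b` (locus tags) and `score`.
#' @export
match_orthologs <- function(nbrA, nbrB, min_score_frac = 0.3, ...) {
  pa <- neighborhood_proteins(nbrA)
  pb <- neighborhood_proteins(nbrB)
  empty <- data.frame(a = character(), b = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(pa) == 0L || length(pb) == 0L) return(empty)
  # deterministic ordering for argmax tie-breaks
  pa <- pa[order(names(pa))]; pb <- pb[order(names(pb))]
  score <- matrix(0, length(pa), length(pb),
                  dimnames = list(names(pa), names(pb)))
  for (i in seq_along(pa))
    for (j in seq_along(pb))
      score[i, j] <- align_pair(pa[[i]], pb[[j]], ...)$score
  best_b <- apply(score, 1, which.max)   # best hit in B of each a
  best_a <- apply(score, 2, which.max)   # best hit in A of each b
  self_a <- vapply(pa, .self_score, numeric(1))
  self_b <- vapply(pb, .self_score, numeric(1))
  rows <- empty
  for (i in seq_along(pa)) {
    j <- best_b[i]
    if (best_a[j] != i) next                         # not reciprocal
    shorter_self <- if (length(pa[[i]]) == length(pb[[j]]))
      min(self_a[i], self_b[j])
    else if (length(pa[[i]]) < length(pb[[j]])) self_a[i] else self_b[j]
    if (score[i, j] < min_score_frac * shorter_self) next
    rows <- rbind(rows, data.frame(a = names(pa)[i], b = names(pb)[j],
                                   score = score[i, j],
                                   stringsAsFactors = FALSE))
  }
  rows
}

#' Relative orientation of two neighbouring genes
#'
#' Taking the gene with the smaller start as upstream: equal strands are
#' `"co-directional"`; upstream `+` with downstream `-` is `"face-to-face"`
#' (convergent, transcribed toward each other); upstream `-` with downstream
#' `+` is `"back-to-back"` (divergent). The classification is symmetric in
#' its arguments. Overlapping genes are an error reporting the overlap
#' length.
#'
#' @param geneA,geneB Single feature rows on the same replicon.
#' @return One of `"co-directional"`, `"face-to-face"`, `"back-to-back"`.
#' @export
classify_orientation <- function(geneA, geneB) {
  g <- rbind(as.data.frame(geneA)[, c("start", "end", "strand")],
             as.data.frame(geneB)[, c("start", "end", "strand")])
  g <- g[order(g$start), ]
  overlap <- g$end[1] - g$start[2]
  if (overlap > 0)
    stop("genes overlap by ", overlap, " bp")
  up <- g$strand[1]; down <- g$strand[2]
  if (up == down) "co-directional"
  else if (up == "+" && down == "-") "face-to-face"
  else "back-to-back"
}

#' Cross-genome synteny table of conserved neighbours
#'
#' Builds ortholog groups across two or more anchored neighborhoods as the
#' transitive closure of pairwise reciprocal best hits, adding edges in
#' decreasing score order and rejecting any edge that would place two genes
#' of the same genome in one group. Each gene belongs to at most one group;
#' groups present in at least two genomes are marked conserved.
#'
#' @param nbrs List of `neighborhood`s (>= 2).
#' @param min_score_frac Passed to [match_orthologs()].
#' @param ... Passed to [align_pair()].
#' @return Data frame sorted by genome then gene-rank offset from the
#'   anchor, with columns `genome_id`, `group`, `locus_tag`, `offset`,
#'   `strand`, `conserved`.
#' @export
synteny_table <- function(nbrs, min_score_frac = 0.3, ...) {
  if (length(nbrs) < 2L)
    stop("synteny table needs at least 2 neighborhoods (got ",
         length(nbrs), ")")
  gids <- vapply(nbrs, function(x) x$genome_id, character(1))
  if (anyDuplicated(gids)) stop("duplicate genome_id among neighborhoods")

  # gene universe, keyed genome|locus_tag
  genes <- do.call(rbind, lapply(nbrs, function(nb) {
    f <- nb$features[order(nb$features$start), , drop = FALSE]
    anchor_rank <- which(f$locus_tag == nb$anchor_tag)
    data.frame(genome_id = nb$genome_id, locus_tag = f$locus_tag,
               offset = seq_len(nrow(f)) - anchor_rank, strand = f$strand,
               stringsAsFactors = FALSE)
  }))
  genes$key <- paste(genes$genome_id, genes$locus_tag, sep = "|")

  edges <- list()
  for (i in seq_len(length(nbrs) - 1L)) {
    for (j in (i + 1L):length(nbrs)) {
      mm <- match_orthologs(nbrs[[i]], nbrs[[j]],
                            min_score_frac = min_score_frac, ...)
      if (nrow(mm) > 0)
        edges[[length(edges) + 1L]] <-
          data.frame(from = paste(gids[i], mm$a, sep = "|"),
                     to = paste(gids[j], mm$b, sep = "|"),
                     score = mm$score, stringsAsFactors = FALSE)
    }
  }
  # union-find over gene indices, with a one-gene-per-genome-per-group
  # constraint; edges are offered in decreasing score order
  n_genes <- nrow(genes)
  parent <- seq_len(n_genes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(edges) > 0) {
    e <- do.call(rbind, edges)
    e <- e[order(-e$score, e$from, e$to), , drop = FALSE]
    for (r in seq_len(nrow(e))) {
      ia <- match(e$from[r], genes$key)
      ib <- match(e$to[r], genes$key)
      ra <- find(ia); rb <- find(ib)
      if (ra == rb) next
      roots <- vapply(seq_len(n_genes), find, integer(1))
      ga <- genes$genome_id[roots == ra]
      gb <- genes$genome_id[roots == rb]
      if (length(intersect(ga, gb)) > 0) next   # genome conflict: skip edge
      parent[rb] <- ra
    }
  }
  genes$comp <- genes$key[vapply(seq_len(n_genes), find, integer(1))]

  sizes <- tapply(genes$genome_id, genes$comp, function(g) length(unique(g)))
  genes$conserved <- unname(sizes[genes$comp] >= 2)
  # stable group ids: number conserved groups first, by first appearance
  ord <- order(match(genes$genome_id, gids), genes$offset)
  genes <- genes[ord, , drop = FALSE]
  grp_levels <- unique(genes$comp[genes$conserved])
  genes$group <- ifelse(genes$conserved,
                        sprintf("OG%02d", match(genes$comp, grp_levels)),
                        NA_character_)
  rownames(genes) <- NULL
  genes[, c("genome_id", "group", "locus_tag", "offset", "strand",
            "conserved")]
}
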