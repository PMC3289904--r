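#' Stop codon of a single gene
#'
#' The last in-frame codon of the strand-aware CDS. A CDS whose length is
#' not a multiple of 3, or whose last codon is not a canonical stop, is
#' reported as `"partial"` rather than rejected (genes truncated at contig
#' edges are common in draft assemblies).
#'
#' @param feature A single feature row (see [gene_features()]).
#' @param record The nucleotide [seq_record()] carrying the feature.
#' @return One of `"TAA"`, `"TAG"`, `"TGA"`, `"partial"`.
#' @export
gene_stop <- function(feature, record) {
  cds <- extract_cds(record, feature)$residues
  n <- nchar(cds)
  if (n %% 3L != 0L || n < 3L) return("partial")
  last <- substr(cds, n - 2L, n)
  if (last %in% .STOP_CODONS) last else "partial"
}

#' Stop-codon usage census of a replicon
#'
#' Counts TAA/TAG/TGA over the complete coding genes of an annotated
#' replicon, paired with the replicon's genomic GC content. Genes without a
#' canonical in-frame stop (partial CDS) are excluded from the denominator
#' and reported in `n_partial`.
#'
#' @param record Nucleotide [seq_record()] of the replicon.
#' @param features Feature table (see [gene_features()]).
#' @param replicon_id Identifier for the census row; defaults to the record
#'   id.
#' @return An object of class `stop_census`: a list with `replicon_id`,
#'   `genome_gc`, `n_genes`, `n_partial`, `counts` (named TAA/TAG/TGA) and
#'   `fractions` (summing to 1 when `n_genes > 0`).
#' @export
stop_codon_census <- function(record, features, replicon_id = record$id) {
  stops <- if (nrow(features) > 0)
    vapply(seq_len(nrow(features)), function(i)
      gene_stop(features[i, , drop = FALSE], record), character(1))
  else character()
  complete <- stops[stops != "partial"]
  counts <- vapply(.STOP_CODONS, function(s) sum(complete == s), integer(1))
  n <- length(complete)
  fractions <- if (n > 0) counts / n else counts * NA_real_
  structure(list(replicon_id = replicon_id, genome_gc = gc_content(record),
                 n_genes = n, n_partial = sum(stops == "partial"),
                 counts = counts, fractions = fractions),
            class = "stop_census")
}

#' @export
print.stop_census <- function(x, ...) {
  cat(sprintf("<stop_census %s> GC=%.3f, %d genes (%d partial): TAA=%d TAG=%d TGA=%d\n",
              x$replicon_id, x$genome_gc, x$n_genes, x$n_partial,
              x$counts["TAA"], x$counts["TAG"], x$counts["TGA"]))
  invisible(x)
}

#' @export
as.data.frame.stop_census <- function(x, ...) {
  data.frame(replicon_id = x$replicon_id, genome_gc = x$genome_gc,
             n_genes = x$n_genes, n_partial = x$n_partial,
             TAA = unname(x$counts["TAA"]), TAG = unname(x$counts["TAG"]),
             TGA = unname(x$counts["TGA"]),
             frac_TAA = unname(x$fractions["TAA"]),
             frac_TAG = unname(x$fractions["TAG"]),
             frac_TGA = unname(x$fractions["TGA"]),
             stringsAsFactors = FALSE)
}

#' Correlate stop-codon usage with genomic GC across replicons
#'
#' For each stop codon, the rank (Spearman) correlation of its per-replicon
#' fraction against genomic GC, with a two-sided p-value. In bacteria the
#' expected pattern is a negative TAA and positive TGA correlation with GC,
#' with TAG staying low and weakly correlated. Pearson correlation is
#' available behind `method`.
#'
#' @param censuses List of [stop_codon_census()] objects (at least 4).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param use_counts Correlate raw counts instead of fractions.
#' @return Data frame with columns `codon`, `estimate`, `p_value`, `n`.
#' @export
stop_codon_correlation <- function(censuses, method = c("spearman", "pearson"),
                                   use_counts = FALSE) {
  method <- match.arg(method)
  if (length(censuses) < 4L)
    stop("need at least 4 censuses (got ", length(censuses), ")")
  gc <- vapply(censuses, function(x) x$genome_gc, numeric(1))
  if (stats::sd(gc) == 0) stop("degenerate predictor: genomic GC is constant")
  rows <- lapply(.STOP_CODONS, function(codon) {
    y <- vapply(censuses, function(x)
      if (use_counts) as.numeric(x$counts[codon]) else x$fractions[codon],
      numeric(1))
    ct <- suppressWarnings(stats::cor.test(gc, y, method = method,
                                           exact = FALSE))
    data.frame(codon = codon, estimate = unname(ct$estimate),
               p_value = ct$p.value, n = length(gc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Length-weighted genomic GC over several replicons
#'
#' @param records List of nucleotide [seq_record()]s.
#' @return Fraction in `[0, 1]`.
#' @export
multi_replicon_gc <- function(records) {
  if (inherits(records, "seq_record")) records <- list(records)
  lens <- vapply(records, length, integer(1))
  gcs <- vapply(records, gc_content, numeric(1))
  sum(gcs * lens) / sum(lens)
}
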