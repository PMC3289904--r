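#' Gene feature tables
#'
#' Gene features are plain data frames with one row per coding gene and
#' columns `contig_id`, `start`, `end`, `strand`, `locus_tag`, `product`,
#' plus `exons`, a compact multi-interval encoding used by spliced
#' (`join(...)`) CDS. Coordinates are 0-based half-open throughout the
#' package; GenBank input is converted at the boundary (1-based inclusive
#' `a..b` becomes `(a-1, b)`).
#'
#' @param contig_id Contig identifier(s).
#' @param start 0-based inclusive start offset(s).
#' @param end Exclusive end offset(s); must satisfy `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @param locus_tag Unique gene label(s).
#' @param product Product description(s).
#' @param exons Optional multi-interval encoding `"s1:e1,s2:e2"` (0-based
#'   half-open, in genomic order); defaults to the single interval.
#' @return A `data.frame` of features sorted as given.
#' @export
gene_features <- function(contig_id, start, end, strand, locus_tag,
                          product = "", exons = NA_character_) {
  df <- data.frame(contig_id = contig_id, start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   locus_tag = locus_tag, product = product,
                   exons = exons, stringsAsFactors = FALSE)
  if (any(df$start < 0L)) stop("feature start must be >= 0")
  if (any(df$start >= df$end)) stop("feature must satisfy start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(df$locus_tag)) stop("duplicate locus_tag")
  df$exons <- ifelse(is.na(df$exons), paste0(df$start, ":", df$end), df$exons)
  df
}

.feature_exons <- function(feature) {
  parts <- strsplit(feature$exons, ",", fixed = TRUE)[[1]]
  m <- do.call(rbind, strsplit(parts, ":", fixed = TRUE))
  matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

#' Extract the coding sequence of a feature
#'
#' Returns the strand-aware CDS: for a minus-strand feature the reverse
#' complement is returned, and multi-exon features are concatenated in
#' transcription order. The result length equals `end - start` in the
#' single-interval case.
#'
#' @param record Nucleotide [seq_record()] the feature lies on.
#' @param feature A single feature row (see [gene_features()]).
#' @return A nucleotide [seq_record()] named after the feature's locus tag.
#' @export
extract_cds <- function(record, feature) {
  if (is.data.frame(feature)) {
    if (nrow(feature) != 1L) stop("'feature' must be a single feature row")
    feature <- as.list(feature)
  }
  L <- length(record)
  ex <- .feature_exons(feature)
  if (any(ex[, "start"] < 0L) || any(ex[, "end"] > L))
    stop("feature '", feature$locus_tag, "' extends beyond sequence (length ",
         L, ")")
  segs <- substring(record$residues, ex[, "start"] + 1L, ex[, "end"])
  cds <- paste(segs, collapse = "")
  if (feature$strand == "-") cds <- reverse_complement(cds)
  seq_record(feature$locus_tag, cds, moltype = "nucleotide",
             desc = if (is.null(feature$product)) "" else feature$product)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codons <- function(x) {
  s <- .residues(x)
  n <- nchar(s)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' Translates with the standard genetic code; a terminal stop codon is
#' dropped, and an internal stop codon is an error reporting its 1-based
#' codon index. Codons containing `N` translate to `X`. With
#' `allow_alt_start = TRUE`, `GTG`/`TTG` initiator codons (common in
#' Actinobacteria, translation table 11 behaviour) are rendered as `M`.
#'
#' @param cds Nucleotide [seq_record()] or string; length must be a multiple
#'   of 3.
#' @param allow_alt_start Treat a leading `GTG`/`TTG` as methionine.
#' @return A protein [seq_record()].
#' @export
translate_cds <- function(cds, allow_alt_start = FALSE) {
  codons <- .codons(cds)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"                       # ambiguous (N-containing) codons
  n <- length(aa)
  if (aa[n] == "*") {
    aa <- aa[-n]
    n <- n - 1L
  }
  internal <- which(aa == "*")
  if (length(internal) > 0L)
    stop("internal stop codon at codon ", internal[1])
  if (n == 0L) stop("coding sequence contains only a stop codon")
  if (allow_alt_start && codons[1] %in% c("GTG", "TTG")) aa[1] <- "M"
  id <- if (inherits(cds, "seq_record")) cds$id else "translation"
  desc <- if (inherits(cds, "seq_record")) cds$desc else ""
  seq_record(id, paste(aa, collapse = ""), moltype = "protein", desc = desc)
}
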