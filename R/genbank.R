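#' Read a GenBank flat file
#'
#' Minimal reader for annotated contigs: parses the LOCUS name, the CDS
#' features of the FEATURES table and the ORIGIN sequence block. GenBank
#' 1-based inclusive locations (`a..b`) are converted to the package's
#' 0-based half-open convention `(a-1, b)`; `complement(...)` sets strand
#' `-`; `join(...)` exons are kept as a multi-interval feature concatenated
#' exon-wise in transcription order by [extract_cds()]. Partial-location
#' markers (`<`, `>`) set the feature's `partial` column rather than being
#' rejected.
#'
#' @param path Path to a GenBank flat file with an ORIGIN block.
#' @return A list with elements `record` (a nucleotide [seq_record()]) and
#'   `features` (a [gene_features()] data frame with an extra logical
#'   `partial` column).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  contig_id <- if (length(locus_line) > 0)
    strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "\\s+")[[1]][1]
  else "contig"

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) stop("GenBank file has no ORIGIN block: ", path)
  seq_lines <- lines[(origin_at[1] + 1L):length(lines)]
  end_at <- grep("^//", seq_lines)
  if (length(end_at) > 0L) seq_lines <- seq_lines[seq_len(end_at[1] - 1L)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(residues)) stop("empty ORIGIN block: ", path)
  record <- seq_record(contig_id, residues, moltype = "nucleotide")

  feats <- .parse_genbank_cds(lines[seq_len(origin_at[1] - 1L)], contig_id,
                              length(record))
  list(record = record, features = feats)
}

# Parse CDS entries of the FEATURES table into a gene_features data frame.
.parse_genbank_cds <- function(lines, contig_id, contig_len) {
  feat_at <- grep("^FEATURES", lines)
  rows <- list()
  if (length(feat_at) > 0L) {
    body <- lines[(feat_at[1] + 1L):length(lines)]
    # A feature starts at indent 5 with a key; qualifier/continuation lines
    # are indented 21.
    is_key <- grepl("^ {5}\\S", body)
    key_idx <- which(is_key)
    for (k in seq_along(key_idx)) {
      i <- key_idx[k]
      j <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(body)
      key <- sub("^ {5}(\\S+).*$", "\\1", body[i])
      if (key != "CDS") next
      block <- body[i:j]
      rows[[length(rows) + 1L]] <-
        .parse_cds_block(block, contig_id, contig_len, length(rows) + 1L)
    }
  }
  if (length(rows) == 0L) {
    f <- gene_features(character(), integer(), integer(), character(),
                       character())
    f$partial <- logical()
    return(f)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.parse_cds_block <- function(block, contig_id, contig_len, ordinal) {
  first <- sub("^ {5}\\S+\\s*", "", block[1])
  rest <- block[-1]
  qual_start <- grep("^ {21}/", rest)
  loc_extra <- if (length(qual_start) > 0L && qual_start[1] > 1L)
    rest[seq_len(qual_start[1] - 1L)]
  else if (length(qual_start) == 0L) rest
  else character()
  location <- gsub("\\s+", "", paste(c(first, trimws(loc_extra)), collapse = ""))

  qual <- function(name) {
    pat <- paste0("^ {21}/", name, "=")
    hit <- grep(pat, rest)
    if (length(hit) == 0L) return(NA_character_)
    # qualifier value may continue over lines until the next /qualifier
    val <- sub(pat, "", rest[hit[1]])
    m <- hit[1] + 1L
    while (m <= length(rest) && !grepl("^ {21}/", rest[m])) {
      val <- paste(val, trimws(rest[m]))
      m <- m + 1L
    }
    gsub("\"", "", val)
  }

  loc <- .parse_location(location)
  if (max(loc$exons[, "end"]) > contig_len)
    stop("CDS '", location, "' extends beyond sequence (length ",
         contig_len, ")")
  tag <- qual("locus_tag")
  if (is.na(tag)) tag <- qual("gene")
  if (is.na(tag)) tag <- sprintf("CDS_%03d", ordinal)
  product <- qual("product")
  if (is.na(product)) product <- ""

  exons <- paste(paste0(loc$exons[, "start"], ":", loc$exons[, "end"]),
                 collapse = ",")
  f <- gene_features(contig_id, min(loc$exons[, "start"]),
                     max(loc$exons[, "end"]), loc$strand, tag, product,
                     exons = exons)
  f$partial <- loc$partial
  f
}

# GenBank location string -> list(exons = 0-based half-open matrix in
# genomic order, strand, partial).
.parse_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  partial <- grepl("[<>]", loc)
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ex <- t(vapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      ab <- rep(as.integer(p), 2L)          # single-base location
    }
    if (anyNA(ab) || ab[1] > ab[2]) stop("cannot parse location part: ", p)
    c(ab[1] - 1L, ab[2])
  }, integer(2)))
  dimnames(ex) <- list(NULL, c("start", "end"))
  # transcription order for '-' strand is handled in extract_cds by
  # reverse-complementing the genomic-order concatenation
  list(exons = ex, strand = strand, partial = partial)
}

#' Convert between GenBank and internal coordinates
#'
#' GenBank locations are 1-based inclusive; the package stores 0-based
#' half-open intervals. These helpers implement the (bijective) conversion.
#'
#' @param a,b GenBank 1-based inclusive endpoints.
#' @param start,end 0-based half-open endpoints.
#' @return A two-element integer vector.
#' @export
genbank_to_internal <- function(a, b) c(start = as.integer(a) - 1L,
                                        end = as.integer(b))

#' @rdname genbank_to_internal
#' @export
internal_to_genbank <- function(start, end) c(a = as.integer(start) + 1L,
                                              b = as.integer(end))
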