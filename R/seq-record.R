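#' Sequence records
#'
#' A `seq_record` is the package's lightweight container for a single named
#' nucleotide or protein sequence. Residues are stored upper-case and are
#' validated against the declared alphabet: `A,C,G,T,N` for nucleotide
#' records, the 20 standard amino acids plus `X` for protein records.
#'
#' @param id Record identifier (non-empty string).
#' @param residues Sequence string (case-insensitive on input).
#' @param moltype `"nucleotide"`, `"protein"`, or `"auto"` to infer from the
#'   residue alphabet (a sequence consisting solely of `A,C,G,T,N` is taken
#'   as nucleotide).
#' @param desc Free-text description (may be empty).
#' @return An object of class `seq_record` with fields `id`, `desc`,
#'   `residues`, `moltype`.
#' @examples
#' r <- seq_record("x", "acgt")
#' r$residues    # "ACGT"
#' length(r)     # 4
#' @export
seq_record <- function(id, residues, moltype = c("auto", "nucleotide", "protein"),
                       desc = "") {
  moltype <- match.arg(moltype)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("record '", id, "': residues must be a non-empty string")
  residues <- toupper(residues)
  if (moltype == "auto") {
    moltype <- if (grepl("^[ACGTN]+$", residues)) "nucleotide" else "protein"
  }
  bad <- .first_illegal(residues, moltype)
  if (!is.na(bad))
    stop("record '", id, "': illegal ", moltype, " character '",
         substr(residues, bad, bad), "' at position ", bad)
  structure(list(id = id, desc = desc, residues = residues, moltype = moltype),
            class = "seq_record")
}

.NUC_ALPHABET <- c("A", "C", "G", "T", "N")
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.first_illegal <- function(residues, moltype) {
  alpha <- if (moltype == "nucleotide") .NUC_ALPHABET else .AA_ALPHABET
  ok <- strsplit(residues, "", fixed = TRUE)[[1]] %in% alpha
  if (all(ok)) NA_integer_ else which(!ok)[1]
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %s, %d %s\n", x$id, x$moltype, length(x),
              if (x$moltype == "nucleotide") "bp" else "aa"))
  invisible(x)
}

# Accept either a seq_record or a bare string; return the residue string.
.residues <- function(x) {
  if (inherits(x, "seq_record")) x$residues else toupper(as.character(x))
}

#' Reverse complement of a nucleotide sequence
#'
#' @param x A nucleotide `seq_record` or string (alphabet `A,C,G,T,N`).
#' @return Same type as the input, reverse complemented.
#' @export
reverse_complement <- function(x) {
  s <- .residues(x)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (inherits(x, "seq_record"))
    seq_record(x$id, rc, moltype = "nucleotide", desc = x$desc)
  else rc
}

#' Read a (multi-record) FASTA file
#'
#' Records are returned in file order; lower-case residues are normalised to
#' upper case and validated against the declared alphabet. An empty file or a
#' file without records is an error, as is any character outside the alphabet
#' (the error names the record and 1-based position).
#'
#' @param path Path to a FASTA file.
#' @param moltype Alphabet of the records (`"auto"` infers per record).
#' @return A named list of [seq_record()] objects (names are record ids).
#' @export
read_fasta <- function(path, moltype = c("auto", "nucleotide", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    h <- headers[i]
    id <- sub("\\s.*$", "", h)
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    out[[i]] <- seq_record(id, as.character(set[[i]]), moltype = moltype,
                           desc = desc)
  }
  names(out) <- vapply(out, function(r) r$id, character(1))
  out
}

#' Write sequence records to FASTA
#'
#' @param records A `seq_record` or list of them.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
    writeLines(paste0(">", header), con)
    starts <- seq(1L, nchar(r$residues), by = width)
    writeLines(substring(r$residues, starts,
                         pmin(starts + width - 1L, nchar(r$residues))), con)
  }
  invisible(path)
}
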