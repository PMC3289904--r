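#' Global pairwise protein alignment
#'
#' Optimal global (Needleman-Wunsch/Gotoh) alignment under affine gap
#' penalties, scored with a substitution matrix. Defaults are the classic
#' ClustalX-style settings: BLOSUM62, gap opening 10, gap extension 0.5 (a
#' gap of length L costs `gap_open + L * gap_extend`). The alignment engine
#' is `Biostrings::pairwiseAlignment`, which has a deterministic traceback.
#'
#' @param a,b Protein [seq_record()]s or strings (non-empty).
#' @param matrix Substitution matrix name (e.g. `"BLOSUM62"`, `"PAM250"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An object of class `pairwise_alignment`: list with gapped strings
#'   `a_aln`, `b_aln`, the optimal `score`, and `mismatch` -- the fraction D
#'   of mismatched columns among columns with no gap in either row.
#' @export
align_pair <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                       gap_extend = 0.5) {
  sa <- .residues(a); sb <- .residues(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  a_aln <- as.character(Biostrings::alignedPattern(pa))
  b_aln <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(a_aln, "", fixed = TRUE)[[1]]
  cb <- strsplit(b_aln, "", fixed = TRUE)[[1]]
  ok <- ca != "-" & cb != "-"
  mismatch <- if (any(ok)) mean(ca[ok] != cb[ok]) else NA_real_
  structure(list(a_aln = a_aln, b_aln = b_aln,
                 score = Biostrings::score(pa), mismatch = mismatch),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score=%.1f D=%.3f\n  %s\n  %s\n",
              x$score, x$mismatch, x$a_aln, x$b_aln))
  invisible(x)
}

# Self-alignment score: sum of diagonal substitution scores.
.self_score <- function(x, matrix = "BLOSUM62") {
  mat <- .subst_matrix(matrix)
  ch <- strsplit(.residues(x), "", fixed = TRUE)[[1]]
  sum(mat[cbind(ch, ch)])
}

.subst_env <- new.env(parent = emptyenv())
.subst_matrix <- function(name) {
  if (is.null(.subst_env[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .subst_env[[name]] <- get(name, envir = e)
  }
  .subst_env[[name]]
}

#' Kimura-corrected protein distance
#'
#' Corrects an observed mismatch fraction D for multiple substitutions with
#' the protein-distance correction used by ClustalX:
#' `d = -ln(1 - D - D^2/5)`. The correction is defined for `D < 0.85`;
#' beyond that the function errors unless `fallback_raw = TRUE`, in which
#' case the raw D is returned.
#'
#' @param D Mismatch fraction(s) in `[0, 1)`.
#' @param fallback_raw Return raw D where the correction is undefined.
#' @return Corrected distance(s), `d >= D`.
#' @examples
#' kimura_distance(0.5)  # -log(0.45)
#' @export
kimura_distance <- function(D, fallback_raw = FALSE) {
  if (any(D < 0 | D > 1, na.rm = TRUE)) stop("D must be in [0, 1]")
  out <- numeric(length(D))
  bad <- D >= 0.85
  if (any(bad, na.rm = TRUE)) {
    if (!fallback_raw)
      stop("mismatch fraction ", max(D), " beyond correction domain (D >= 0.85); ",
           "set fallback_raw = TRUE to use the uncorrected distance")
    out[bad] <- D[bad]
  }
  out[!bad] <- -log(1 - D[!bad] - D[!bad]^2 / 5)
  out
}

#' All-pairs Kimura-corrected distance matrix from unaligned proteins
#'
#' Aligns every pair globally with [align_pair()] and corrects the mismatch
#' fraction with [kimura_distance()]. Symmetric by construction.
#'
#' @param proteins Named list of protein [seq_record()]s or a named character
#'   vector; at least 3 with unique labels.
#' @param fallback_raw Passed to [kimura_distance()].
#' @param ... Passed to [align_pair()].
#' @return A symmetric numeric matrix with the labels as dimnames.
#' @export
protein_distance_matrix <- function(proteins, fallback_raw = FALSE, ...) {
  labels <- names(proteins)
  if (is.null(labels))
    labels <- vapply(proteins, function(p)
      if (inherits(p, "seq_record")) p$id else NA_character_, character(1))
  if (anyNA(labels) || any(!nzchar(labels))) stop("all proteins must be labelled")
  if (anyDuplicated(labels)) stop("duplicate protein labels")
  n <- length(proteins)
  if (n < 3L) stop("need at least 3 proteins (got ", n, ")")
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D <- align_pair(proteins[[i]], proteins[[j]], ...)$mismatch
      d[i, j] <- d[j, i] <- kimura_distance(D, fallback_raw = fallback_raw)
    }
  }
  d
}

#' Kimura-corrected distance matrix from a multiple alignment
#'
#' Pairwise mismatch fractions are computed over columns where neither
#' sequence has a gap, then corrected with [kimura_distance()]. This is the
#' distance backend of [bootstrap_support()].
#'
#' @param aln Named character vector of equal-length gapped sequences, or a
#'   character matrix (rows = taxa).
#' @param fallback_raw Passed to [kimura_distance()]; defaults to `TRUE`
#'   because bootstrap resampling can push D past the correction domain.
#' @return A symmetric numeric matrix.
#' @export
alignment_distance_matrix <- function(aln, fallback_raw = TRUE) {
  m <- .alignment_matrix(aln)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) stop("sequences '", rownames(m)[i], "' and '",
                         rownames(m)[j], "' share no ungapped columns")
      D <- mean(m[i, ok] != m[j, ok])
      d[i, j] <- d[j, i] <- kimura_distance(D, fallback_raw = fallback_raw)
    }
  }
  d
}

# named character vector / list of seq_records / matrix -> character matrix
.alignment_matrix <- function(aln) {
  if (is.matrix(aln)) {
    if (is.null(rownames(aln))) stop("alignment matrix must have row names")
    return(aln)
  }
  if (is.list(aln))
    aln <- vapply(aln, .residues, character(1))
  if (is.null(names(aln)) || any(!nzchar(names(aln))))
    stop("aligned sequences must be named")
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}
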