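#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; ambiguity bases `N` are excluded from both
#' numerator and denominator, so the estimate is unbiased under ambiguity.
#'
#' @param x Nucleotide [seq_record()] or string.
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(x) {
  s <- .residues(x)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  gc <- sum(ch == "G" | ch == "C")
  at <- sum(ch == "A" | ch == "T")
  if (gc + at == 0L) stop("sequence has no unambiguous bases")
  gc / (gc + at)
}

.new_profile <- function(center, value, kind, window, step) {
  structure(data.frame(center = center, value = value),
            kind = kind, window = window, step = step,
            class = c("composition_profile", "data.frame"))
}

#' Sliding-window GC profile
#'
#' One point per complete window (trailing partial windows are discarded);
#' points are indexed by window centers, `start + window/2`, in 0-based
#' coordinates. Windows whose unambiguous-base count is zero yield `NA`.
#'
#' @param record Nucleotide [seq_record()] or string.
#' @param window Window size in bp (contigs are typically profiled at 500 bp,
#'   single genes at 40 bp).
#' @param step Step size in bp.
#' @return A `composition_profile` data frame with columns `center`, `value`;
#'   the number of points is `floor((L - window)/step) + 1`.
#' @export
windowed_gc <- function(record, window, step = 1L) {
  s <- .residues(record)
  L <- nchar(s)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("window and step must be positive")
  if (window > L) stop("window (", window, ") exceeds sequence length (", L, ")")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  cs_gc <- c(0, cumsum(ch == "G" | ch == "C"))
  cs_ok <- c(0, cumsum(ch != "N"))
  starts <- seq(0L, L - window, by = step)      # 0-based window starts
  gc <- cs_gc[starts + window + 1L] - cs_gc[starts + 1L]
  ok <- cs_ok[starts + window + 1L] - cs_ok[starts + 1L]
  value <- ifelse(ok > 0, gc / ok, NA_real_)
  .new_profile(starts + window / 2, value, "nucleotide_gc", window, step)
}

# codon matrix (3 x n_codons) of a CDS, optionally dropping a terminal stop
.codon_matrix <- function(cds, drop_stop = TRUE) {
  codons <- .codons(cds)
  n <- length(codons)
  if (drop_stop && n > 1L && codons[n] %in% .STOP_CODONS)
    codons <- codons[-n]
  matrix(unlist(strsplit(codons, "", fixed = TRUE), use.names = FALSE),
         nrow = 3L)
}

#' Codon-position GC (GC1, GC2, GC3)
#'
#' Fraction of codons whose first/second/third base is G or C, over all
#' codons including the start codon. By default the terminal stop codon is
#' excluded (it is analysed separately by the stop-codon census); set
#' `drop_stop = FALSE` to include it. `N` bases are excluded per position.
#'
#' @param cds Nucleotide [seq_record()] or string, length a multiple of 3.
#' @param drop_stop Exclude a terminal `TAA`/`TAG`/`TGA` codon.
#' @return Named numeric vector `c(gc1, gc2, gc3)`.
#' @export
codon_position_gc <- function(cds, drop_stop = TRUE) {
  m <- .codon_matrix(cds, drop_stop = drop_stop)
  f <- function(b) {
    ok <- b != "N"
    if (!any(ok)) return(NA_real_)
    sum(b[ok] == "G" | b[ok] == "C") / sum(ok)
  }
  c(gc1 = f(m[1, ]), gc2 = f(m[2, ]), gc3 = f(m[3, ]))
}

#' Sliding-window codon-position GC profiles
#'
#' Computes GC1/GC2/GC3 in windows of `window` codons advanced by `step`
#' codons along a coding sequence (defaults follow the FramePlot-style
#' 10-codon window, 1-codon step convention). Window centers are in codon
#' units (0-based codon start + window/2).
#'
#' @inheritParams codon_position_gc
#' @param window Window size in codons.
#' @param step Step size in codons.
#' @return A list of three `composition_profile`s named `gc1`, `gc2`, `gc3`.
#' @export
sliding_codon_gc <- function(cds, window = 10L, step = 1L, drop_stop = TRUE) {
  m <- .codon_matrix(cds, drop_stop = drop_stop)
  n <- ncol(m)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("window and step must be positive")
  if (n < window)
    stop("too few codons (", n, ") for window of ", window, " codons")
  starts <- seq(0L, n - window, by = step)
  centers <- starts + window / 2
  one <- function(row, kind) {
    is_gc <- m[row, ] == "G" | m[row, ] == "C"
    ok <- m[row, ] != "N"
    cs_gc <- c(0, cumsum(is_gc & ok)); cs_ok <- c(0, cumsum(ok))
    gc <- cs_gc[starts + window + 1L] - cs_gc[starts + 1L]
    nn <- cs_ok[starts + window + 1L] - cs_ok[starts + 1L]
    .new_profile(centers, ifelse(nn > 0, gc / nn, NA_real_), kind, window, step)
  }
  list(gc1 = one(1L, "codon_gc1"), gc2 = one(2L, "codon_gc2"),
       gc3 = one(3L, "codon_gc3"))
}

#' Compositional outlier report for a contig's genes
#'
#' Scores every gene's GC3 and mean(GC1, GC2) as standard (z) scores among
#' the contig's genes and flags candidate ameliorated horizontal acquisitions:
#' genes whose third codon position is unusually GC-saturated while the first
#' two positions are unusually GC-poor (`z3 >= z_thresh` and
#' `z12 <= -z_thresh`). This scoring is a package-defined formalisation of
#' the amelioration signature, not a literature statistic.
#'
#' @param cds_list Named list of coding sequences ([seq_record()]s or
#'   strings); names are locus tags. At least 3 genes are required for the
#'   z-scores to be meaningful.
#' @param z_thresh Flagging threshold on the standard scores (default 2).
#' @param drop_stop Passed to [codon_position_gc()].
#' @return Data frame with one row per gene, ordered by locus tag, columns
#'   `locus_tag`, `gc`, `gc1`, `gc2`, `gc3`, `z3`, `z12`, `flag`.
#' @export
outlier_report <- function(cds_list, z_thresh = 2.0, drop_stop = TRUE) {
  if (is.null(names(cds_list)) && length(cds_list) > 0)
    names(cds_list) <- vapply(cds_list, function(x)
      if (inherits(x, "seq_record")) x$id else NA_character_, character(1))
  if (length(cds_list) < 3L)
    stop("outlier report needs at least 3 genes (got ", length(cds_list), ")")
  if (anyNA(names(cds_list))) stop("all genes must be named")
  tags <- sort(names(cds_list))
  pos <- t(vapply(cds_list[tags], codon_position_gc, numeric(3),
                  drop_stop = drop_stop))
  gc <- vapply(cds_list[tags], function(x) {
    s <- .residues(x)
    if (drop_stop) {
      cod <- .codons(s)
      if (length(cod) > 1L && cod[length(cod)] %in% .STOP_CODONS)
        s <- substr(s, 1L, nchar(s) - 3L)
    }
    gc_content(s)
  }, numeric(1))
  zscore <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  z3 <- zscore(pos[, "gc3"])
  z12 <- zscore((pos[, "gc1"] + pos[, "gc2"]) / 2)
  data.frame(locus_tag = tags, gc = unname(gc), gc1 = unname(pos[, "gc1"]),
             gc2 = unname(pos[, "gc2"]), gc3 = unname(pos[, "gc3"]),
             z3 = unname(z3), z12 = unname(z12),
             flag = unname(z3 >= z_thresh & z12 <= -z_thresh),
             stringsAsFactors = FALSE)
}

# IUPAC average residue masses (Da): monomer mass minus one water.
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

#' Molecular weight of a protein
#'
#' Sum of IUPAC average residue masses plus one water, in kilodaltons.
#' Dps-family subunits, for example, run between roughly 16 and 26 kD.
#'
#' @param protein Protein [seq_record()] or string; `X` is not allowed.
#' @return Mass in kD (unrounded; display conventionally uses 1 decimal).
#' @examples
#' round(protein_mw("G") * 1000, 2)  # 75.07 Da
#' @export
protein_mw <- function(protein) {
  s <- .residues(protein)
  if (!nzchar(s)) stop("empty protein")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (any(ch == "X")) stop("protein contains ambiguous residue X")
  m <- .RESIDUE_MASS[ch]
  if (anyNA(m)) stop("unknown residue '", ch[which(is.na(m))[1]], "'")
  (sum(m) + .WATER_MASS) / 1000
}
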