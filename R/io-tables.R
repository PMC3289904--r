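#' Write and read a tree in Newick format
#'
#' Branch lengths are written with six decimals and internal-node bootstrap
#' supports (if present as `node.label`) as integer labels; output
#' round-trips through [read_newick()] with identical topology and branch
#' lengths.
#'
#' @param tree An `ape::phylo` tree; every leaf must be named.
#' @param path Output path.
#' @return `path` invisibly (for the writer); a `phylo` (for the reader).
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label)))
    stop("all leaves must be named")
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path, digits = 7)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ape::read.tree(path)
}

#' Write a table as TSV
#'
#' Tab-separated values with a header row; optional `# key=value` comment
#' lines record the parameters that produced the table (read back by
#' [read_tsv_table()], which skips them).
#'
#' @param table A data frame.
#' @param path Output path.
#' @param comments Optional named character vector written as `# key=value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(table, path, comments = NULL) {
  stopifnot(is.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments) && length(comments) > 0)
    writeLines(paste0("# ", names(comments), "=", unname(comments)), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
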