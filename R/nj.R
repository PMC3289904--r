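#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair minimising
#' `Q(i,j) = (m-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` with the standard
#' branch-length formulas; on additive distance matrices the generating tree
#' is recovered exactly. Exact ties in Q are broken by the lexicographically
#' smallest label pair (internal nodes inherit the smallest descendant
#' label), making the output independent of taxon order. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sibling
#' edge, so total path lengths through the join are preserved.
#'
#' @param d Symmetric numeric matrix with unique row/column labels (or a
#'   `dist`), all entries finite, at least 3 taxa.
#' @return An unrooted `ape::phylo` tree (degree-3 root surrogate).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) stop("'d' must be a numeric matrix")
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix needs unique row/column labels")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa (got ", n, ")")
  if (any(!is.finite(d))) stop("non-finite distances")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")

  ids <- seq_len(n)            # active node ids (tips 1..n, internals > n)
  tie <- labels                # lexicographic tie-break key per active node
  D <- d
  dimnames(D) <- NULL
  next_id <- n + 1L
  parent <- integer(0); child <- integer(0); blen <- numeric(0)
  add_edge <- function(p, c, l) {
    parent <<- c(parent, p); child <<- c(child, c); blen <<- c(blen, l)
  }

  m <- n
  while (m > 3L) {
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      lo <- pmin(tie[cand[, 1]], tie[cand[, 2]])
      hi <- pmax(tie[cand[, 1]], tie[cand[, 2]])
      cand <- cand[order(lo, hi)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    add_edge(u, ids[i], li)
    add_edge(u, ids[j], lj)
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
               c(duk[keep], 0))
    ids <- c(ids[keep], u)
    tie <- c(tie[keep], min(tie[c(i, j)]))
    m <- m - 1L
  }

  # final star join of the three remaining nodes
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  center <- next_id
  add_edge(center, ids[1], max(0, la))
  add_edge(center, ids[2], max(0, lb))
  add_edge(center, ids[3], max(0, lc))

  # assemble an ape phylo: tips keep ids 1..n; internals renumbered with the
  # root surrogate (the star center) as n+1
  internals <- sort(unique(parent))
  map <- integer(max(internals))
  map[center] <- n + 1L
  others <- setdiff(internals, center)
  if (length(others) > 0) map[others] <- n + 1L + seq_along(others)
  renum <- function(v) ifelse(v > n, map[v], v)
  tree <- structure(list(edge = cbind(renum(parent), renum(child)),
                         edge.length = blen, tip.label = labels,
                         Nnode = length(internals)),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the Kimura/NJ tree
#' per replicate, and reports for each internal edge of the full-alignment
#' tree the percentage of replicates containing the same bipartition
#' (the conventional figure legend reads "bootstrap values (%) of N
#' repeats"). Fully reproducible for a fixed seed and invariant under taxon
#' order because column resampling is label-free and NJ tie-breaks are
#' label-keyed.
#'
#' @param aln Multiple protein alignment: named character vector of
#'   equal-length (gapped) sequences, list of protein [seq_record()]s, or a
#'   character matrix. At least 3 sequences and 2 columns.
#' @param n_reps Number of bootstrap replicates (>= 1; classically 1000).
#' @param seed Integer seed (mandatory; no global RNG state is consumed).
#' @param fallback_raw Passed to [alignment_distance_matrix()].
#' @return A list of class `bootstrap_result` with `tree` (the
#'   full-alignment NJ tree, `node.label` holding integer percentage
#'   supports, the root surrogate unlabelled), `support` (integer vector
#'   indexed by internal node number), `n_reps`, `seed`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed,
                              fallback_raw = TRUE) {
  if (missing(seed)) stop("'seed' is required")
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  m <- .alignment_matrix(aln)
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  tree <- nj_tree(alignment_distance_matrix(m, fallback_raw = fallback_raw))
  L <- ncol(m)
  idx <- withr::with_seed(seed,
    matrix(sample.int(L, L * n_reps, replace = TRUE), nrow = n_reps))
  boot <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    boot[[r]] <- nj_tree(alignment_distance_matrix(m[, idx[r, ], drop = FALSE],
                                                   fallback_raw = fallback_raw))
  }
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / n_reps))
  names(support) <- seq_along(support) + length(tree$tip.label)
  labels <- as.character(support)
  labels[1] <- ""                     # root surrogate carries no bipartition
  tree$node.label <- labels
  structure(list(tree = tree, support = support, n_reps = n_reps,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates, seed %s; supports: %s\n",
              x$n_reps, format(x$seed),
              paste(x$support[-1], collapse = " ")))
  invisible(x)
}

#' Root a tree with an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge. Internal
#' node labels (bootstrap supports) are carried as edge-associated labels so
#' they stay attached to the same bipartitions.
#'
#' @param tree An `ape::phylo` (a `bootstrap_result` is also accepted).
#' @param outgroup Leaf label to root with.
#' @return A rooted `ape::phylo` with a degree-2 root.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (inherits(tree, "bootstrap_result")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  if (!(outgroup %in% tree$tip.label))
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  has_labels <- !is.null(tree$node.label)
  r <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                 edgelabel = has_labels)
  root_node <- length(r$tip.label) + 1L
  kids <- which(r$edge[, 1] == root_node)
  if (length(kids) == 2L && !is.null(r$edge.length)) {
    total <- sum(r$edge.length[kids])
    r$edge.length[kids] <- total / 2
  }
  r
}

#' Leaf-to-leaf path-length matrix of a tree
#'
#' Thin wrapper over `ape::cophenetic.phylo`, ordered by the given labels.
#' On an additive input matrix, the NJ tree's path lengths reproduce the
#' input exactly.
#'
#' @param tree An `ape::phylo`.
#' @return Symmetric numeric matrix over the tree's leaves.
#' @export
tree_path_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}
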