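#' Distance-based clustering of aligned sequences (NJ / BIONJ)
#'
#' Builds an unrooted tree from a K2P distance matrix using either the
#' classic Saitou-Nei neighbor-joining reduction or the variance-weighted
#' BIONJ reduction (the agglomeration used for the subfamily clustering
#' analyses).  Branch lengths are in substitutions per site.  Negative
#' branch lengths, which NJ-family methods can produce, are retained and
#' reported via a message rather than clamped.
#'
#' @param d a symmetric distance matrix with labelled rows/columns (e.g.
#'   from [distance_matrix()]), or a `dist` object.
#' @param method `"bionj"` (default) or `"nj"`.
#' @return an `ape::phylo` tree.
#' @export
build_tree <- function(d, method = c("bionj", "nj")) {
  method <- match.arg(method)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix contains NA entries")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tree <- switch(method, nj = ape::nj(d), bionj = ape::bionj(d))
  if (any(tree$edge.length < 0))
    message(sum(tree$edge.length < 0),
            " negative branch length(s) retained in ", method, " tree")
  tree
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the tips into two sets;
#' the split is canonicalised as the sorted side that does not contain the
#' first tip label (alphabetically), so that two trees on the same tips can
#' be compared as sets of strings regardless of rotation or rooting.
#'
#' @param tree an `ape::phylo` object.
#' @return character vector of canonical split strings (tip labels joined
#'   by `"|"`); trivial splits (single tip / all-but-one) are omitted.
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap supports for a distance-clustered tree
#'
#' Alignment columns are resampled with replacement in each replicate, a
#' K2P distance matrix and tree are rebuilt, and the support of each
#' internal bipartition of the point-estimate tree is the percentage of
#' replicate trees containing that bipartition.  Replicates in which any
#' pairwise distance is undefined are dropped and counted.
#'
#' @param msa named character vector (or `DNAStringSet`) of aligned rows.
#' @param method passed to [build_tree()].
#' @param replicates number of bootstrap replicates (0 gives the point tree
#'   with no supports).
#' @param seed optional integer seed for the resampling.
#' @return a list of class `"ty_boot"`: `tree` (point estimate with integer
#'   percentage supports in `node.label`), `consensus` (majority-rule
#'   consensus of the replicate trees, or `NULL` when `replicates = 0`),
#'   `supports` (named by split), `n_used`, `n_dropped`.
#' @export
bootstrap_supports <- function(msa, method = "bionj", replicates = 100,
                               seed = NULL) {
  msa <- as_msa(msa)
  if (!is.null(seed)) set.seed(seed)
  point <- build_tree(distance_matrix(msa), method = method)
  if (replicates == 0) {
    out <- list(tree = point, consensus = NULL, supports = NULL,
                n_used = 0L, n_dropped = 0L)
    class(out) <- "ty_boot"
    return(out)
  }
  len <- nchar(msa[[1]])
  mat <- do.call(rbind, lapply(msa, .as_chars))
  rep_trees <- list()
  dropped <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(len, len, replace = TRUE)
    boot <- apply(mat[, cols, drop = FALSE], 1, .collapse)
    tr <- tryCatch(suppressMessages(
      build_tree(distance_matrix(boot), method = method)),
      error = function(e) NULL)
    if (is.null(tr)) dropped <- dropped + 1L else rep_trees <- c(rep_trees, list(tr))
  }
  n_used <- length(rep_trees)
  if (n_used == 0) stop("all bootstrap replicates had undefined distances")
  rep_split_sets <- lapply(rep_trees, tree_splits)
  supports <- .split_supports(point, rep_split_sets, n_used)
  point <- .label_tree_supports(point, rep_split_sets, n_used)
  class(rep_trees) <- "multiPhylo"
  cons <- ape::consensus(rep_trees, p = 0.5)
  out <- list(tree = point, consensus = cons, supports = supports,
              n_used = n_used, n_dropped = dropped)
  class(out) <- "ty_boot"
  out
}

.split_supports <- function(point, rep_split_sets, n_used) {
  splits <- tree_splits(point)
  vapply(splits, function(s) {
    round(100 * mean(vapply(rep_split_sets, function(rs) s %in% rs,
                            logical(1))))
  }, numeric(1))
}

# attach integer supports as node labels on the (rooted representation of
# the) point tree: each non-root internal node's clade defines a split
.label_tree_supports <- function(tree, rep_split_sets, n_used) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  node_lab <- character(length(parts))
  for (i in seq_along(parts)) {
    side <- labs[parts[[i]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2 || length(side) > length(tips) - 2) {
      node_lab[i] <- ""
      next
    }
    key <- paste(sort(side), collapse = "|")
    node_lab[i] <- as.character(round(100 * mean(vapply(
      rep_split_sets, function(rs) key %in% rs, logical(1)))))
  }
  tree$node.label <- node_lab
  tree
}

#' @export
print.ty_boot <- function(x, ...) {
  cat("Distance-clustered tree with bootstrap supports\n")
  cat("  tips:", length(x$tree$tip.label),
      " replicates used:", x$n_used,
      " dropped:", x$n_dropped, "\n")
  if (!is.null(x$supports)) {
    cat("  supports (%):",
        paste(sprintf("%d", sort(unname(x$supports), decreasing = TRUE)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a tree in newick format
#'
#' Standard newick with branch lengths; integer internal-node labels carry
#' bootstrap supports.  Reading back a written tree yields the same tree up
#' to rotation (compare with [tree_splits()]).
#'
#' @param tree an `ape::phylo` object.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    stop("malformed newick in ", path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick in ", path)
  tree
}
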