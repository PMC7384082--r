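# Tree handling: pruning to the analysis taxa and the species relatedness
# matrix A (shared root-to-tip path lengths, scaled to unit tree height)
# together with its inverse, as consumed by the mixed model.

#' Prune a phylogeny to a set of taxa
#'
#' Returns the induced subtree on `keep`; internal nodes left with a single
#' descendant are suppressed with their branch lengths summed (standard
#' behaviour of `ape::keep.tip`).
#'
#' @param tree An `ape::phylo` tree (or a path to / string of Newick).
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep) {
  tree <- as_phylo(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2L)
    stop("fewer than 2 taxa requested; cannot build a phylogeny")
  ape::keep.tip(tree, keep)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, a Newick string, or a file path")
}

#' Species relatedness matrix from an ultrametric tree
#'
#' `A[i, j]` is the depth of the most recent common ancestor of tips i and j
#' divided by the tree height, so that after scaling an ultrametric tree has
#' unit diagonal and off-diagonals in \[0, 1).  Scaling to unit height makes
#' heritable variance components directly comparable to residual ones when a
#' relative (not absolute) time calibration is all the tree provides.  The
#' inverse is computed densely; if ill-conditioned, a 1e-10 diagonal jitter
#' is applied once (with a message).
#'
#' @param tree A rooted `phylo` with nonnegative branch lengths, >= 2 tips.
#' @param ultrametric_tol Relative tip-depth spread beyond which a
#'   non-ultrametric warning is emitted (scaling still uses the maximum tip
#'   depth).
#' @return An object of class `phylo_cov`: `taxa` (tip labels, fixing the
#'   matrix order), `A`, `A_inv`, `height`.
#' @export
phylo_covariance <- function(tree, ultrametric_tol = 0.01) {
  tree <- as_phylo(tree)
  if (ape::Ntip(tree) < 2L) stop("fewer than 2 taxa; cannot build A")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  height <- max(depths)
  if (height <= 0) stop("tree has zero height")
  if ((max(depths) - min(depths)) / height > ultrametric_tol)
    warning("tree is not ultrametric within tolerance; scaling by maximum tip depth")
  A <- ape::vcv.phylo(tree) / height
  A <- (A + t(A)) / 2
  A_inv <- tryCatch(solve(A), error = function(e) NULL)
  cond_bad <- is.null(A_inv) ||
    max(abs(A %*% A_inv - diag(nrow(A)))) > 1e-6
  if (cond_bad) {
    message("relatedness matrix ill-conditioned; applying 1e-10 diagonal jitter")
    A <- A + diag(1e-10, nrow(A))
    A_inv <- solve(A)
  }
  structure(list(taxa = rownames(A), A = A, A_inv = A_inv, height = height),
            class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat(sprintf("Phylogenetic covariance over %d taxa (unit height)\n",
              length(x$taxa)))
  invisible(x)
}
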