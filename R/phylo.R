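#' Read a rooted bifurcating tree from a Newick string
#'
#' Parses a Newick string into an [ape::phylo] object and validates the
#' structural assumptions the rest of the package relies on: the tree is
#' rooted and strictly bifurcating, every non-root edge carries a branch
#' length, all branch lengths are non-negative, and tip labels are unique.
#' Internal node labels are ignored.
#'
#' @param text A single Newick string (terminating semicolon required).
#' @return A `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick string: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree))
    stop("malformed Newick string: parser returned no tree", call. = FALSE)
  tree$node.label <- NULL
  validate_tree(tree)
}

#' Serialise a tree to Newick
#'
#' Branch lengths are written with 15 significant digits so that a
#' write/read round trip preserves edge lengths to within 1e-12.
#'
#' @param tree A `phylo` object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  ape::write.tree(tree, digits = 15)
}

## Shared structural checks; all package entry points funnel trees through
## this so downstream code can assume a rooted, bifurcating, labelled tree.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("expected a 'phylo' tree object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("all branch lengths must be present and >= 0", call. = FALSE)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  n <- length(tree$tip.label)
  if (n >= 2L && !ape::is.binary(tree))
    stop("tree must be strictly bifurcating", call. = FALSE)
  if (n >= 2L && !ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  tree
}

#' Tree height
#'
#' Maximum root-to-tip distance.
#'
#' @param tree A `phylo` object.
#' @return Numeric scalar.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' Rescale a tree to unit height
#'
#' Multiplies every branch length by the reciprocal of the tree height so
#' the deepest tip sits at distance 1 from the root. Topology is untouched.
#'
#' @param tree A `phylo` object with height > 0.
#' @return The rescaled `phylo` object.
#' @export
rescale_to_unit_height <- function(tree) {
  validate_tree(tree)
  h <- tree_height(tree)
  if (h <= 0) stop("cannot rescale a zero-height tree", call. = FALSE)
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Node depths (distance from the root)
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector over all nodes in ape numbering (tips
#'   first, then internal nodes); tips carry their labels as names.
#' @export
node_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  names(d) <- c(tree$tip.label,
                rep("", tree$Nnode))
  d
}

## TRUE when all tip depths agree within tol; warn (not error) otherwise
## so user-supplied non-ultrametric trees still pass through the fitters,
## whose covariance formulas remain valid.
check_ultrametric <- function(tree, tol = 1e-9, warn = TRUE) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  ok <- diff(range(d)) <= tol
  if (!ok && warn)
    warning("tree is not ultrametric within tolerance ", tol, call. = FALSE)
  ok
}

#' Matrix of MRCA depths between tips
#'
#' Entry (i, j) is the depth (distance from the root) of the most recent
#' common ancestor of tips i and j; the diagonal holds tip depths. This is
#' the shared-time matrix underlying the Brownian-motion covariance. Rows
#' and columns follow sorted tip-label order for reproducibility.
#'
#' @param tree A `phylo` object.
#' @param tips Optional character vector selecting/ordering tips; defaults
#'   to all tips in sorted label order.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
mrca_depths <- function(tree, tips = NULL) {
  validate_tree(tree)
  if (is.null(tips)) tips <- sort(tree$tip.label)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("unknown tip label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  V <- ape::vcv(tree)
  V[tips, tips, drop = FALSE]
}

#' Drop tips from a tree
#'
#' Removes the given tips; internal nodes left with a single child are
#' suppressed with their incident edge lengths summed, so every retained
#' tip keeps its root-to-tip depth.
#'
#' @param tree A `phylo` object.
#' @param drop Character vector of tip labels to remove (may be empty).
#' @return The pruned `phylo` object.
#' @export
prune_tips <- function(tree, drop) {
  validate_tree(tree)
  drop <- as.character(drop)
  if (length(drop) == 0L) return(tree)
  missing <- setdiff(drop, tree$tip.label)
  if (length(missing))
    stop("unknown tip label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- setdiff(tree$tip.label, drop)
  if (length(keep) < 2L)
    stop("pruning must leave at least 2 tips", call. = FALSE)
  ape::drop.tip(tree, drop)
}
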