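#' Specification of a trait-evolution model
#'
#' Bundles a generating model name with its parameters. The defaults are
#' the study conditions used throughout the package's experiments: rate
#' \eqn{\sigma^2_0 = 0.5} in the root regime (shifting to
#' \eqn{\sigma^2_1 = 1} in the derived regime under BMS), optimum
#' \eqn{\theta_0 = 10} (shifting to \eqn{\theta_1 = 11} under OUM) and
#' attraction strength \eqn{\alpha = 1.5}, i.e. a phylogenetic half-life
#' of \eqn{\ln 2 / 1.5 \approx 0.46} on a unit-height tree — an OU process
#' of moderate strength. The root value is the root optimum for OU/OUM and
#' 10 for BM/BMS (any constant shift is invisible to BM inference; using
#' the \eqn{\theta_0} scale keeps trait ranges comparable across models).
#'
#' @param model One of `"BM"`, `"BMS"`, `"OU"`, `"OUM"`.
#' @param sigma2_0 Brownian rate in the root regime (trait variance per
#'   unit time), > 0.
#' @param sigma2_1 Rate in the derived regime (BMS only), > 0.
#' @param theta_0 Optimum in the root regime (trait units; OU/OUM).
#' @param theta_1 Optimum in the derived regime (OUM only).
#' @param alpha Attraction strength towards the optimum, per unit time
#'   (OU/OUM only), > 0.
#' @param root_value Trait value at the root; defaults to `theta_0` for
#'   OU/OUM and 10 for BM/BMS.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(model = c("BM", "BMS", "OU", "OUM"),
                       sigma2_0 = 0.5, sigma2_1 = 1,
                       theta_0 = 10, theta_1 = 11,
                       alpha = 1.5, root_value = NULL) {
  model <- match.arg(model)
  stopifnot(sigma2_0 > 0, sigma2_1 > 0)
  if (model %in% c("OU", "OUM")) stopifnot(alpha > 0)
  if (is.null(root_value))
    root_value <- if (model %in% c("OU", "OUM")) theta_0 else 10
  structure(
    list(model = model, sigma2_0 = sigma2_0, sigma2_1 = sigma2_1,
         theta_0 = theta_0, theta_1 = theta_1, alpha = alpha,
         root_value = root_value),
    class = "model_spec")
}

#' Initial tree size for a target retained-tip count
#'
#' Trees are sized before pruning so that the tip count after dropping
#' missing taxa is constant (300 by default), isolating the effect of
#' missing taxa from the effect of tree size: `round(n_target / (1 - p))`,
#' e.g. 333 tips at 10% missing, 600 at 50%, 3000 at 90%.
#'
#' @param p_missing Expected fraction of missing taxa, in `[0, 1)`.
#' @param n_target Number of tips to retain after pruning.
#' @return Integer tip count.
#' @export
initial_tree_size <- function(p_missing, n_target = 300L) {
  stopifnot(p_missing >= 0, n_target >= 2)
  if (p_missing >= 1) stop("p_missing must be < 1", call. = FALSE)
  as.integer(round(n_target / (1 - p_missing)))
}

#' Simulate a pure-birth tree rescaled to unit height
#'
#' Draws a Yule (pure-birth, rate 1) tree conditioned on `n_tips` extant
#' tips and rescales it to unit height. Only the topology and relative
#' node times matter downstream, so the birth rate is immaterial.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @return An ultrametric `phylo` object of height 1.
#' @export
simulate_yule_tree <- function(n_tips, seed = NULL) {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  rescale_to_unit_height(tree)
}

## Edge indices in preorder (every parent appears before its children):
## reversed postorder of the edge matrix.
preorder_edges <- function(tree) {
  po <- stats::reorder(tree, "postorder")
  idx <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  rev(idx)
}

#' Simulate a binary regime character under the equal-rates Mk model
#'
#' The root state is drawn uniformly from \{0, 1\} (the stationary
#' distribution of the equal-rates chain) and each child node's state is
#' sampled from the two-state transition probability
#' \eqn{P(\mathrm{change}) = (1 - e^{-2qt})/2} over its branch of length
#' t. Each edge carries the state of its parent (rootward) node — the
#' regime is constant along an edge and within-edge transitions are not
#' tracked; the same convention is used by the trait simulator and the
#' multi-regime fitters so the two sides agree exactly.
#'
#' @param tree A `phylo` object.
#' @param q Transition rate (>= 0); the study default is 0.5.
#' @param seed Optional integer seed.
#' @return A `regime_painting`: list with `node_state` (integer 0/1 per
#'   node in ape numbering, tips first) and `edge_state` (0/1 per edge,
#'   the parent node's state).
#' @export
simulate_mk_regimes <- function(tree, q = 0.5, seed = NULL) {
  stopifnot(q >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_node <- length(tree$tip.label) + tree$Nnode
  state <- integer(n_node)
  root <- length(tree$tip.label) + 1L
  state[root] <- sample(0:1, 1L)
  idx <- preorder_edges(tree)
  p_change <- (1 - exp(-2 * q * tree$edge.length)) / 2
  flips <- stats::runif(nrow(tree$edge)) < p_change
  for (e in idx) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    state[child] <- if (flips[e]) 1L - state[parent] else state[parent]
  }
  regime_painting(tree, state)
}

#' Construct a regime painting from node states
#'
#' @param tree A `phylo` object.
#' @param node_state Integer vector of 0/1 states, one per node in ape
#'   numbering (tips first, then internal nodes).
#' @return A list of class `regime_painting`.
#' @export
regime_painting <- function(tree, node_state) {
  n_node <- length(tree$tip.label) + tree$Nnode
  node_state <- as.integer(node_state)
  stopifnot(length(node_state) == n_node, all(node_state %in% 0:1))
  structure(
    list(node_state = node_state,
         edge_state = node_state[tree$edge[, 1]],
         root_state = node_state[length(tree$tip.label) + 1L]),
    class = "regime_painting")
}

#' Check the regime-balance constraint
#'
#' The experiments require the minority regime to cover between 25% and
#' 45% (inclusive) of the tips retained after pruning; replicates failing
#' this are redrawn.
#'
#' @param painting A `regime_painting`.
#' @param tree The tree the painting was simulated on.
#' @param retained_tips Character vector of retained tip labels.
#' @return Logical scalar.
#' @export
regime_balance_ok <- function(painting, tree, retained_tips) {
  stopifnot(length(retained_tips) > 0)
  idx <- match(retained_tips, tree$tip.label)
  if (anyNA(idx)) stop("retained tips not in tree", call. = FALSE)
  states <- painting$node_state[idx]
  share1 <- mean(states == 1L)
  minority <- min(share1, 1 - share1)
  minority >= 0.25 && minority <= 0.45
}

## Exact Gaussian transition along one edge. BM/BMS: mean parent, variance
## sigma2*t. OU/OUM: mean theta + (parent-theta)*exp(-alpha*t), variance
## sigma2/(2*alpha)*(1-exp(-2*alpha*t)).
edge_transition <- function(parent_value, t, sigma2, theta, alpha, z) {
  if (is.null(alpha)) {
    parent_value + z * sqrt(sigma2 * t)
  } else {
    m <- theta + (parent_value - theta) * exp(-alpha * t)
    v <- sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * t))
    m + z * sqrt(v)
  }
}

#' Simulate a continuous trait under BM, BMS, OU or OUM
#'
#' Pre-order recursion from the root value using the exact Gaussian
#' transition of each process over each edge; the edge's regime (its
#' parent node's state) selects \eqn{\sigma^2} (BMS) or \eqn{\theta}
#' (OUM).
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting` covering the tree (ignored for BM
#'   and OU; may be `NULL` for those models).
#' @param spec A [model_spec()].
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_trait <- function(tree, painting, spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  needs_regimes <- spec$model %in% c("BMS", "OUM")
  if (needs_regimes && is.null(painting))
    stop(spec$model, " requires a regime painting", call. = FALSE)
  n_tip <- length(tree$tip.label)
  value <- numeric(n_tip + tree$Nnode)
  value[n_tip + 1L] <- spec$root_value
  idx <- preorder_edges(tree)
  z <- stats::rnorm(nrow(tree$edge))
  ou <- spec$model %in% c("OU", "OUM")
  for (e in idx) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    r <- if (needs_regimes) painting$edge_state[e] else 0L
    sigma2 <- if (spec$model == "BMS" && r == 1L) spec$sigma2_1 else spec$sigma2_0
    theta <- if (spec$model == "OUM" && r == 1L) spec$theta_1 else spec$theta_0
    value[child] <- edge_transition(value[parent], tree$edge.length[e],
                                    sigma2, theta,
                                    if (ou) spec$alpha else NULL, z[e])
  }
  stats::setNames(value[seq_len(n_tip)], tree$tip.label)
}

#' Write / read a regime painting as TSV
#'
#' Three-column tab-separated file `(node_id, node_type, state)` with
#' nodes in ape numbering (tips first, labelled by tip label; internal
#' nodes by number).
#'
#' @param painting A `regime_painting`.
#' @param tree The tree the painting belongs to.
#' @param path File path.
#' @return `read_regimes_tsv` returns a `regime_painting`;
#'   `write_regimes_tsv` returns `path` invisibly.
#' @export
write_regimes_tsv <- function(painting, tree, path) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  utils::write.table(
    data.frame(node_id = seq_len(n_node),
               node_type = rep(c("tip", "internal"),
                               c(n_tip, tree$Nnode)),
               state = painting$node_state),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regimes_tsv
#' @export
read_regimes_tsv <- function(path, tree) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  regime_painting(tree, d$state[order(d$node_id)])
}

#' Simulate a Brownian liability
#'
#' A latent continuous trait evolving by Brownian motion from 0 with rate
#' `sigma2`; thresholding it yields a binary character with phylogenetic
#' signal (the threshold model), used to build phylogenetically clumped
#' missingness.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Brownian rate (> 0), default 1.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip liabilities.
#' @export
simulate_liability <- function(tree, sigma2 = 1, seed = NULL) {
  spec <- model_spec("BM", sigma2_0 = sigma2, root_value = 0)
  simulate_trait(tree, NULL, spec, seed = seed)
}
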