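# Small fixture trees and an independent multivariate-normal oracle for
# the model likelihoods, built entrywise from first principles (parent
# pointers and closed-form kernels, dense solve/determinant) without the
# package's covariance or weight-matrix code paths.

tree_3tip <- function() read_newick("((A:0.5,B:0.5):0.5,C:1);")
tree_4tip <- function() read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")

# parent pointer and root-to-node path (sequence of edge indices)
oracle_parents <- function(tree) {
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  edge_of <- integer(length(parent))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  list(parent = parent, edge_of = edge_of,
       root = length(tree$tip.label) + 1L)
}

oracle_path_edges <- function(tree, node) {
  pp <- oracle_parents(tree)
  path <- integer(0)
  while (node != pp$root) {
    path <- c(pp$edge_of[node], path)
    node <- pp$parent[node]
  }
  path  # rootward-first
}

# model covariance, entry by entry
oracle_cov <- function(tree, spec, painting = NULL) {
  tips <- sort(tree$tip.label)
  ti <- match(tips, tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree)
  n <- length(ti)
  V <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- if (i == j) ti[i] else M[ti[i], ti[j]]
    ta <- depth[a]
    V[i, j] <- switch(spec$model,
      BM = spec$sigma2_0 * ta,
      BMS = {
        acc <- 0
        for (e in oracle_path_edges(tree, a)) {
          s2 <- if (painting$edge_state[e] == 1L) spec$sigma2_1
                else spec$sigma2_0
          acc <- acc + s2 * tree$edge.length[e]
        }
        acc
      },
      OU = ,
      OUM = spec$sigma2_0 / (2 * spec$alpha) *
        exp(-spec$alpha * (depth[ti[i]] + depth[ti[j]] - 2 * ta)) *
        (1 - exp(-2 * spec$alpha * ta)))
  }
  V
}

# model mean, tip by tip (root value known; OU/OUM integrate the optimum
# along the root-to-tip path, regime of an edge = its parent node state)
oracle_mean <- function(tree, spec, painting = NULL) {
  tips <- sort(tree$tip.label)
  ti <- match(tips, tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  mu <- numeric(length(ti))
  for (k in seq_along(ti)) {
    if (spec$model %in% c("BM", "BMS")) {
      mu[k] <- spec$root_value
    } else {
      d <- depth[ti[k]]
      m <- spec$root_value * exp(-spec$alpha * d)
      for (e in oracle_path_edges(tree, ti[k])) {
        th <- if (spec$model == "OUM" && painting$edge_state[e] == 1L)
          spec$theta_1 else spec$theta_0
        t0 <- depth[tree$edge[e, 1]]
        t1 <- depth[tree$edge[e, 2]]
        m <- m + th * (exp(-spec$alpha * (d - t1)) -
                         exp(-spec$alpha * (d - t0)))
      }
      mu[k] <- m
    }
  }
  stats::setNames(mu, tips)
}

oracle_loglik <- function(tree, trait, spec, painting = NULL) {
  tips <- sort(tree$tip.label)
  x <- as.numeric(trait[tips])
  V <- oracle_cov(tree, spec, painting)
  mu <- as.numeric(oracle_mean(tree, spec, painting))
  r <- x - mu
  as.numeric(-0.5 * (length(x) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V, r)))
}
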