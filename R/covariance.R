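#' Brownian-motion covariance structure of a tree
#'
#' Unit-rate BM covariance: `C[i, j]` is the depth of the MRCA of tips i
#' and j (their shared path length from the root); the model covariance
#' is `sigma2 * C`. Rows/columns in sorted tip-label order.
#'
#' @param tree A `phylo` object with >= 2 tips.
#' @return Symmetric positive semidefinite matrix.
#' @export
bm_covariance <- function(tree) {
  mrca_depths(tree)
}

## Per-regime cumulative depth of every node (preorder accumulation) and
## the per-regime shared-path matrices used by the BMS covariance.
regime_path_lengths <- function(tree, painting) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  len0 <- numeric(n_node)
  len1 <- numeric(n_node)
  idx <- preorder_edges(tree)
  for (e in idx) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    r <- painting$edge_state[e]
    len0[ch] <- len0[p] + if (r == 0L) tree$edge.length[e] else 0
    len1[ch] <- len1[p] + if (r == 1L) tree$edge.length[e] else 0
  }
  tips <- sort(tree$tip.label)
  ti <- match(tips, tree$tip.label)
  M <- ape::mrca(tree)[ti, ti, drop = FALSE]  # MRCA node numbers
  diag(M) <- ti
  C0 <- matrix(len0[M], length(ti), dimnames = list(tips, tips))
  C1 <- matrix(len1[M], length(ti), dimnames = list(tips, tips))
  list(C0 = C0, C1 = C1)
}

#' Multi-rate Brownian covariance
#'
#' `V[i, j]` accumulates, regime by regime, the length of the
#' root-to-MRCA(i, j) path lying in each regime, scaled by that regime's
#' rate; the diagonal uses the full root-to-tip path.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting` covering the tree's edges.
#' @param sigma2_0,sigma2_1 Rates in the root (0) and derived (1) regime.
#' @return Symmetric covariance matrix in sorted tip-label order.
#' @export
bms_covariance <- function(tree, painting, sigma2_0, sigma2_1) {
  cp <- regime_path_lengths(tree, painting)
  sigma2_0 * cp$C0 + sigma2_1 * cp$C1
}

#' Fixed-root Ornstein-Uhlenbeck covariance
#'
#' Unit-rate (sigma2 = 1) covariance of an OU process started at a known
#' root value:
#' `V0[i, j] = exp(-alpha * (d_i + d_j - 2 t_a)) * (1 - exp(-2 alpha t_a)) / (2 alpha)`
#' with `d` the tip depths and `t_a` the MRCA depth; the model covariance
#' is `sigma2 * V0`. As `alpha -> 0` this tends to the BM covariance.
#'
#' @param tree A `phylo` object.
#' @param alpha Attraction strength (> 0).
#' @return Symmetric covariance matrix in sorted tip-label order.
#' @export
ou_covariance <- function(tree, alpha) {
  stopifnot(alpha > 0)
  Ta <- mrca_depths(tree)
  ou_covariance_from_depths(Ta, alpha)
}

ou_covariance_from_depths <- function(Ta, alpha) {
  d <- diag(Ta)
  D1 <- outer(d, d, `+`) - 2 * Ta
  exp(-alpha * D1) * (1 - exp(-2 * alpha * Ta)) / (2 * alpha)
}

## Root-to-tip path decomposition into regime segments: one row per edge
## per tip path, with start/end depths and the edge regime. Computed once
## per (tree, painting); the weight matrix is then a cheap function of
## alpha.
path_segments <- function(tree, painting) {
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- integer(n_tip + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  tips <- sort(tree$tip.label)
  ti <- match(tips, tree$tip.label)
  root <- n_tip + 1L
  rows <- vector("list", length(ti))
  for (k in seq_along(ti)) {
    node <- ti[k]
    segs <- list()
    while (node != root) {
      e <- edge_of[node]
      segs[[length(segs) + 1L]] <-
        c(k, depth[parent[node]], depth[node], painting$edge_state[e])
      node <- parent[node]
    }
    rows[[k]] <- do.call(rbind, segs)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("tip", "t_start", "t_end", "regime")
  list(segments = out, tip_depth = depth[ti], tips = tips,
       root_state = painting$root_state)
}

#' Hansen weight matrix for a multi-optimum OU model
#'
#' Row i gives the weights of the regime optima `(theta_0, theta_1)` in
#' the expected tip value: each regime segment `[t_start, t_end]` of the
#' root-to-tip path contributes
#' `exp(-alpha (d_i - t_end)) - exp(-alpha (d_i - t_start))` to its
#' regime's column, and the root term `exp(-alpha d_i)` goes to the root
#' regime's column (the root value is pinned to the root regime's
#' optimum). Every row sums to 1. Columns identically zero (a regime
#' absent from the painting) are dropped, so a single-regime painting
#' collapses to the single-optimum OU design (a column of ones).
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_painting`.
#' @param alpha Attraction strength (> 0).
#' @return Matrix (tips in sorted label order) x (optima), with columns
#'   named `theta_0`, `theta_1`.
#' @export
ou_weight_matrix <- function(tree, painting, alpha) {
  stopifnot(alpha > 0)
  ps <- path_segments(tree, painting)
  W <- weight_matrix_from_segments(ps, alpha)
  W[, colSums(abs(W)) > 0, drop = FALSE]
}

weight_matrix_from_segments <- function(ps, alpha) {
  seg <- ps$segments
  d <- ps$tip_depth[seg[, "tip"]]
  contrib <- exp(-alpha * (d - seg[, "t_end"])) -
             exp(-alpha * (d - seg[, "t_start"]))
  W <- matrix(0, length(ps$tips), 2,
              dimnames = list(ps$tips, c("theta_0", "theta_1")))
  for (r in 0:1) {
    sel <- seg[, "regime"] == r
    if (any(sel)) {
      acc <- rowsum(contrib[sel], seg[sel, "tip"])
      ti <- as.integer(rownames(acc))
      W[ti, r + 1L] <- W[ti, r + 1L] + acc[, 1]
    }
  }
  W[, ps$root_state + 1L] <- W[, ps$root_state + 1L] +
    exp(-alpha * ps$tip_depth)
  W
}

## Cholesky with a diagonal ridge fallback for near-singular covariances
## (large alpha drives off-diagonal OU entries to zero faster than the
## diagonal, but extreme alpha can still lose positive definiteness in
## floating point).
safe_chol <- function(V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    ridge <- 1e-10 * mean(diag(V))
    R <- tryCatch(chol(V + diag(ridge, nrow(V))), error = function(e) NULL)
    if (is.null(R))
      stop("covariance matrix is not positive definite", call. = FALSE)
    attr(R, "ridged") <- TRUE
  }
  R
}

#' Profiled generalised-least-squares Gaussian likelihood
#'
#' For data `x ~ Normal(W beta, sigma2 * V0)` with `V0` known up to the
#' scale `sigma2`, computes the GLS coefficients
#' `beta = (W' V0^-1 W)^-1 W' V0^-1 x`, the profiled ML variance
#' `sigma2_hat = r' V0^-1 r / n` (residual `r = x - W beta`), and the
#' maximised log-likelihood
#' `-(n/2) (log 2 pi + log sigma2_hat + 1) - log det(V0) / 2`.
#' All four trait models reduce to this after 0- or 1-dimensional
#' profiling of their shape parameter.
#'
#' @param x Numeric response vector.
#' @param V0 Positive definite matrix (unit-rate covariance).
#' @param W Design matrix of full column rank.
#' @return List with `coefficients`, `sigma2_hat`, `logLik`, `residuals`.
#' @export
gls_profile <- function(x, V0, W) {
  n <- length(x)
  W <- as.matrix(W)
  stopifnot(nrow(V0) == n, nrow(W) == n)
  R <- safe_chol(V0)
  # whiten: V0 = R'R, so solving t(R) z = y gives z = R'^-1 y
  xs <- forwardsolve(t(R), x)
  Ws <- forwardsolve(t(R), W)
  qrW <- qr(Ws)
  if (qrW$rank < ncol(W))
    stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qrW, xs)
  res_w <- xs - Ws %*% beta
  sigma2_hat <- sum(res_w^2) / n
  logdet <- 2 * sum(log(diag(R)))
  logLik <- -(n / 2) * (log(2 * pi) + log(sigma2_hat) + 1) - logdet / 2
  list(coefficients = stats::setNames(as.numeric(beta), colnames(W)),
       sigma2_hat = sigma2_hat, logLik = as.numeric(logLik),
       residuals = as.numeric(x - W %*% beta))
}
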