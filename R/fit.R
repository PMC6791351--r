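## Bounds for the 1-D profiled shape parameters (log scale). alpha is the
## OU attraction strength per unit tree height; rho the BMS rate ratio
## sigma2_1 / sigma2_0.
.alpha_bounds <- c(1e-6, 1e3)
.rho_bounds <- c(1e-4, 1e4)

## Coarse log-grid scan followed by stats::optimize in the bracketing
## interval. f takes the parameter on the natural scale and returns the
## profiled log-likelihood (to be maximised).
profile_1d <- function(f, bounds, n_grid = 12L, tol = 1e-5) {
  lg <- seq(log(bounds[1]), log(bounds[2]), length.out = n_grid)
  vals <- vapply(lg, function(u) f(exp(u)), numeric(1))
  i <- which.max(vals)
  lo <- lg[max(1L, i - 1L)]
  hi <- lg[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(u) f(exp(u)), c(lo, hi),
                         maximum = TRUE, tol = tol)
  # keep the grid point if refinement did not improve on it
  if (opt$objective >= vals[i]) {
    par <- exp(opt$maximum); val <- opt$objective
  } else {
    par <- exp(lg[i]); val <- vals[i]
  }
  list(par = par, value = val,
       boundary = par <= bounds[1] * 1.01 || par >= bounds[2] * 0.99)
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Fits one of four Gaussian models of continuous trait evolution to tip
#' data on a phylogeny:
#' \describe{
#'   \item{BM}{single-rate Brownian motion; parameters `sigma2_0` and the
#'     root mean `z_0` (k = 2).}
#'   \item{BMS}{Brownian motion with a regime-dependent rate
#'     (`sigma2_0`, `sigma2_1`, `z_0`; k = 3).}
#'   \item{OU}{single-optimum Ornstein-Uhlenbeck with the root pinned to
#'     the optimum (`sigma2_0`, `theta_0`, `alpha`; k = 3).}
#'   \item{OUM}{OU with a regime-dependent optimum via the Hansen weight
#'     matrix (`sigma2_0`, `theta_0`, `theta_1`, `alpha`; k = 4).}
#' }
#' All models are multivariate normal, so fitting reduces to profiled GLS
#' ([gls_profile()]): BM is closed form; BMS profiles the rate ratio and
#' OU/OUM the attraction strength `alpha` on a log scale (coarse grid
#' scan then golden-section refinement). AICc is attached using the
#' model's free-parameter count.
#'
#' @param tree A `phylo` object (>= 5 tips).
#' @param trait Named numeric vector of tip values.
#' @param model One of `"BM"`, `"BMS"`, `"OU"`, `"OUM"`.
#' @param painting A `regime_painting` (required for BMS/OUM, with both
#'   regimes present among edges).
#' @return An object of class `trait_fit`; see [print.trait_fit()].
#' @seealso [fit_all_models()], [select_best()], [aicc()]
#' @export
fit_trait_model <- function(tree, trait, model = c("BM", "BMS", "OU", "OUM"),
                            painting = NULL) {
  model <- match.arg(model)
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n < 5) stop("need at least 5 tips to fit", call. = FALSE)
  tips <- sort(tree$tip.label)
  x <- as.numeric(trait[tips])
  if (anyNA(x)) stop("trait must cover all tips", call. = FALSE)
  if (model %in% c("BMS", "OUM")) {
    if (is.null(painting))
      stop(model, " requires a regime painting", call. = FALSE)
    if (length(unique(painting$edge_state)) < 2L)
      stop(model, " requires both regimes among edges", call. = FALSE)
  }
  check_ultrametric(tree, warn = TRUE)
  ones <- matrix(1, n, 1, dimnames = list(NULL, "z_0"))
  converged <- TRUE
  boundary <- FALSE
  if (stats::var(x) == 0) {
    # zero-variance input: sigma2_hat collapses to 0, logL diverges
    res <- list(model = model, estimates = NULL, logLik = NA_real_,
                k = NA_integer_, n = n, aicc = NA_real_,
                converged = FALSE, boundary = TRUE,
                tree = tree, trait = stats::setNames(x, tips),
                painting = painting)
    class(res) <- "trait_fit"
    return(res)
  }

  if (model == "BM") {
    Ta <- mrca_depths(tree)
    g <- gls_profile(x, Ta, ones)
    est <- c(sigma2_0 = g$sigma2_hat, z_0 = unname(g$coefficients))
    ll <- g$logLik; k <- 2L
  } else if (model == "BMS") {
    cp <- regime_path_lengths(tree, painting)
    f <- function(rho) gls_profile(x, cp$C0 + rho * cp$C1, ones)$logLik
    opt <- profile_1d(f, .rho_bounds)
    boundary <- opt$boundary
    g <- gls_profile(x, cp$C0 + opt$par * cp$C1, ones)
    est <- c(sigma2_0 = g$sigma2_hat, sigma2_1 = opt$par * g$sigma2_hat,
             z_0 = unname(g$coefficients))
    ll <- g$logLik; k <- 3L
  } else if (model == "OU") {
    Ta <- mrca_depths(tree)
    f <- function(a) gls_profile(x, ou_covariance_from_depths(Ta, a),
                                 ones)$logLik
    opt <- profile_1d(f, .alpha_bounds)
    boundary <- opt$boundary
    g <- gls_profile(x, ou_covariance_from_depths(Ta, opt$par), ones)
    est <- c(sigma2_0 = g$sigma2_hat, theta_0 = unname(g$coefficients),
             alpha = opt$par)
    ll <- g$logLik; k <- 3L
  } else { # OUM
    Ta <- mrca_depths(tree)
    ps <- path_segments(tree, painting)
    f <- function(a) {
      W <- weight_matrix_from_segments(ps, a)
      gls_profile(x, ou_covariance_from_depths(Ta, a), W)$logLik
    }
    opt <- profile_1d(f, .alpha_bounds)
    boundary <- opt$boundary
    W <- weight_matrix_from_segments(ps, opt$par)
    g <- gls_profile(x, ou_covariance_from_depths(Ta, opt$par), W)
    est <- c(sigma2_0 = g$sigma2_hat,
             theta_0 = unname(g$coefficients["theta_0"]),
             theta_1 = unname(g$coefficients["theta_1"]),
             alpha = opt$par)
    ll <- g$logLik; k <- 4L
  }
  res <- list(model = model, estimates = est, logLik = ll, k = k, n = n,
              aicc = aicc(ll, k, n), converged = converged,
              boundary = boundary, tree = tree,
              trait = stats::setNames(x, tips), painting = painting)
  class(res) <- "trait_fit"
  res
}

#' Log-likelihood of a trait model at fixed parameter values
#'
#' Evaluates the exact multivariate-normal log-density of the tip data
#' under the given model and parameters (no estimation): the mean vector
#' comes from the root value and, for OU/OUM, the Hansen weight
#' structure; the covariance from the model's kernel. Useful for
#' likelihood checks and for comparing the maximised likelihood against
#' the generating parameters.
#'
#' @param tree A `phylo` object.
#' @param trait Named numeric vector of tip values.
#' @param spec A [model_spec()] holding the parameter values.
#' @param painting A `regime_painting` (required for BMS/OUM).
#' @return Log-likelihood (nats).
#' @export
trait_model_loglik <- function(tree, trait, spec, painting = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  tips <- sort(tree$tip.label)
  x <- as.numeric(trait[tips])
  if (anyNA(x)) stop("trait must cover all tips", call. = FALSE)
  n <- length(x)
  if (spec$model %in% c("BMS", "OUM") && is.null(painting))
    stop(spec$model, " requires a regime painting", call. = FALSE)
  V <- switch(spec$model,
    BM = spec$sigma2_0 * mrca_depths(tree),
    BMS = bms_covariance(tree, painting, spec$sigma2_0, spec$sigma2_1),
    OU = spec$sigma2_0 * ou_covariance(tree, spec$alpha),
    OUM = spec$sigma2_0 * ou_covariance(tree, spec$alpha))
  d <- diag(mrca_depths(tree))
  mu <- switch(spec$model,
    BM = rep(spec$root_value, n),
    BMS = rep(spec$root_value, n),
    OU = spec$theta_0 + (spec$root_value - spec$theta_0) *
      exp(-spec$alpha * d),
    OUM = {
      W <- weight_matrix_from_segments(path_segments(tree, painting),
                                       spec$alpha)
      theta_root <- if (painting$root_state == 1L) spec$theta_1
                    else spec$theta_0
      as.numeric(W %*% c(spec$theta_0, spec$theta_1)) +
        (spec$root_value - theta_root) * exp(-spec$alpha * d)
    })
  R <- safe_chol(V)
  z <- forwardsolve(t(R), x - mu)
  as.numeric(-0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2)))
}

#' Sample-size-corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param logL Maximised log-likelihood (nats).
#' @param k Number of free parameters.
#' @param n Sample size (must exceed `k + 1`).
#' @return Numeric scalar.
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1", call. = FALSE)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit all four trait models and rank them by AICc
#'
#' @inheritParams fit_trait_model
#' @param models Character vector of models to fit.
#' @return List with `fits` (named list of `trait_fit`), `best` (model
#'   name) and `delta` (named AICc differences to the best model).
#' @export
fit_all_models <- function(tree, trait, painting,
                           models = c("BM", "BMS", "OU", "OUM")) {
  fits <- lapply(models, function(m)
    fit_trait_model(tree, trait, m, painting = painting))
  names(fits) <- models
  sel <- select_best(fits)
  c(list(fits = fits), sel)
}

#' Select the best model by AICc
#'
#' The best model has the lowest AICc; exact ties break towards fewer
#' parameters, then the fixed order BM, BMS, OU, OUM.
#'
#' @param fits Named list of `trait_fit` objects (>= 2).
#' @return List with `best` (model name) and `delta` (named numeric AICc
#'   differences, 0 for the best model).
#' @export
select_best <- function(fits) {
  stopifnot(length(fits) >= 2)
  order_pref <- c("BM", "BMS", "OU", "OUM")
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  k <- vapply(fits, function(f) as.numeric(f$k), numeric(1))
  delta <- a - min(a, na.rm = TRUE)
  cand <- names(fits)[!is.na(a) & a == min(a, na.rm = TRUE)]
  cand <- cand[k[cand] == min(k[cand])]
  best <- cand[order(match(cand, order_pref))][1]
  list(best = best, delta = delta)
}

#' Likelihood-ratio test of BM against single-optimum OU
#'
#' BM is the boundary case alpha -> 0 of OU, so the two fits are nested
#' with one extra parameter. The statistic `2 (logL_OU - logL_BM)` is
#' referred to the chi-square distribution with 1 df (no boundary
#' correction): OU is preferred when it exceeds the critical value
#' (3.841 at level 0.05).
#'
#' @param fit_bm,fit_ou `trait_fit` objects for the same data.
#' @param alpha_level Test level (default 0.05).
#' @return List with `statistic`, `critical`, `p_value` and `decision`
#'   (`"BM"` or `"OU"`).
#' @export
lrt_bm_vs_ou <- function(fit_bm, fit_ou, alpha_level = 0.05) {
  stopifnot(fit_bm$model == "BM", fit_ou$model == "OU")
  if (fit_bm$n != fit_ou$n)
    stop("fits have different sample sizes", call. = FALSE)
  lambda <- 2 * (fit_ou$logLik - fit_bm$logLik)
  # BM is the alpha -> 0 boundary of OU; with alpha bounded at 1e-6 the
  # OU fit can sit a hair's breadth below BM's likelihood, so clamp
  # small negatives silently and warn only on material violations
  if (lambda < -0.01)
    warning("logL(OU) < logL(BM) beyond numerical tolerance")
  lambda <- max(lambda, 0)
  crit <- stats::qchisq(1 - alpha_level, df = 1)
  list(statistic = lambda, critical = crit,
       p_value = stats::pchisq(lambda, df = 1, lower.tail = FALSE),
       decision = if (lambda > crit) "OU" else "BM")
}

#' Transfer a regime painting onto a pruned tree
#'
#' Pruning preserves the MRCAs of retained tips, so each internal node of
#' the pruned tree corresponds to an original node: it is found as the
#' original MRCA of one representative tip from each child subtree, and
#' inherits that node's state. Tips keep their original states; merged
#' edges take the state of their (pruned-tree) parent node.
#'
#' @param tree Original `phylo` the painting was simulated on.
#' @param painting `regime_painting` on `tree`.
#' @param pruned_tree A tree obtained from `tree` via [prune_tips()].
#' @return A `regime_painting` on `pruned_tree`.
#' @export
prune_painting <- function(tree, painting, pruned_tree) {
  n_tip <- length(pruned_tree$tip.label)
  state <- integer(n_tip + pruned_tree$Nnode)
  state[seq_len(n_tip)] <-
    painting$node_state[match(pruned_tree$tip.label, tree$tip.label)]
  tv <- tree_traversal(pruned_tree)
  rep_tip <- integer(n_tip + pruned_tree$Nnode)
  rep_tip[seq_len(n_tip)] <- seq_len(n_tip)
  for (z in tv$node_order) {
    ch <- tv$children_of[[as.character(z)]]
    rep_tip[z] <- rep_tip[ch[1]]
    orig <- ape::getMRCA(tree, pruned_tree$tip.label[
      c(rep_tip[ch[1]], rep_tip[ch[2]])])
    state[z] <- painting$node_state[orig]
  }
  regime_painting(pruned_tree, state)
}
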