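#' @export
print.trait_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Trait-evolution model fit: %s (n = %d tips)\n", x$model, x$n))
  if (!isTRUE(x$converged)) {
    cat("  <fit did not converge; estimates unavailable>\n")
    return(invisible(x))
  }
  est <- format(signif(x$estimates, digits))
  cat("  estimates: ",
      paste(names(x$estimates), est, sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  logLik = %.*f   k = %d   AICc = %.*f\n",
              digits, x$logLik, x$k, digits, x$aicc))
  if (x$boundary) cat("  note: profiled parameter at search boundary\n")
  invisible(x)
}

#' @export
summary.trait_fit <- function(object, ...) {
  structure(object, class = c("summary.trait_fit", "trait_fit"))
}

#' @export
print.summary.trait_fit <- function(x, digits = 4, ...) {
  print.trait_fit(x, digits = digits, ...)
  if (isTRUE(x$converged) && x$model %in% c("OU", "OUM")) {
    hl <- log(2) / x$estimates[["alpha"]]
    cat(sprintf("  phylogenetic half-life ln(2)/alpha = %.*f tree heights\n",
                digits, hl))
    cat(sprintf("  stationary variance sigma2/(2 alpha) = %.*f\n",
                digits,
                x$estimates[["sigma2_0"]] / (2 * x$estimates[["alpha"]])))
  }
  invisible(x)
}

#' @export
coef.trait_fit <- function(object, ...) object$estimates

#' @export
logLik.trait_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' Expected tip values under a fitted model
#'
#' BM/BMS: the estimated root mean for every tip. OU: the estimated
#' optimum. OUM: the Hansen weight matrix applied to the estimated
#' optima.
#'
#' @param object A `trait_fit`.
#' @param ... Unused.
#' @return Named numeric vector over tips (sorted label order).
#' @export
predict.trait_fit <- function(object, ...) {
  est <- object$estimates
  tips <- names(object$trait)
  mu <- switch(object$model,
    BM = rep(est[["z_0"]], object$n),
    BMS = rep(est[["z_0"]], object$n),
    OU = rep(est[["theta_0"]], object$n),
    OUM = {
      W <- weight_matrix_from_segments(
        path_segments(object$tree, object$painting), est[["alpha"]])
      as.numeric(W %*% c(est[["theta_0"]], est[["theta_1"]]))
    })
  stats::setNames(mu, tips)
}

## Unit-rate covariance of a fitted model (used by residuals/simulate).
fitted_covariance <- function(object) {
  est <- object$estimates
  switch(object$model,
    BM = est[["sigma2_0"]] * mrca_depths(object$tree),
    BMS = bms_covariance(object$tree, object$painting,
                         est[["sigma2_0"]], est[["sigma2_1"]]),
    OU = est[["sigma2_0"]] * ou_covariance(object$tree, est[["alpha"]]),
    OUM = est[["sigma2_0"]] * ou_covariance(object$tree, est[["alpha"]]))
}

#' Residuals of a fitted trait model
#'
#' `type = "response"` gives raw deviations from the expected tip values;
#' `type = "normalized"` whitens them by the inverse Cholesky factor of
#' the fitted covariance, so under the model they are approximately iid
#' standard normal.
#'
#' @param object A `trait_fit`.
#' @param type `"response"` or `"normalized"`.
#' @param ... Unused.
#' @return Numeric vector over tips.
#' @export
residuals.trait_fit <- function(object, type = c("response", "normalized"),
                                ...) {
  type <- match.arg(type)
  r <- object$trait - predict(object)
  if (type == "response") return(r)
  V <- fitted_covariance(object)
  R <- safe_chol(V)
  stats::setNames(as.numeric(forwardsolve(t(R), r)), names(r))
}

#' Simulate traits from a fitted model
#'
#' Parametric-bootstrap draws: new tip traits are simulated on the
#' fitted tree under the fitted model and parameter estimates.
#'
#' @param object A `trait_fit`.
#' @param nsim Number of replicate trait vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with one column per replicate, rows named by tip.
#' @export
simulate.trait_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  est <- object$estimates
  spec <- switch(object$model,
    BM = model_spec("BM", sigma2_0 = est[["sigma2_0"]],
                    root_value = est[["z_0"]]),
    BMS = model_spec("BMS", sigma2_0 = est[["sigma2_0"]],
                     sigma2_1 = est[["sigma2_1"]], root_value = est[["z_0"]]),
    OU = model_spec("OU", sigma2_0 = est[["sigma2_0"]],
                    theta_0 = est[["theta_0"]], alpha = est[["alpha"]]),
    OUM = model_spec("OUM", sigma2_0 = est[["sigma2_0"]],
                     theta_0 = est[["theta_0"]], theta_1 = est[["theta_1"]],
                     alpha = est[["alpha"]]))
  sims <- replicate(nsim,
    simulate_trait(object$tree, object$painting, spec)[names(object$trait)])
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plot for a fitted trait model
#'
#' Observed tip values against fitted expectations, with the identity
#' line.
#'
#' @param x A `trait_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.trait_fit <- function(x, ...) {
  mu <- predict(x)
  graphics::plot(mu, x$trait,
                 xlab = "fitted expectation", ylab = "observed trait",
                 main = sprintf("%s fit (n = %d)", x$model, x$n), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
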