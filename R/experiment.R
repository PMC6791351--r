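#' Specification of one experiment cell
#'
#' A cell of the factorial design: a generating model for the trait of
#' interest, a missing-taxa scenario, and a missing-taxa percentage.
#' Scenarios: `nMT` (no missing taxa, `p_missing` must be 0), `rMT`
#' (random, per-tip Bernoulli), `cluMT` (phylogenetically clumped via a
#' thresholded Brownian liability) and `corMT` (missingness probability
#' linearly proportional to the trait value).
#'
#' @param scenario One of `"nMT"`, `"rMT"`, `"cluMT"`, `"corMT"`.
#' @param p_missing Missing-taxa fraction (0 for nMT; 0.1/0.5/0.9 in the
#'   study design).
#' @param model Generating model for the trait.
#' @param n_target Retained tip count after pruning (default 300).
#' @param trait_spec A [model_spec()]; defaults to the study parameters
#'   for `model`.
#' @param q Mk transition rate for the regime character (default 0.5).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("nMT", "rMT", "cluMT", "corMT"),
                          p_missing = 0, model = c("BM", "BMS", "OU", "OUM"),
                          n_target = 300L, trait_spec = NULL, q = 0.5) {
  scenario <- match.arg(scenario)
  model <- match.arg(model)
  if (scenario == "nMT" && p_missing != 0)
    stop("nMT requires p_missing = 0", call. = FALSE)
  if (scenario != "nMT" && p_missing <= 0)
    stop(scenario, " requires p_missing > 0", call. = FALSE)
  if (is.null(trait_spec)) trait_spec <- model_spec(model)
  stopifnot(trait_spec$model == model)
  structure(list(scenario = scenario, p_missing = p_missing, model = model,
                 n_target = as.integer(n_target), trait_spec = trait_spec,
                 q = q),
            class = "scenario_spec")
}

## Draw the sampling status for one replicate under the cell's scenario.
draw_status <- function(spec, tree, trait) {
  tips <- tree$tip.label
  switch(spec$scenario,
    nMT = stats::setNames(rep.int(1L, length(tips)), tips),
    rMT = sample_missing_random(tips, spec$p_missing),
    cluMT = sample_missing_clumped(simulate_liability(tree, sigma2 = 1),
                                   spec$p_missing),
    corMT = sample_missing_correlated(trait, spec$p_missing))
}

#' Run one simulation replicate
#'
#' Full pipeline for one replicate of a cell: simulate a pure-birth tree
#' sized so `n_target` tips remain after pruning; repeatedly draw the
#' regime character, the trait and the sampling status until the minority
#' regime covers 25-45% of the retained tips (the whole triple is redrawn
#' on failure, because under corMT the retained set depends on the
#' trait); compute the Fritz-Purvis D of the sampling status on the full
#' tree (skipped for nMT); prune; fit the requested models to the pruned
#' data with the pruned regime painting; select the AICc-best model.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed for this replicate.
#' @param fit_models Models to fit (default all four; `character(0)`
#'   skips fitting, e.g. for D-statistic-only replicates).
#' @param n_null_d Null replicates for the D statistic.
#' @param compute_d Whether to compute D (ignored for nMT).
#' @param max_attempts Cap on regime-balance redraws.
#' @return A list of class `replicate_record`.
#' @export
run_replicate <- function(spec, seed,
                          fit_models = c("BM", "BMS", "OU", "OUM"),
                          n_null_d = 1000L, compute_d = TRUE,
                          max_attempts = 1000L) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  n0 <- initial_tree_size(spec$p_missing, spec$n_target)
  tree <- simulate_yule_tree(n0)
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("regime-balance rejection loop exhausted after ",
           max_attempts, " attempts (seed ", seed, ")", call. = FALSE)
    painting <- simulate_mk_regimes(tree, q = spec$q)
    trait <- simulate_trait(tree, painting, spec$trait_spec)
    status <- draw_status(spec, tree, trait)
    retained <- names(status)[status == 1L]
    if (length(retained) < 5L) next
    if (regime_balance_ok(painting, tree, retained)) break
  }
  D <- NULL
  if (spec$scenario != "nMT" && compute_d)
    D <- d_statistic(tree, status, n_null = n_null_d)
  am <- apply_missingness(tree, trait, status)
  ptree <- am$tree
  ppaint <- if (spec$scenario == "nMT") painting
            else prune_painting(tree, painting, ptree)
  fits <- lapply(fit_models, function(m)
    fit_trait_model(ptree, am$trait, m, painting = ppaint))
  names(fits) <- fit_models
  sel <- if (length(fits) >= 2L) select_best(fits)
         else if (length(fits) == 1L)
           list(best = fit_models, delta = stats::setNames(0, fit_models))
         else list(best = NA_character_, delta = numeric(0))
  structure(
    list(seed = seed, scenario = spec$scenario, p_missing = spec$p_missing,
         model = spec$model, trait_spec = spec$trait_spec,
         attempts = attempts, n_retained = length(ptree$tip.label),
         D = if (is.null(D)) NA_real_ else D$D,
         fits = fits, best = sel$best, delta = sel$delta,
         delta_generating = unname(sel$delta[spec$model])),
    class = "replicate_record")
}

## True parameter values of a generating model, in reporting order.
true_params <- function(spec) {
  ts <- spec$trait_spec %||% spec
  switch(ts$model %||% spec$model,
    BM = c(sigma2_0 = ts$sigma2_0),
    BMS = c(sigma2_0 = ts$sigma2_0, sigma2_1 = ts$sigma2_1),
    OU = c(sigma2_0 = ts$sigma2_0, theta_0 = ts$theta_0, alpha = ts$alpha),
    OUM = c(sigma2_0 = ts$sigma2_0, theta_0 = ts$theta_0,
            theta_1 = ts$theta_1, alpha = ts$alpha))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Estimates of the generating model across records, converged fits only.
generating_estimates <- function(records) {
  model <- records[[1]]$model
  keep <- vapply(records, function(r) isTRUE(r$fits[[model]]$converged),
                 logical(1))
  pn <- names(true_params(records[[1]]))
  est <- vapply(records[keep], function(r) r$fits[[model]]$estimates[pn],
                numeric(length(pn)))
  t(matrix(est, nrow = length(pn), dimnames = list(pn, NULL)))
}

#' Model-selection error rate of a cell
#'
#' Counts replicates whose AICc-best model is not the generating model,
#' plus the frequency of each selected model.
#'
#' @param records List of `replicate_record` from one cell.
#' @return One-row data frame: cell identifiers, replicate count, number
#'   and proportion miss-selected, and `best_BM` ... `best_OUM` counts.
#' @export
summarize_error_rates <- function(records) {
  stopifnot(length(records) >= 1)
  r1 <- records[[1]]
  best <- vapply(records, function(r) r$best, character(1))
  miss <- sum(best != r1$model)
  counts <- vapply(c("BM", "BMS", "OU", "OUM"),
                   function(m) sum(best == m), integer(1))
  data.frame(model = r1$model, scenario = r1$scenario,
             p_missing = r1$p_missing, n_reps = length(records),
             n_miss = miss, prop_miss = miss / length(records),
             best_BM = counts[["BM"]], best_BMS = counts[["BMS"]],
             best_OU = counts[["OU"]], best_OUM = counts[["OUM"]])
}

#' Median delta AICc of the generating model when it loses
#'
#' Median, over the miss-selected replicates only, of the generating
#' model's AICc minus the best model's AICc. `NA` when every replicate
#' selected the generating model.
#'
#' @inheritParams summarize_error_rates
#' @return One-row data frame.
#' @export
summarize_delta_aicc <- function(records) {
  r1 <- records[[1]]
  miss <- Filter(function(r) r$best != r$model, records)
  med <- if (length(miss)) stats::median(
    vapply(miss, function(r) r$delta_generating, numeric(1))) else NA_real_
  data.frame(model = r1$model, scenario = r1$scenario,
             p_missing = r1$p_missing, n_miss = length(miss),
             median_delta_aicc = med)
}

#' Normalized bias of parameter estimates
#'
#' For each parameter of the generating model, the mean estimate (over
#' converged fits of the generating model itself) minus the true value,
#' divided by the true value.
#'
#' @inheritParams summarize_error_rates
#' @return Data frame with one row per parameter: true value, mean
#'   estimate, bias and normalized bias.
#' @export
summarize_bias <- function(records) {
  r1 <- records[[1]]
  truth <- true_params(r1)
  est <- generating_estimates(records)
  m <- colMeans(est)
  data.frame(model = r1$model, scenario = r1$scenario,
             p_missing = r1$p_missing, parameter = names(truth),
             true = unname(truth), mean_estimate = unname(m),
             bias = unname(m - truth),
             normalized_bias = unname((m - truth) / truth),
             n_used = nrow(est), row.names = NULL)
}

#' Normalized precision (median absolute deviation) of estimates
#'
#' Median absolute deviation from the median of the estimates, divided by
#' the true value; smaller is more precise.
#'
#' @inheritParams summarize_error_rates
#' @return Data frame with one row per parameter.
#' @export
summarize_precision <- function(records) {
  r1 <- records[[1]]
  truth <- true_params(r1)
  est <- generating_estimates(records)
  mad_raw <- apply(est, 2, function(v) stats::median(abs(v - stats::median(v))))
  data.frame(model = r1$model, scenario = r1$scenario,
             p_missing = r1$p_missing, parameter = names(truth),
             true = unname(truth), mad = unname(mad_raw),
             normalized_precision = unname(mad_raw / truth),
             n_used = nrow(est), row.names = NULL)
}

## Flatten one record to a CSV-friendly row.
replicate_row <- function(rec, id) {
  est <- rep(NA_real_, 5)
  names(est) <- c("sigma2_0", "sigma2_1", "theta_0", "theta_1", "alpha")
  f <- rec$fits[[rec$model]]
  if (isTRUE(f$converged)) est[names(f$estimates)] <- f$estimates
  aiccs <- vapply(c("BM", "BMS", "OU", "OUM"), function(m)
    if (m %in% names(rec$fits)) rec$fits[[m]]$aicc else NA_real_, numeric(1))
  data.frame(replicate = id, seed = rec$seed, model = rec$model,
             scenario = rec$scenario, p_missing = rec$p_missing,
             attempts = rec$attempts, n_retained = rec$n_retained,
             D = rec$D, best = rec$best,
             delta_generating = rec$delta_generating,
             aicc_BM = aiccs[["BM"]], aicc_BMS = aiccs[["BMS"]],
             aicc_OU = aiccs[["OU"]], aicc_OUM = aiccs[["OUM"]],
             est_sigma2_0 = est[["sigma2_0"]], est_sigma2_1 = est[["sigma2_1"]],
             est_theta_0 = est[["theta_0"]], est_theta_1 = est[["theta_1"]],
             est_alpha = est[["alpha"]])
}

#' Run a replicated missing-taxa experiment
#'
#' Enumerates the cells (generating model x scenario x percentage; nMT
#' appears once per model at p = 0), runs `reps` replicates per cell with
#' seeds derived deterministically from `seed`, and writes per-replicate
#' and per-cell summary CSVs (error rates, median delta AICc, bias,
#' precision, D means) plus a JSON manifest to `out_dir` when given.
#'
#' @param models Generating models to include.
#' @param scenarios Missing-taxa scenarios to include.
#' @param ps Missing percentages for the non-nMT scenarios.
#' @param reps Replicates per cell.
#' @param seed Master seed.
#' @param out_dir Optional output directory (created if needed).
#' @param n_null_d Null replicates per D statistic.
#' @param n_target Retained tip count.
#' @param verbose Print per-cell progress.
#' @return Invisibly, a list with `records` (per cell), `error_rates`,
#'   `delta_aicc`, `bias`, `precision` and `dstat_means` data frames.
#' @export
run_experiment <- function(models = c("BM", "BMS", "OU", "OUM"),
                           scenarios = c("nMT", "rMT", "cluMT", "corMT"),
                           ps = c(0.1, 0.5, 0.9),
                           reps = 1000L, seed = 1L, out_dir = NULL,
                           n_null_d = 1000L, n_target = 300L,
                           verbose = FALSE) {
  cells <- list()
  for (m in models) {
    if ("nMT" %in% scenarios)
      cells[[length(cells) + 1L]] <- scenario_spec("nMT", 0, m, n_target)
    for (sc in setdiff(scenarios, "nMT"))
      for (p in ps)
        cells[[length(cells) + 1L]] <- scenario_spec(sc, p, m, n_target)
  }
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             length(cells) * reps),
                  nrow = length(cells))
  all_records <- vector("list", length(cells))
  rows <- list()
  for (i in seq_along(cells)) {
    sp <- cells[[i]]
    if (verbose)
      message(sprintf("cell %d/%d: %s %s p=%.1f", i, length(cells),
                      sp$model, sp$scenario, sp$p_missing))
    recs <- lapply(seq_len(reps), function(j)
      run_replicate(sp, seeds[i, j], n_null_d = n_null_d))
    all_records[[i]] <- recs
    rows[[i]] <- do.call(rbind, Map(replicate_row, recs, seq_len(reps)))
  }
  replicates <- do.call(rbind, rows)
  error_rates <- do.call(rbind, lapply(all_records, summarize_error_rates))
  delta_aicc <- do.call(rbind, lapply(all_records, summarize_delta_aicc))
  bias <- do.call(rbind, lapply(all_records, summarize_bias))
  precision <- do.call(rbind, lapply(all_records, summarize_precision))
  dsub <- replicates[!is.na(replicates$D), , drop = FALSE]
  dstat_means <- if (nrow(dsub))
    stats::aggregate(D ~ model + scenario, data = dsub, FUN = mean)
  else data.frame(model = character(), scenario = character(), D = numeric())
  out <- list(records = all_records, replicates = replicates,
              error_rates = error_rates, delta_aicc = delta_aicc,
              bias = bias, precision = precision,
              dstat_means = dstat_means)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(replicates, file.path(out_dir, "replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(error_rates, file.path(out_dir, "table2_error_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(delta_aicc, file.path(out_dir, "table3_delta_aicc.csv"),
                     row.names = FALSE)
    utils::write.csv(bias, file.path(out_dir, "table4_bias.csv"),
                     row.names = FALSE)
    utils::write.csv(precision, file.path(out_dir, "table5_precision.csv"),
                     row.names = FALSE)
    utils::write.csv(dstat_means, file.path(out_dir, "dstat_means.csv"),
                     row.names = FALSE)
    manifest <- list(seed = seed, reps = reps, n_target = n_target,
                     n_null_d = n_null_d,
                     cells = lapply(cells, function(s)
                       list(model = s$model, scenario = s$scenario,
                            p_missing = s$p_missing)),
                     rejection_attempts = lapply(all_records, function(rs)
                       vapply(rs, function(r) r$attempts, integer(1))),
                     r_version = as.character(getRversion()))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
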