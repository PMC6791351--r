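# Fake replicate records with known fields, for exercising the summary
# arithmetic without running simulations.
fake_record <- function(model = "BM", best = "BM", delta_gen = 0,
                        est = c(sigma2_0 = 0.5), converged = TRUE,
                        scenario = "nMT", p = 0) {
  fits <- list()
  fits[[model]] <- list(model = model, estimates = est,
                        converged = converged, aicc = 0)
  spec <- model_spec(model)
  structure(list(seed = 1L, scenario = scenario, p_missing = p,
                 model = model, trait_spec = spec, attempts = 1L,
                 n_retained = 300L, D = NA_real_, fits = fits,
                 best = best, delta = c(BM = 0), delta_generating = delta_gen),
            class = "replicate_record")
}

test_that("scenario specifications enforce the design invariants", {
  expect_error(scenario_spec("nMT", 0.5, "BM"), "p_missing = 0")
  expect_error(scenario_spec("rMT", 0, "BM"), "p_missing > 0")
  sp <- scenario_spec("cluMT", 0.5, "OUM")
  expect_equal(sp$trait_spec$model, "OUM")
  expect_equal(sp$n_target, 300L)
})

test_that("error-rate summaries count miss-selected replicates", {
  recs <- c(replicate(7, fake_record(best = "BM"), simplify = FALSE),
            replicate(2, fake_record(best = "OU"), simplify = FALSE),
            replicate(1, fake_record(best = "BMS"), simplify = FALSE))
  tab <- summarize_error_rates(recs)
  expect_equal(tab$n_miss, 3L)
  expect_equal(tab$prop_miss, 0.3)
  expect_equal(tab$best_BM + tab$best_BMS + tab$best_OU + tab$best_OUM,
               tab$n_reps)
  all_correct <- replicate(5, fake_record(), simplify = FALSE)
  expect_equal(summarize_error_rates(all_correct)$n_miss, 0L)
})

test_that("median delta AICc is over miss-selected replicates only", {
  recs <- list(fake_record(best = "OU", delta_gen = 1.5))
  expect_equal(summarize_delta_aicc(recs)$median_delta_aicc, 1.5)
  recs <- c(recs, list(fake_record(best = "OU", delta_gen = 3.5),
                       fake_record(best = "BM", delta_gen = 0)))
  expect_equal(summarize_delta_aicc(recs)$median_delta_aicc, 2.5)
  expect_true(is.na(summarize_delta_aicc(
    list(fake_record(best = "BM")))$median_delta_aicc))
})

test_that("bias and precision summaries follow their definitions", {
  exact <- replicate(4, fake_record(est = c(sigma2_0 = 0.5)),
                     simplify = FALSE)
  b <- summarize_bias(exact)
  expect_equal(b$normalized_bias, 0)
  expect_equal(b$parameter, "sigma2_0")

  ests <- c(0.4, 0.5, 0.5, 0.6, 1.0)
  recs <- lapply(ests, function(e) fake_record(est = c(sigma2_0 = e)))
  p <- summarize_precision(recs)
  expect_equal(p$normalized_precision, 0.2)  # MAD 0.1 over true 0.5
  b2 <- summarize_bias(recs)
  expect_equal(b2$normalized_bias, (mean(ests) - 0.5) / 0.5)
  # non-converged fits are excluded
  recs2 <- c(recs, list(fake_record(est = c(sigma2_0 = 99),
                                    converged = FALSE)))
  expect_equal(summarize_bias(recs2)$n_used, 5L)
  expect_equal(summarize_bias(recs2)$normalized_bias, b2$normalized_bias)
  same <- replicate(3, fake_record(est = c(sigma2_0 = 0.7)),
                    simplify = FALSE)
  expect_equal(summarize_precision(same)$normalized_precision, 0)
})

test_that("one replicate runs the whole pipeline per scenario", {
  sp <- scenario_spec("nMT", 0, "BM", n_target = 60L)
  r <- run_replicate(sp, 1001, n_null_d = 100)
  expect_s3_class(r, "replicate_record")
  expect_equal(r$n_retained, 60L)
  expect_true(is.na(r$D))
  expect_equal(length(r$fits), 4L)
  expect_equal(unname(r$delta[r$best]), 0)
  expect_gte(r$delta_generating, 0)

  spc <- scenario_spec("cluMT", 0.5, "BM", n_target = 60L)
  rc <- run_replicate(spc, 1002, n_null_d = 100, fit_models = "BM")
  expect_equal(rc$n_retained, 60L)  # exactly half of 120 dropped
  expect_false(is.na(rc$D))

  spo <- scenario_spec("corMT", 0.1, "BM", n_target = 60L)
  ro <- run_replicate(spo, 1003, n_null_d = 100, fit_models = "BM")
  expect_equal(ro$n_retained, 60L)

  # determinism: identical seed, identical record
  r2 <- run_replicate(sp, 1001, n_null_d = 100)
  expect_equal(replicate_rows_equal <- replicate_row(r, 1),
               replicate_row(r2, 1))
})

test_that("corMT replicates always retain the minimum-trait tip", {
  sp <- scenario_spec("corMT", 0.5, "BM", n_target = 40L)
  for (s in 2001:2005) {
    set.seed(s)
    n0 <- initial_tree_size(0.5, 40L)
    tree <- simulate_yule_tree(n0)
    trait <- simulate_trait(tree, NULL, model_spec("BM"))
    status <- sample_missing_correlated(trait, 0.5)
    expect_equal(unname(status[names(which.min(trait))]), 1L)
  }
})

test_that("a small experiment writes coherent tables and is reproducible", {
  out1 <- tempfile("exp1")
  res <- run_experiment(models = "BM", scenarios = "cluMT", ps = 0.5,
                        reps = 2, seed = 99, out_dir = out1,
                        n_null_d = 50, n_target = 40L)
  expect_equal(nrow(res$replicates), 2L)
  expect_equal(res$error_rates$n_reps, 2L)
  expect_equal(nrow(res$bias), 1L)       # BM has one reported parameter
  expect_equal(res$bias$parameter, "sigma2_0")
  expect_true(all(file.exists(file.path(out1, c(
    "replicates.csv", "table2_error_rates.csv", "table3_delta_aicc.csv",
    "table4_bias.csv", "table5_precision.csv", "dstat_means.csv",
    "manifest.json")))))
  out2 <- tempfile("exp2")
  run_experiment(models = "BM", scenarios = "cluMT", ps = 0.5,
                 reps = 2, seed = 99, out_dir = out2,
                 n_null_d = 50, n_target = 40L)
  expect_identical(readLines(file.path(out1, "replicates.csv")),
                   readLines(file.path(out2, "replicates.csv")))
  unlink(c(out1, out2), recursive = TRUE)
})
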