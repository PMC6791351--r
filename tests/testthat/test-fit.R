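test_that("model selection picks the lowest AICc with documented tie-breaks", {
  mk <- function(model, aicc, k) list(model = model, aicc = aicc, k = k)
  fits <- list(BM = mk("BM", 10, 2), BMS = mk("BMS", 12, 3),
               OU = mk("OU", 11, 3), OUM = mk("OUM", 13, 4))
  sel <- select_best(fits)
  expect_equal(sel$best, "BM")
  expect_equal(unname(sel$delta), c(0, 2, 1, 3))
  # exact tie: fewer parameters wins
  fits$OU$aicc <- 10
  expect_equal(select_best(fits)$best, "BM")
  # tie on AICc and k: fixed model order decides
  fits2 <- list(OU = mk("OU", 5, 3), BMS = mk("BMS", 5, 3))
  expect_equal(select_best(fits2)$best, "BMS")
  expect_equal(min(select_best(fits)$delta), 0)
})

test_that("the BM-vs-OU likelihood-ratio test uses the chi-square(1) cutoff", {
  mkfit <- function(model, ll, n) list(model = model, logLik = ll, n = n)
  expect_equal(lrt_bm_vs_ou(mkfit("BM", -10, 300),
                            mkfit("OU", -10, 300))$decision, "BM")
  r <- lrt_bm_vs_ou(mkfit("BM", -10, 300), mkfit("OU", -7.5, 300))
  expect_equal(r$statistic, 5)
  expect_equal(r$critical, qchisq(0.95, 1))
  expect_equal(r$decision, "OU")
  expect_error(lrt_bm_vs_ou(mkfit("BM", -10, 300), mkfit("OU", -9, 200)),
               "sample sizes")
})

test_that("maximised likelihoods dominate the truth and respect nesting", {
  set.seed(29)
  for (gen in c("BM", "OUM")) {
    tr <- simulate_yule_tree(80)
    pt <- simulate_mk_regimes(tr, 0.5)
    while (length(unique(pt$edge_state)) < 2) pt <- simulate_mk_regimes(tr, 0.5)
    spec <- model_spec(gen)
    x <- simulate_trait(tr, pt, spec)
    fits <- lapply(c("BM", "BMS", "OU", "OUM"), function(m)
      fit_trait_model(tr, x, m, painting = pt))
    names(fits) <- c("BM", "BMS", "OU", "OUM")
    ll <- vapply(fits, function(f) f$logLik, numeric(1))
    # ML dominates the likelihood at the generating parameters
    expect_gte(ll[[gen]] + 1e-6, trait_model_loglik(tr, x, spec, pt))
    # nesting: the richer model can never fit worse
    expect_gte(ll[["BMS"]], ll[["BM"]] - 1e-6)
    expect_gte(ll[["OUM"]], ll[["OU"]] - 1e-6)
    # OU contains BM as its alpha -> 0 boundary
    expect_gte(ll[["OU"]], ll[["BM"]] - 1e-3)
  }
})

test_that("BM fits recover the generating rate without material bias", {
  set.seed(30)
  ests <- replicate(30, {
    tr <- simulate_yule_tree(100)
    x <- simulate_trait(tr, NULL, model_spec("BM"))
    fit_trait_model(tr, x, "BM")$estimates[["sigma2_0"]]
  })
  expect_lt(abs(mean(ests) - 0.5), 0.05)
  expect_true(all(ests > 0))
})

test_that("OUM fits on OUM data recover optima and report k = 4", {
  set.seed(31)
  tr <- simulate_yule_tree(150)
  pt <- simulate_mk_regimes(tr, 0.5)
  while (length(unique(pt$edge_state)) < 2) pt <- simulate_mk_regimes(tr, 0.5)
  x <- simulate_trait(tr, pt, model_spec("OUM"))
  f <- fit_trait_model(tr, x, "OUM", pt)
  expect_equal(f$k, 4L)
  expect_equal(f$n, 150L)
  expect_equal(f$aicc, aicc(f$logLik, 4, 150))
  expect_lt(abs(f$estimates[["theta_0"]] - 10), 1)
  expect_lt(abs(f$estimates[["theta_1"]] - 11), 1)
  expect_true(all(f$estimates[c("sigma2_0", "alpha")] > 0))
})

test_that("degenerate inputs are flagged rather than fitted", {
  tr <- simulate_yule_tree(20, seed = 32)
  flat <- setNames(rep(2.5, 20), tr$tip.label)
  f <- fit_trait_model(tr, flat, "BM")
  expect_false(f$converged)
  expect_true(is.na(f$aicc))
  expect_error(fit_trait_model(tr, flat[1:10], "BM"), "cover")
  expect_error(fit_trait_model(tr, setNames(rnorm(20), tr$tip.label),
                               "OUM"), "painting")
})

test_that("paintings transfer onto pruned trees via preserved MRCAs", {
  set.seed(33)
  tree <- simulate_yule_tree(60)
  pt <- simulate_mk_regimes(tree, 0.5)
  pruned <- prune_tips(tree, sample(tree$tip.label, 20))
  pp <- prune_painting(tree, pt, pruned)
  n_tip <- length(pruned$tip.label)
  # tips keep their states
  expect_equal(pp$node_state[seq_len(n_tip)],
               pt$node_state[match(pruned$tip.label, tree$tip.label)])
  # every internal node's state equals the state of the original MRCA of
  # its full descendant tip set (independent re-derivation)
  for (z in (n_tip + 1L):(n_tip + pruned$Nnode)) {
    tips_z <- pruned$tip.label[
      unlist(ape::prop.part(pruned)[z - n_tip], use.names = FALSE)]
    orig <- ape::getMRCA(tree, tips_z)
    expect_equal(pp$node_state[z], pt$node_state[orig])
  }
  expect_equal(pp$edge_state, pp$node_state[pruned$edge[, 1]])
})

test_that("trait_fit methods expose coefficients, likelihood and residuals", {
  set.seed(34)
  tr <- simulate_yule_tree(40)
  pt <- simulate_mk_regimes(tr, 0.5)
  while (length(unique(pt$edge_state)) < 2) pt <- simulate_mk_regimes(tr, 0.5)
  x <- simulate_trait(tr, pt, model_spec("OUM"))
  f <- fit_trait_model(tr, x, "OUM", pt)
  expect_named(coef(f), c("sigma2_0", "theta_0", "theta_1", "alpha"))
  ll <- logLik(f)
  expect_equal(attr(ll, "df"), 4L)
  expect_equal(attr(ll, "nobs"), 40L)
  expect_output(print(f), "OUM")
  expect_output(print(summary(f)), "half-life")
  mu <- predict(f)
  expect_named(mu, sort(tr$tip.label))
  r <- residuals(f)
  expect_equal(unname(r), unname(f$trait - mu))
  rn <- residuals(f, type = "normalized")
  expect_gt(var(rn), 0.3)
  expect_lt(var(rn), 3)
  sims <- simulate(f, nsim = 3, seed = 35)
  expect_equal(dim(sims), c(40L, 3L))
  expect_equal(simulate(f, nsim = 2, seed = 36),
               simulate(f, nsim = 2, seed = 36))
  bmf <- fit_trait_model(tr, x, "BM")
  expect_equal(unname(predict(bmf)), rep(coef(bmf)[["z_0"]], 40))
})
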