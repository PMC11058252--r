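test_that("point fit recovers truth from noise-free matrices", {
  env <- default_env()
  mat <- simulate_rate_matrix(env, ref_params(), noise_sd = 0,
                              n_replicates = 1, seed = 1)
  fit <- nls_fit(mat)
  expect_true(fit$converged)
  truth <- c(L0 = 50.8, K_L = 57.2, K_N = 2.8)
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # basic form fits mu_0, K_L, K_N only, storages pinned at zero
  fb <- nls_fit(mat, model_spec("multiplicative_basic"))
  expect_setequal(names(fb$estimates), c("mu_0", "K_L", "K_N"))
  expect_true(fb$converged)
  # no-acetate protocol fixes L0 = 0
  fa <- nls_fit(mat, model_spec(acetate = FALSE))
  expect_setequal(names(fa$estimates), c("K_L", "K_N"))
})

test_that("degenerate fitting inputs are rejected", {
  env <- default_env()
  mat <- simulate_rate_matrix(env, ref_params(), 0, 1, seed = 1)
  expect_error(nls_fit(mat[0, ]), "empty")
  expect_error(nls_fit(mat[1, ]), "non-identifiable")
  flat <- mat; flat$mu_per_day <- 1.5
  expect_error(nls_fit(flat), "identical")
})

test_that("bootstrap selection follows the inverse-variance weighting law", {
  env <- default_env()
  mat <- simulate_rate_matrix(env, ref_params(), noise_sd = 0.05,
                              n_replicates = 2, seed = 2)
  # SE ratio 1:3 at every condition -> weights 1/1 : 1/9 -> rep1 w.p. 0.9
  mat$se_per_day <- ifelse(mat$replicate_id == "rep1", 0.1, 0.3)
  B <- 200
  boot <- bootstrap_fit(mat, B = B, seed = 4)
  n_draws <- B * 64
  freq <- boot$selection_counts[["rep1"]] / n_draws
  expect_lt(abs(freq - 0.9), 3 * sqrt(0.9 * 0.1 / n_draws))
})

test_that("zero standard errors get the dominant finite weight", {
  w <- colimfit:::condition_weights(c(0.1, 0.3, 0))
  expect_equal(w, c(100, 100 / 9, 100) / (200 + 100 / 9), tolerance = 1e-12)
  expect_equal(colimfit:::condition_weights(c(0, 0)), c(0.5, 0.5))
})

test_that("identical replicates give a degenerate bootstrap at the point fit", {
  env <- default_env()
  mat <- simulate_rate_matrix(env, ref_params(), noise_sd = 0,
                              n_replicates = 3, seed = 1)
  boot <- bootstrap_fit(mat, B = 25, seed = 8)
  expect_equal(unname(boot$sds), rep(0, 3))
  expect_equal(boot$means, boot$point_fit$estimates, tolerance = 1e-9)
})

test_that("bootstrap spread grows with injected noise", {
  env <- default_env()
  sds <- sapply(c(0.05, 0.1, 0.2), function(s) {
    mat <- simulate_rate_matrix(env, ref_params(), noise_sd = s,
                                n_replicates = 3, seed = 6)
    bootstrap_fit(mat, B = 100, seed = 7)$sds
  })
  for (p in rownames(sds)) expect_true(all(diff(sds[p, ]) > 0))
})

test_that("parameter significance reports both Wald and tail readings", {
  env <- default_env()
  mat <- simulate_rate_matrix(env, ref_params(), noise_sd = 0.1,
                              n_replicates = 3, seed = 9)
  boot <- bootstrap_fit(mat, B = 50, seed = 10)
  # mean equal to the null gives p = 1
  fake <- boot
  fake$samples[, "L0"] <- fake$samples[, "L0"] - mean(fake$samples[, "L0"])
  expect_equal(param_significance(fake, "L0", 0)$p_wald, 1)
  # |mean - null| / sd = 1.96 gives p ~ 0.05
  fake$samples[, "L0"] <- stats::rnorm(50)
  s <- fake$samples[, "L0"]
  null <- mean(s) - 1.96 * stats::sd(s)
  expect_equal(param_significance(fake, "L0", null)$p_wald, 0.05,
               tolerance = 1e-3)
  # samples all on one side of the null: tail fraction below 2/B
  expect_lt(param_significance(boot, "L0", 0)$p_tail, 2 / 50)
  expect_error(param_significance(boot, "mu_max"), "not a free parameter")
  # degenerate distribution warns and reports 0/1 exactly
  fake$samples[, "L0"] <- 5
  expect_warning(p1 <- param_significance(fake, "L0", 5)$p_wald, "degenerate")
  expect_identical(p1, 1)
  expect_warning(p0 <- param_significance(fake, "L0", 0)$p_wald, "degenerate")
  expect_identical(p0, 0)
})

test_that("model comparison favors the generating multiplicative form", {
  env <- default_env()
  mat <- simulate_rate_matrix(env, ref_params(), noise_sd = 0.1,
                              n_replicates = 3, seed = 14)
  cmp <- compare_models(mat, list(model_spec("multiplicative_storage"),
                                  model_spec("liebig_min"),
                                  model_spec("multiplicative_basic")),
                        B = 40, seed = 15)
  expect_s3_class(cmp, "colim_compare")
  expect_identical(cmp$form[cmp$rank_sse == 1], "multiplicative_storage")
  # nested bound: with its rate ceiling freed, the storage form contains
  # the basic form (L0 = 0, mu_max = mu_0) and can always match it
  mats <- simulate_rate_matrix(env, ref_params(), noise_sd = 0.1,
                               n_replicates = 1, seed = 16)
  f_basic <- nls_fit(mats, model_spec("multiplicative_basic"))
  f_store <- nls_fit(mats, model_spec(free = c("mu_max", "L0", "K_L", "K_N")))
  expect_lte(f_store$sse, f_basic$sse * (1 + 1e-6) + 1e-9)
  # single spec: table of one row, no ranking columns
  one <- compare_models(mat, list(model_spec()), B = 5, seed = 1)
  expect_identical(nrow(one), 1L)
  expect_false("rank_sse" %in% names(one))
})

test_that("prediction maps are monotone and saturate at mu_max", {
  p <- ref_params()
  L <- c(seq(0, 150, by = 10), 1e12)
  N <- c(seq(0, 100, by = 10), 1e12)
  map <- predict_map(p, L, N)
  expect_identical(dim(map), c(length(N), length(L)))
  expect_equal(map[length(N), length(L)], 2.4, tolerance = 1e-9)
  expect_true(all(apply(map, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(map, 2, function(c) all(diff(c) >= 0))))
  # two lake scenarios: clear deep-water site vs bright mid-lake site
  cayuga <- growth_rate_multiplicative(0.1, 93, p)
  hemlock <- growth_rate_multiplicative(100, 17, p)
  expect_true(cayuga > 0 && cayuga < 2.4)
  expect_true(hemlock > 0 && hemlock < 2.4)
  expect_gt(hemlock, cayuga)
  # degenerate 1x1 grid
  expect_identical(dim(predict_map(p, 10, 5)), c(1L, 1L))
  expect_error(predict_map(p, c(5, 1), c(1, 2)), "ascending")
})

test_that("predicted-vs-observed pairing and its R2 are consistent", {
  env <- default_env()
  mat <- simulate_rate_matrix(env, ref_params(), noise_sd = 0,
                              n_replicates = 1, seed = 18)
  pv <- predicted_vs_observed(mat, ref_params())
  expect_equal(pv$mu_pred, pv$mu_obs, tolerance = 1e-12)
  expect_equal(attr(pv, "r2"), 1, tolerance = 1e-12)
  # algebraic identity: R2 = 1 - SSE/SST
  noisy <- simulate_rate_matrix(env, ref_params(), noise_sd = 0.15,
                                n_replicates = 1, seed = 19)
  pv2 <- predicted_vs_observed(noisy, ref_params())
  sse <- sum((pv2$mu_obs - pv2$mu_pred)^2)
  sst <- sum((pv2$mu_obs - mean(pv2$mu_obs))^2)
  expect_equal(attr(pv2, "r2"), 1 - sse / sst, tolerance = 1e-12)
  # shuffling observations destroys the fit
  set.seed(20)
  shuf <- noisy; shuf$mu_per_day <- sample(shuf$mu_per_day)
  expect_lt(attr(predicted_vs_observed(shuf, ref_params()), "r2"),
            attr(pv2, "r2"))
})
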