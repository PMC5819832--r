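test_that("prior-predictive mode reproduces the prior quantiles", {
  ds <- tiny_dataset()
  fit <- fit_bayes_binomial_glmm(ds,
    draws = 4000, chains = 2, seed = 3,
    prior_only = TRUE
  )
  # group log-odds prior: Normal(0, 2.5); intervals are on the response scale
  expect_equal(
    fit$intervals$upper95,
    rep(plogis(qnorm(0.975) * 2.5), nrow(fit$intervals)),
    tolerance = 0.02
  )
  expect_equal(fit$intervals$mean, rep(0.5, nrow(fit$intervals)), tolerance = 0.03)
})

test_that("Bayesian and Laplace GLMMs agree in the strong-data limit", {
  ds <- simulate_assay_dataset(
    simulation_scenario(
      group_logits = c(control = 0, mut = 1),
      n_days = 4, plates_per_group = 200, animals_per_plate = 100
    ),
    variance_components(0, 0, 0),
    seed = 19
  )
  freq <- fit_binomial_glmm(ds)
  bayes <- fit_bayes_binomial_glmm(ds, draws = 1000, chains = 2, seed = 20)
  i <- which(freq$contrasts$strain_a == "mut")
  j <- which(bayes$contrasts$strain_a == "mut")
  expect_lt(abs(freq$contrasts$estimate[i] - bayes$contrasts$estimate[j]), 0.1)
  expect_true(bayes$converged)
})

test_that("credible intervals are nested, match their draws, and flag thin posteriors", {
  ds <- simulate_assay_dataset(
    simulation_scenario(),
    variance_preset("low"),
    seed = 23
  )
  fit <- fit_bayes_binomial_glmm(ds, draws = 600, chains = 2, seed = 24)
  ci <- credible_intervals(fit)
  expect_true(all(ci$lower95 <= ci$lower75 & ci$upper75 <= ci$upper95))
  expect_true(all(ci$lower95 >= 0 & ci$upper95 <= 1))
  # endpoints recompute exactly from the stored response-scale draws
  for (k in seq_len(nrow(ci))) {
    dr <- fit$draws$response[, ci$strain[k]]
    expect_identical(
      unname(quantile(dr, c(0.025, 0.975), names = FALSE)),
      c(ci$lower95[k], ci$upper95[k])
    )
  }
  # two-sided posterior tail probability is consistent with the intervals:
  # raw_p < 0.05 iff the 95% contrast interval excludes zero
  tab <- fit$contrasts
  expect_equal(
    tab$raw_p < 0.05,
    tab$lower95 > 0 | tab$upper95 < 0
  )
  thin <- suppressWarnings(
    fit_bayes_binomial_glmm(ds, draws = 100, chains = 2, seed = 1)
  )
  expect_warning(credible_intervals(thin), "400")
  expect_error(
    fit_bayes_binomial_glmm(ds, draws = 0),
    class = "hid_config_error"
  )
})

test_that("the MCMC is reproducible in the seed and separation needs no ridge", {
  ds <- tiny_dataset()
  a <- fit_bayes_binomial_glmm(ds, draws = 300, chains = 2, seed = 5)
  b <- fit_bayes_binomial_glmm(ds, draws = 300, chains = 2, seed = 5)
  expect_identical(a$draws$beta, b$draws$beta)
  c <- fit_bayes_binomial_glmm(ds, draws = 300, chains = 2, seed = 6)
  expect_false(identical(a$draws$beta, c$draws$beta))

  ds_sep <- dataset_from_props(list(N2 = c(0.2, 0.3, 0.25), mut = c(0, 0, 0)), n = 20L)
  f <- fit_bayes_binomial_glmm(ds_sep, draws = 500, chains = 2, seed = 8)
  expect_true(all(is.finite(f$fixed_effects)))
  expect_true(all(is.finite(f$contrasts$estimate)))
})

test_that("split-Rhat detects disagreeing chains and passes stationary ones", {
  set.seed(42)
  same <- list(
    matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b"))),
    matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  )
  expect_true(all(abs(split_rhat(same) - 1) < 0.05))
  shifted <- same
  shifted[[2]][, 1] <- shifted[[2]][, 1] + 3
  expect_gt(split_rhat(shifted)[["a"]], 1.5)
  expect_lt(split_rhat(shifted)[["b"]], 1.05)
})

test_that("Bayesian Poisson GLMM recovers a rate ratio", {
  g <- simulate_grid_counts(c(N2 = 20, mut = 40), variance_components(0.2, 0.1, 0),
    n_worms_per_day = 40, n_days = 3, seed = 51
  )
  fit <- fit_poisson_glmm(g, bayes = TRUE, draws = 800, chains = 2, seed = 52)
  expect_identical(fit$method, "bayes_glmm_poisson")
  i <- which(fit$contrasts$strain_a == "mut")
  expect_equal(exp(fit$contrasts$estimate[i]), 2, tolerance = 0.2)
  expect_true(all(fit$intervals$lower95 >= 0))
})
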