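test_that("GLMM without random terms reproduces pooled logits exactly", {
  ds <- simulate_assay_dataset(
    simulation_scenario(group_logits = c(control = -0.4, a = 0.2, b = 0.9)),
    variance_preset("low"),
    seed = 14
  )
  fit <- fit_binomial_glmm(ds, random_terms = character(0))
  pooled <- aggregate(cbind(n_dauer, n_total) ~ strain_id, as.data.frame(ds), sum)
  expected <- qlogis(pooled$n_dauer / pooled$n_total)
  expect_equal(unname(fit$fixed_effects[pooled$strain_id]), expected, tolerance = 1e-6)
})

test_that("GLMM with random terms matches pooled estimates on variance-free data", {
  ds <- simulate_assay_dataset(
    simulation_scenario(
      group_logits = c(control = 0, a = 0.5),
      n_days = 4, plates_per_group = 100, animals_per_plate = 100
    ),
    variance_components(0, 0, 0),
    seed = 15
  )
  full <- fit_binomial_glmm(ds)
  pooled <- fit_binomial_glmm(ds, random_terms = character(0))
  expect_equal(full$fixed_effects, pooled$fixed_effects, tolerance = 1e-3)
  expect_true(all(full$variance_estimates < 0.05, na.rm = TRUE))
})

test_that("GLMM recovers a 1-logit contrast at large n", {
  sc <- simulation_scenario(
    group_logits = c(control = 0, mut = 1),
    n_days = 4, plates_per_group = 100, animals_per_plate = 100
  )
  ds <- simulate_assay_dataset(sc, variance_components(0, 0, 0), seed = 16)
  fit <- fit_binomial_glmm(ds)
  i <- which(fit$contrasts$strain_a == "mut")
  expect_gt(fit$contrasts$estimate[i], 0.9)
  expect_lt(fit$contrasts$estimate[i], 1.1)
  expect_true(fit$converged)
})

test_that("complete separation is ridge-stabilized and flagged", {
  ds <- dataset_from_props(
    list(N2 = c(0.2, 0.3, 0.25), mut = c(0, 0, 0)),
    n = 20L
  )
  fit <- fit_binomial_glmm(ds, random_terms = character(0))
  expect_true(fit$degenerate)
  expect_true(all(is.finite(fit$fixed_effects)))
  expect_true(all(is.finite(fit$contrasts$se)))
})

test_that("Poisson GLMM recovers rate ratios and reduces to log sample mean", {
  g <- simulate_grid_counts(c(N2 = 20, mut = 40), variance_components(0, 0, 0),
    n_worms_per_day = 170, n_days = 3, seed = 41
  )
  fit <- fit_poisson_glmm(g)
  i <- which(fit$contrasts$strain_a == "mut")
  ratio <- exp(fit$contrasts$estimate[i])
  expect_gt(ratio, 1.85)
  expect_lt(ratio, 2.15)

  # identical groups: ratio ~ 1, interval covers 1 on the rate scale
  g_eq <- simulate_grid_counts(c(a = 25, b = 25), variance_components(0, 0, 0),
    n_worms_per_day = 100, n_days = 2, seed = 42
  )
  f_eq <- fit_poisson_glmm(g_eq)
  expect_equal(exp(f_eq$contrasts$estimate), 1, tolerance = 0.1)
  expect_lt(abs(f_eq$contrasts$statistic), 3.3) # well inside the null band
  expect_true(f_eq$contrasts$lower95 <= 1 || f_eq$contrasts$raw_p > 0.001)

  # single group, no random effects: intercept = log of the sample mean
  g1 <- simulate_grid_counts(c(only = 15), variance_components(0, 0, 0),
    n_worms_per_day = 40, n_days = 1, seed = 43
  )
  f1 <- fit_poisson_glmm(g1,
    random_terms = character(0),
    contrasts = contrast_spec("none")
  )
  expect_equal(unname(f1$fixed_effects), log(mean(g1$score)), tolerance = 1e-8)

  # all-zero group flagged and stabilized
  g0 <- data.frame(
    strain_id = rep(c("a", "b"), each = 4), day_id = "d1",
    worm_id = paste0("w", 1:8), score = c(5, 7, 6, 4, 0, 0, 0, 0)
  )
  f0 <- fit_poisson_glmm(g0, random_terms = character(0))
  expect_true(f0$degenerate)
  expect_true(all(is.finite(f0$fixed_effects)))
})

test_that("log10 LMM recovers geometric-mean ratios and rejects bad input", {
  # ratio 2 in geometric mean, no day/plate variance, small residual noise
  set.seed(77)
  d <- data.frame(
    strain_id = rep(c("wt", "mut"), each = 30),
    day_id = rep(rep(c("d1", "d2", "d3"), each = 10), 2),
    plate_id = rep(rep(c("pl1", "pl2"), each = 5), 6),
    intensity = 100 * 2^rep(c(0, 1), each = 30) * 10^rnorm(60, 0, 0.02)
  )
  fit <- fit_lmm_log10(d)
  i <- which(fit$contrasts$strain_a == "mut")
  expect_equal(fit$contrasts$estimate[i], log10(2), tolerance = 0.05)

  # identical groups: difference ~ 0
  d0 <- d
  d0$intensity <- rep(100, 60) * 10^rnorm(60, 0, 0.02)
  f0 <- fit_lmm_log10(d0)
  expect_equal(f0$contrasts$estimate, 0, tolerance = 0.03)

  d_bad <- d
  d_bad$intensity[3] <- -1
  expect_error(fit_lmm_log10(d_bad), class = "hid_validation_error")
})

test_that("log10 LMM recovers a simulated day variance component", {
  # day sd 0.1 on the log10 scale, averaged over replicates
  est <- vapply(1:40, function(r) {
    set.seed(900 + r)
    n_days <- 8
    day_eff <- rnorm(n_days, 0, 0.1)
    d <- expand.grid(day = seq_len(n_days), worm = 1:12)
    d$intensity <- 10^(2 + day_eff[d$day] + rnorm(nrow(d), 0, 0.05))
    df <- data.frame(
      strain_id = "wt", day_id = paste0("d", d$day),
      plate_id = paste0("pl", d$day), intensity = d$intensity
    )
    fit_lmm_log10(df,
      contrasts = contrast_spec("none"),
      random_terms = "day"
    )$variance_estimates[["sd_day"]]
  }, numeric(1))
  expect_equal(mean(est), 0.1, tolerance = 0.15)
})

test_that("likelihood-ratio test behaves at its boundary cases", {
  ds <- simulate_assay_dataset(
    simulation_scenario(group_logits = c(control = 0, mut = 2), plates_per_group = 51),
    variance_components(0, 0, 0),
    seed = 61
  )
  full <- fit_binomial_glmm(ds, random_terms = character(0))
  expect_identical(lrt_nested(full, full)$statistic, 0)
  expect_identical(lrt_nested(full, full)$p, 1)

  # strong fixed effect: collapse strain labels for the reduced model
  ds_red <- assay_dataset(
    rep("all", nrow(ds)), ds$day_id, ds$plate_id, ds$n_total, ds$n_dauer
  )
  reduced <- fit_binomial_glmm(ds_red,
    random_terms = character(0),
    contrasts = contrast_spec("none")
  )
  res <- lrt_nested(full, reduced)
  expect_equal(res$df, 1L)
  expect_lt(res$p, 1e-4)

  # non-nested: reduced has a random term the full model lacks
  f_day <- fit_binomial_glmm(ds, random_terms = "day")
  expect_error(lrt_nested(full, f_day), class = "hid_nesting_error")

  # reversed log-likelihoods beyond tolerance -> refit error
  expect_error(lrt_nested(reduced, full), class = "hid_refit_error")
})

test_that("null fixed-effect LRT follows its chi-square(1) reference", {
  sc <- simulation_scenario(
    group_logits = c(control = 0, mut = 0),
    plates_per_group = 6
  )
  stat <- vapply(1:300, function(r) {
    ds <- simulate_assay_dataset(sc, variance_components(0, 0, 0),
      seed = derive_seed(700, r)
    )
    full <- fit_binomial_glmm(ds,
      random_terms = character(0),
      contrasts = contrast_spec("none")
    )
    ds_red <- assay_dataset(
      rep("all", nrow(ds)), ds$day_id, ds$plate_id, ds$n_total, ds$n_dauer
    )
    reduced <- fit_binomial_glmm(ds_red,
      random_terms = character(0),
      contrasts = contrast_spec("none")
    )
    lrt_nested(full, reduced)$statistic
  }, numeric(1))
  # chi-square(1): 95th percentile 3.84, mean 1
  expect_equal(unname(quantile(stat, 0.95)), qchisq(0.95, 1), tolerance = 0.25)
  expect_equal(mean(stat), 1, tolerance = 0.25)
  # boundary-corrected reference halves the tail p
  p_naive <- pchisq(3, 1, lower.tail = FALSE)
  f <- fit_result(method = "anova", log_lik = 1.5, n_params = 2L, param_names = "a")
  r <- fit_result(method = "anova", log_lik = 0, n_params = 1L, param_names = "a")
  expect_equal(lrt_nested(f, r)$p, p_naive)
  expect_equal(lrt_nested(f, r, boundary_correction = TRUE)$p, p_naive / 2 + 0.5 * 0)
})
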