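test_that("single-contrast adjustment is the identity and 'none' passes through", {
  expect_equal(adjust_multcomp(2.1, diag(1), df = 10), 2 * pt(-2.1, 10))
  p <- c(0.01, 0.2, 0.6)
  expect_identical(
    adjust_multcomp(c(1, 2, 3), raw_p = p, scheme = "none"),
    p
  )
})

test_that("independent contrasts approach the Sidak limit", {
  for (k in c(2, 4)) {
    z <- qnorm(1 - 0.025) # each contrast has raw two-sided p = 0.05
    adj <- adjust_multcomp(rep(z, k), diag(k), df = Inf)
    expect_equal(adj, rep(1 - 0.95^k, k), tolerance = 1e-3)
  }
})

test_that("Dunnett-type adjustment matches a brute-force multivariate-t simulation", {
  # oracle: max|T| distribution simulated from first principles — shared
  # control numerator + chi-square denominator, never via pmvt
  k <- 3
  rho <- 0.5
  df <- 12
  tstat <- c(2.2, 1.0, 2.8)
  set.seed(4242)
  n_mc <- 4e5
  z0 <- rnorm(n_mc)
  zi <- matrix(rnorm(n_mc * k), ncol = k)
  num <- sqrt(rho) * z0 + sqrt(1 - rho) * zi # compound-symmetric normals
  denom <- sqrt(rchisq(n_mc, df) / df)
  maxT <- apply(abs(num / denom), 1, max)
  oracle <- vapply(abs(tstat), function(t) mean(maxT >= t), numeric(1))
  corr <- matrix(rho, k, k)
  diag(corr) <- 1
  adj <- adjust_multcomp(tstat, corr, df = df)
  expect_equal(adj, oracle, tolerance = 0.003)
})

test_that("adjustment never decreases a p-value and rejects bad correlation input", {
  set.seed(9)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    t <- rnorm(k, 0, 2)
    A <- matrix(rnorm(k * k), k)
    corr <- cov2cor(crossprod(A) + diag(k))
    raw <- 2 * pnorm(-abs(t))
    adj <- adjust_multcomp(t, corr, df = Inf)
    expect_true(all(adj >= raw - 1e-12))
    expect_true(all(adj <= 1))
  }
  bad <- matrix(c(1, 2, 2, 1), 2, 2) # not PSD
  expect_error(adjust_multcomp(c(1, 2), bad, df = Inf), class = "hid_validation_error")
})

test_that("adjusted p-values agree with the established multivariate-t implementation", {
  # independent cross-check of the whole ANOVA + Dunnett path against
  # multcomp's glht on the same model
  skip_if_not_installed("multcomp")
  ds <- simulate_assay_dataset(
    simulation_scenario(group_logits = c(control = 0, a = 0.6, b = -0.2)),
    variance_preset("low"),
    seed = 71
  )
  ours <- anova_prop(ds)
  df0 <- data.frame(
    prop = plate_proportions(ds),
    strain = stats::relevel(factor(ds$strain_id), "control")
  )
  ref <- summary(multcomp::glht(
    stats::aov(prop ~ strain, df0),
    linfct = multcomp::mcp(strain = "Dunnett")
  ))
  ref_p <- as.numeric(ref$test$pvalues)
  names(ref_p) <- sub(" - control", "", rownames(ref$linfct))
  expect_equal(
    ours$contrasts$adjusted_p[match(names(ref_p), ours$contrasts$strain_a)],
    unname(ref_p),
    tolerance = 2e-3
  )
})

test_that("dose-response GLM recovers odds ratios and flags rank deficiency", {
  # identical strains: odds ratio ~ 1
  set.seed(55)
  doses <- rep(c(0, 1, 2, 4), each = 6)
  mk <- function(strain_shift, n = 60) {
    eta <- -2 + 0.8 * rep(doses, 2) + rep(c(0, strain_shift), each = length(doses))
    data.frame(
      strain_id = rep(c("N2", "rict-1"), each = length(doses)),
      n_total = n, n_dauer = rbinom(2 * length(doses), n, plogis(eta)),
      dose = rep(doses, 2)
    )
  }
  d0 <- mk(0)
  f0 <- fit_dose_response_glm(d0, control = "N2")
  expect_equal(unname(f0$diagnostics$odds_ratios), 1, tolerance = 0.35)

  # strain offset log(21.3) on the logit scale recovers the target odds ratio
  d1 <- mk(log(21.3), n = 120)
  f1 <- fit_dose_response_glm(d1, control = "N2")
  or <- unname(f1$diagnostics$odds_ratios)
  expect_gt(or, 17)
  expect_lt(or, 27)
  expect_true(all(c("strain", "dose") %in% f1$diagnostics$wald$term))
  expect_lt(f1$diagnostics$wald$p[f1$diagnostics$wald$term == "dose"], 1e-6)

  d_one <- d1[d1$dose == 1, ]
  expect_error(fit_dose_response_glm(d_one, control = "N2"), class = "hid_rank_error")
})

test_that("null dose effects give calibrated Wald tests", {
  rej <- vapply(1:300, function(r) {
    set.seed(1300 + r)
    doses <- rep(c(0, 1, 2), each = 8)
    d <- data.frame(
      strain_id = "N2", n_total = 40,
      n_dauer = rbinom(length(doses), 40, 0.3), dose = doses
    )
    f <- fit_dose_response_glm(d, control = "N2")
    f$diagnostics$wald$p[f$diagnostics$wald$term == "dose"] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("quadratic dose model fits a curved continuous response", {
  set.seed(66)
  doses <- rep(c(0, 1, 2, 3), each = 10)
  d <- data.frame(
    strain_id = rep(c("wt", "mut"), 20),
    dose = doses,
    response = 5 + 2 * doses - 0.4 * doses^2 +
      0.5 * (rep(c(0, 1), 20)) + rnorm(40, 0, 0.2)
  )
  f <- fit_dose_response_glm(d, model = "quadratic", control = "wt")
  expect_equal(unname(f$fixed_effects[["dose"]]), 2, tolerance = 0.2)
  expect_equal(unname(f$fixed_effects[["I(dose^2)"]]), -0.4, tolerance = 0.2)
})
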