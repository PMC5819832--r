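#' Fit results
#'
#' Every analysis route in the package (Welch t-tests, ANOVA, frequentist
#' and Bayesian binomial GLMMs, Poisson GLMM, log10 LMM, dose-response GLM)
#' returns the same container so that downstream code — multiplicity
#' adjustment, credible-interval extraction, the method-comparison engine,
#' result serialization — is method-agnostic.
#'
#' @section Structure:
#' A `hid_fit` is a list with elements:
#' * `method` — one of `"welch_t"`, `"anova"`, `"glmm_binomial"`,
#'   `"bayes_glmm_binomial"`, `"glmm_poisson"`, `"bayes_glmm_poisson"`,
#'   `"lmm_log10"`, `"glm_dose"`.
#' * `fixed_effects` — named per-group estimates on the link scale.
#' * `variance_estimates` — fitted `sd_day` / `sd_plate` / `sd_history`
#'   (where the model has them; `NA` otherwise).
#' * `contrasts` — data.frame with columns `strain_a`, `strain_b`,
#'   `estimate` (link scale, a minus b), `se`, `statistic`, `df`, `raw_p`,
#'   `adjusted_p`, and for Bayesian fits `lower95`/`upper95` of the
#'   contrast posterior and `post_prob_direction`. For Bayesian fits
#'   `raw_p` holds the two-sided posterior tail probability
#'   `2 * min(Pr(d > 0), Pr(d < 0))`, so "the 100(1-a)% equal-tailed
#'   interval excludes zero" is exactly `raw_p < a`.
#' * `intervals` — per-group response-scale summaries: `mean`, `lower95`,
#'   `upper95`, `lower75`, `upper75` (75% nested in 95%).
#' * `converged`, `degenerate` — logical flags.
#' * `log_lik`, `n_params`, `param_names` — for nested likelihood-ratio
#'   tests.
#' * `draws` — for Bayesian fits, a list of posterior draw matrices.
#' * `diagnostics` — e.g. split-R-hat per parameter.
#' * `seed` — the seed used, or `NA`.
#'
#' @param ... named elements as above; missing ones are filled with
#'   defaults.
#' @return A list of class `hid_fit`.
#' @name fit_result
#' @export
fit_result <- function(...) {
  x <- list(...)
  defaults <- list(
    method = NA_character_, fixed_effects = numeric(0),
    variance_estimates = c(sd_day = NA_real_, sd_plate = NA_real_, sd_history = NA_real_),
    contrasts = empty_contrast_table(), intervals = NULL,
    converged = TRUE, degenerate = FALSE,
    log_lik = NA_real_, n_params = NA_integer_, param_names = character(0),
    draws = NULL, diagnostics = list(), seed = NA_integer_
  )
  for (nm in names(defaults)) if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  ctr <- x$contrasts
  if (nrow(ctr) && any(ctr$adjusted_p + 1e-12 < ctr$raw_p, na.rm = TRUE)) {
    hid_abort("adjusted p-values must be >= raw p-values", "hid_validation_error")
  }
  structure(x, class = "hid_fit")
}

empty_contrast_table <- function() {
  data.frame(
    strain_a = character(0), strain_b = character(0), estimate = numeric(0),
    se = numeric(0), statistic = numeric(0), df = numeric(0),
    raw_p = numeric(0), adjusted_p = numeric(0), stringsAsFactors = FALSE
  )
}

#' @export
print.hid_fit <- function(x, ...) {
  cat(sprintf(
    "<hid_fit> method: %s | converged: %s%s\n", x$method, x$converged,
    if (isTRUE(x$degenerate)) " | DEGENERATE" else ""
  ))
  if (length(x$fixed_effects)) {
    cat("Group estimates (link scale):\n")
    print(round(x$fixed_effects, 4))
  }
  ve <- x$variance_estimates
  if (any(!is.na(ve))) {
    cat("Variance components (sd):\n")
    print(round(ve[!is.na(ve)], 4))
  }
  if (nrow(x$contrasts)) {
    cat("Contrasts:\n")
    print(x$contrasts, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Central credible / confidence intervals on the response scale
#'
#' For Bayesian fits, equal-tailed posterior quantile intervals of each
#' group's response-scale mean (the expected proportion or rate for a
#' typical day/plate, i.e. with random effects at zero); for frequentist
#' fits, Wald intervals mapped through the inverse link. The 75% interval
#' is nested inside the 95% interval by quantile monotonicity.
#'
#' @param fit a `hid_fit`.
#' @param levels numeric vector of central interval levels.
#' @return data.frame with one row per group: `strain`, `mean`, and
#'   `lower`/`upper` columns per level.
#' @export
credible_intervals <- function(fit, levels = c(0.95, 0.75)) {
  stopifnot(inherits(fit, "hid_fit"))
  if (!is.null(fit$draws) && !is.null(fit$draws$response)) {
    dr <- fit$draws$response # matrix draws x groups, response scale
    if (nrow(dr) < 400) {
      warning("fewer than 400 posterior draws; intervals are noisy")
    }
    out <- data.frame(strain = colnames(dr), mean = colMeans(dr))
    for (lv in levels) {
      a <- round((1 - lv) / 2, 10) # 0.025 exactly, not 0.025000000000000022
      q <- apply(dr, 2, quantile, probs = c(a, 1 - a), names = FALSE)
      out[[sprintf("lower%d", round(lv * 100))]] <- q[1, ]
      out[[sprintf("upper%d", round(lv * 100))]] <- q[2, ]
    }
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(fit$intervals)) {
    hid_abort("fit carries neither posterior draws nor stored intervals", "hid_validation_error")
  }
  fit$intervals
}

# Wald-style per-group response-scale intervals for frequentist fits.
# linkinv maps link scale -> response; intervals for binomial fits are
# clamped to [0, 1] (the clamp only matters for the t-based plate-mean
# intervals, which are not themselves logit-scale).
wald_intervals <- function(strains, est, se, df = Inf, linkinv = identity,
                           clamp01 = FALSE, levels = c(0.95, 0.75)) {
  out <- data.frame(strain = strains, mean = linkinv(est))
  for (lv in levels) {
    a <- (1 - lv) / 2
    qq <- qt(1 - a, df) # df may be vectorized; qt handles df = Inf
    lo <- linkinv(est - qq * se)
    hi <- linkinv(est + qq * se)
    if (clamp01) {
      lo <- pmin(pmax(lo, 0), 1)
      hi <- pmin(pmax(hi, 0), 1)
    }
    out[[sprintf("lower%d", round(lv * 100))]] <- lo
    out[[sprintf("upper%d", round(lv * 100))]] <- hi
  }
  rownames(out) <- NULL
  out
}
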