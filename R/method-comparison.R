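#' Define one condition of the method-comparison study
#'
#' A condition fixes the data-generating regime under which the four
#' dauer-assay analysis methods are compared: the variance preset, design
#' balance, the fraction of days with systematic control bias, and whether
#' the truth is null (all groups equal) or carries the reference effect of
#' 1 logit in one test group. The simulated design per replicate follows
#' the standard layout: a control and two test genotypes, 6 assay plates
#' per group sampled over 3 days.
#'
#' @param variance `"none"`, `"low"`, `"high"` (see [variance_preset()]),
#'   or a [variance_components()] object.
#' @param balanced logical; unbalanced designs drop each test group from
#'   one day (see [simulation_scenario()]).
#' @param bias_fraction fraction of days with a shared control-day offset.
#' @param scenario `"null_all_equal"` or `"one_effect_logit1"`.
#' @param n_reps simulation replicates for this condition.
#' @param alpha nominal per-comparison test level.
#' @param label optional display label.
#' @return A list of class `comparison_condition`.
#' @export
comparison_condition <- function(variance = "low", balanced = TRUE,
                                 bias_fraction = 0,
                                 scenario = c("null_all_equal", "one_effect_logit1"),
                                 n_reps = 1000L, alpha = 0.05, label = NULL) {
  scenario <- match.arg(scenario)
  if (n_reps < 1L) hid_abort("n_reps must be >= 1", "hid_config_error")
  if (alpha <= 0 || alpha >= 1) hid_abort("alpha must lie in (0, 1)", "hid_config_error")
  vc <- if (is.character(variance)) variance_preset(variance) else as_variance_components(variance)
  vname <- if (is.character(variance)) variance else "custom"
  if (is.null(label)) {
    label <- sprintf(
      "%s variance, %s%s, %s", vname,
      if (balanced) "balanced" else "unbalanced",
      if (bias_fraction > 0) sprintf(", bias %g", bias_fraction) else "",
      if (scenario == "null_all_equal") "null" else "effect 1 logit"
    )
  }
  structure(
    list(
      variance = vc, variance_name = vname, balanced = balanced,
      bias_fraction = bias_fraction, scenario = scenario,
      n_reps = as.integer(n_reps), alpha = alpha, label = label
    ),
    class = "comparison_condition"
  )
}

#' Monte Carlo comparison of the four dauer-assay analysis methods
#'
#' For each condition and replicate, a clustered-binomial dataset is drawn
#' with [simulate_assay_dataset()] (control + two test genotypes, 6 plates
#' per group over 3 days) and analyzed with each requested method using
#' Dunnett-type contrasts against the control. A comparison is "rejected"
#' when its per-contrast p-value is below alpha (frequentist routes) or
#' when the `100(1 - alpha)%` equal-tailed credible interval of the
#' contrast excludes zero (Bayesian route). Per-comparison type-I error is
#' the rejection rate over truly-null contrasts; type-II error is the
#' fraction of replicates in which the 1-logit effect contrast is not
#' detected. Non-converged fits are excluded from the rates and counted.
#'
#' The full per-replicate rejection log is retained, so rates can be
#' recomputed at other alpha levels ([rates_from_log()]) without
#' refitting.
#'
#' @param conditions a [comparison_condition()] or list of them.
#' @param methods subset of `c("welch_t", "anova", "glmm_binomial",
#'   "bayes_glmm_binomial")`.
#' @param seed root seed; replicate r of condition c uses sub-stream
#'   `derive_seed(seed, c, r)`.
#' @param base_logit control log-odds (all groups under the null).
#' @param effect_logit the test effect under the effect scenario.
#' @param animals_per_plate animals scored per plate.
#' @param bayes_draws,bayes_chains,bayes_adapt,bayes_burn reduced MCMC
#'   settings used inside the loop.
#' @param adjust_families also compute single-step multivariate-t adjusted
#'   p-values per replicate (family-wise rates; slower).
#' @return An object of class `hid_method_comparison`: list with `rates`
#'   (per condition x method), `log` (per condition x replicate x method x
#'   contrast), `conditions`, `methods`, `alpha`, `seed`.
#' @export
run_comparison <- function(conditions, methods = c(
                             "welch_t", "anova",
                             "glmm_binomial", "bayes_glmm_binomial"
                           ),
                           seed = 1L, base_logit = 0, effect_logit = 1,
                           animals_per_plate = 50L,
                           bayes_draws = 500L, bayes_chains = 2L,
                           bayes_adapt = 300L, bayes_burn = 500L,
                           adjust_families = TRUE) {
  if (inherits(conditions, "comparison_condition")) conditions <- list(conditions)
  methods <- match.arg(methods,
    c("welch_t", "anova", "glmm_binomial", "bayes_glmm_binomial"),
    several.ok = TRUE
  )
  if (!length(methods)) hid_abort("at least one method required", "hid_config_error")
  logs <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    eff <- if (cond$scenario == "one_effect_logit1") effect_logit else 0
    scenario <- simulation_scenario(
      group_logits = c(
        control = base_logit, mutantA = base_logit + eff,
        mutantB = base_logit
      ),
      n_days = 3L, plates_per_group = 6L, balanced = cond$balanced,
      bias_fraction = cond$bias_fraction,
      animals_per_plate = animals_per_plate
    )
    cspec <- contrast_spec("dunnett_vs_control", control = "control")
    n_err <- setNames(integer(length(methods)), methods)
    for (r in seq_len(cond$n_reps)) {
      rseed <- derive_seed(seed, ci, r)
      ds <- simulate_assay_dataset(scenario, cond$variance, seed = rseed)
      for (m in methods) {
        fit <- tryCatch(
          switch(m,
            welch_t = welch_prop_test(ds, cspec, adjust = adjust_families),
            anova = anova_prop(ds, cspec, adjust = adjust_families),
            glmm_binomial = fit_binomial_glmm(ds,
              contrasts = cspec,
              adjust = adjust_families
            ),
            bayes_glmm_binomial = fit_bayes_binomial_glmm(ds,
              contrasts = cspec, draws = bayes_draws,
              chains = bayes_chains, adapt = bayes_adapt,
              burn = bayes_burn, seed = derive_seed(rseed, 7L)
            )
          ),
          error = function(e) e
        )
        if (inherits(fit, "error")) {
          n_err[m] <- n_err[m] + 1L
          next
        }
        tab <- fit$contrasts
        logs[[length(logs) + 1L]] <- data.frame(
          condition = cond$label, condition_idx = ci, rep = r, method = m,
          contrast = tab$strain_a, estimate = tab$estimate,
          raw_p = tab$raw_p, adjusted_p = tab$adjusted_p,
          true_effect = ifelse(tab$strain_a == "mutantA", eff, 0),
          converged = fit$converged, degenerate = fit$degenerate,
          stringsAsFactors = FALSE
        )
      }
    }
    bad <- n_err / cond$n_reps > 0.10
    if (any(bad)) {
      hid_abort(
        sprintf(
          "method(s) %s failed on >10%% of replicates in condition '%s'",
          paste(methods[bad], collapse = ", "), cond$label
        ),
        "hid_stage_error"
      )
    }
  }
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  alpha <- conditions[[1]]$alpha
  structure(
    list(
      rates = rates_from_log(log, alpha), log = log,
      conditions = conditions, methods = methods, alpha = alpha,
      seed = as.integer(seed)
    ),
    class = "hid_method_comparison"
  )
}

#' Recompute error rates from a stored rejection log
#'
#' Rates are pure bookkeeping over the per-replicate log, so alpha sweeps
#' and alternative families need no refitting. For the Bayesian method the
#' logged `raw_p` is the two-sided posterior tail probability; `raw_p <
#' alpha` is then exactly "the `100(1 - alpha)%` equal-tailed credible
#' interval excludes zero".
#'
#' @param log the `log` component of a `hid_method_comparison`.
#' @param alpha per-comparison level.
#' @param use_adjusted use the multiplicity-adjusted p-values (family-wise
#'   view) instead of the raw per-comparison ones.
#' @return data.frame with one row per condition x method: `type_I_rate`,
#'   `type_I_se`, `type_II_rate`, `type_II_se`, `n_null`, `n_effect`,
#'   `n_converged`, `n_degenerate`.
#' @export
rates_from_log <- function(log, alpha = 0.05, use_adjusted = FALSE) {
  p <- if (use_adjusted) log$adjusted_p else log$raw_p
  log$reject <- p < alpha
  keep <- log$converged
  out <- list()
  for (cond in unique(log$condition)) {
    for (m in unique(log$method)) {
      d <- log[log$condition == cond & log$method == m & keep, ]
      null_d <- d[d$true_effect == 0, ]
      eff_d <- d[d$true_effect != 0, ]
      t1 <- if (nrow(null_d)) mean(null_d$reject) else NA_real_
      t2 <- if (nrow(eff_d)) mean(!eff_d$reject) else NA_real_
      all_m <- log[log$condition == cond & log$method == m, ]
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, method = m,
        type_I_rate = t1,
        type_I_se = if (nrow(null_d)) sqrt(t1 * (1 - t1) / nrow(null_d)) else NA_real_,
        type_II_rate = t2,
        type_II_se = if (nrow(eff_d)) sqrt(t2 * (1 - t2) / nrow(eff_d)) else NA_real_,
        n_null = nrow(null_d), n_effect = nrow(eff_d),
        n_converged = length(unique(all_m$rep[all_m$converged])),
        n_degenerate = length(unique(all_m$rep[all_m$degenerate])),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a method comparison
#'
#' @param result a `hid_method_comparison`.
#' @param path optional CSV path (rates table; a JSON sidecar carries the
#'   metadata via [write_results()]).
#' @param plot if `TRUE` and ggplot2 is installed, also return a heatmap
#'   of type-I and type-II rates per condition and method.
#' @return The rates table (invisibly when written to `path`).
#' @export
summarize_comparison <- function(result, path = NULL, plot = FALSE) {
  stopifnot(inherits(result, "hid_method_comparison"))
  tab <- result$rates
  if (!is.null(path)) write_results(result, path)
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    long <- rbind(
      data.frame(
        condition = tab$condition, method = tab$method,
        error = "type I", rate = tab$type_I_rate
      ),
      data.frame(
        condition = tab$condition, method = tab$method,
        error = "type II", rate = tab$type_II_rate
      )
    )
    p <- ggplot2::ggplot(
      long,
      ggplot2::aes(x = method, y = condition, fill = rate)
    ) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(
        label = ifelse(is.na(rate), "", sprintf("%.3f", rate))
      ), size = 3) +
      ggplot2::facet_wrap(~error) +
      ggplot2::scale_fill_gradient(low = "white", high = "firebrick", na.value = "grey90") +
      ggplot2::labs(x = NULL, y = NULL, fill = "rate") +
      ggplot2::theme_minimal()
    return(list(table = tab, plot = p))
  }
  if (is.null(path)) tab else invisible(tab)
}

#' @export
print.hid_method_comparison <- function(x, ...) {
  cat(sprintf(
    "<hid_method_comparison> %d condition(s) x %d method(s), alpha = %g\n",
    length(x$conditions), length(x$methods), x$alpha
  ))
  print(x$rates, digits = 3, row.names = FALSE)
  invisible(x)
}
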