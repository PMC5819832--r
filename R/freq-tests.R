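#' Welch t-tests on plate-level dauer proportions
#'
#' The simplest of the four dauer-assay analysis routes: each requested
#' contrast is an unpooled two-sample t-test with Welch-Satterthwaite
#' degrees of freedom on the per-plate proportions, ignoring all clustering
#' by day or culture history. Group variances are floored at `var_floor` so
#' that constant groups (common in small simulated null datasets) yield a
#' computable statistic; such fits are flagged `degenerate`.
#'
#' @param data an `assay_dataset`.
#' @param contrasts a [contrast_spec()]; defaults to Dunnett-type contrasts
#'   against the dataset's control strain.
#' @param var_floor lower bound on a group's variance of plate proportions.
#' @param adjust apply single-step multivariate-t adjustment across the
#'   contrast family (raw per-contrast p-values are always reported too).
#' @return A [fit_result] with `method = "welch_t"`. Fixed effects are the
#'   group mean proportions (identity link); `intervals` are per-group
#'   t-based 95%/75% confidence intervals clamped to `[0, 1]`.
#' @export
welch_prop_test <- function(data, contrasts = NULL, var_floor = 1e-12,
                            adjust = TRUE) {
  stopifnot(inherits(data, "assay_dataset"))
  if (is.null(contrasts)) {
    contrasts <- contrast_spec("dunnett_vs_control", control = control_strain(data))
  }
  p <- plate_proportions(data)
  by_strain <- split(p, data$strain_id)
  strains <- names(by_strain)
  n <- vapply(by_strain, length, integer(1))
  m <- vapply(by_strain, mean, numeric(1))
  v <- vapply(by_strain, var, numeric(1))
  pairs <- contrast_pairs(data$strain_id, contrasts)
  compared <- unique(c(pairs$strain_a, pairs$strain_b))
  if (any(n[compared] < 2L)) {
    hid_abort(
      sprintf(
        "Welch test needs >= 2 plates per compared group (offending: %s)",
        paste(compared[n[compared] < 2L], collapse = ", ")
      ),
      "hid_replication_error"
    )
  }
  degenerate <- any(v[compared] <= var_floor)
  vf <- pmax(v, var_floor)
  tab <- empty_contrast_table()
  if (nrow(pairs)) {
    a <- pairs$strain_a
    b <- pairs$strain_b
    se <- sqrt(vf[a] / n[a] + vf[b] / n[b])
    stat <- (m[a] - m[b]) / se
    df <- (vf[a] / n[a] + vf[b] / n[b])^2 /
      ((vf[a] / n[a])^2 / (n[a] - 1) + (vf[b] / n[b])^2 / (n[b] - 1))
    raw_p <- 2 * pt(-abs(stat), df)
    # Correlation between contrast statistics induced by shared groups
    # (e.g. the common control in a Dunnett family).
    k <- nrow(pairs)
    corr <- diag(k)
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          cv <- 0
          for (s in strains) {
            ci <- (pairs$strain_a[i] == s) - (pairs$strain_b[i] == s)
            cj <- (pairs$strain_a[j] == s) - (pairs$strain_b[j] == s)
            cv <- cv + ci * cj * vf[s] / n[s]
          }
          corr[i, j] <- corr[j, i] <- cv / (se[i] * se[j])
        }
      }
    }
    adjusted <- if (adjust) {
      adjust_multcomp(stat, corr, df = min(df), raw_p = raw_p)
    } else {
      raw_p
    }
    tab <- data.frame(
      strain_a = a, strain_b = b, estimate = m[a] - m[b], se = se,
      statistic = stat, df = df, raw_p = raw_p, adjusted_p = adjusted,
      stringsAsFactors = FALSE
    )
    rownames(tab) <- NULL
  }
  fit_result(
    method = "welch_t",
    fixed_effects = m,
    contrasts = tab,
    intervals = wald_intervals(strains, m, sqrt(vf / n),
      df = pmax(n - 1, 1),
      clamp01 = TRUE
    ),
    converged = TRUE, degenerate = degenerate,
    log_lik = NA_real_, n_params = NA_integer_,
    param_names = paste0("mean:", strains)
  )
}

#' One-way ANOVA on plate-level dauer proportions
#'
#' Second analysis route: ordinary one-way ANOVA treating each plate's
#' dauer proportion as an independent Gaussian observation (clustering by
#' day and culture history again ignored). The omnibus F test is reported
#' in `diagnostics`; post-hoc contrasts use the pooled residual variance
#' and are adjusted by the single-step multivariate-t method
#' (Dunnett-type against the control or Tukey-type all pairs).
#'
#' @inheritParams welch_prop_test
#' @return A [fit_result] with `method = "anova"`; `diagnostics` holds
#'   `F`, `df1`, `df2` and the omnibus `p`.
#' @export
anova_prop <- function(data, contrasts = NULL, adjust = TRUE) {
  stopifnot(inherits(data, "assay_dataset"))
  if (is.null(contrasts)) {
    contrasts <- contrast_spec("dunnett_vs_control", control = control_strain(data))
  }
  if (length(unique(data$strain_id)) < 2L) {
    hid_abort("ANOVA requires at least two strains", "hid_replication_error")
  }
  df0 <- data.frame(prop = plate_proportions(data), strain = factor(data$strain_id))
  fit <- lm(prop ~ 0 + strain, data = df0)
  # perfect fits (all observations equal) trigger spurious precision warnings
  av <- suppressWarnings(anova(lm(prop ~ strain, data = df0)))
  est <- coef(fit)
  names(est) <- sub("^strain", "", names(est))
  V <- suppressWarnings(vcov(fit)) # perfect fits: "essentially perfect fit"
  dimnames(V) <- list(names(est), names(est))
  rdf <- fit$df.residual
  pairs <- contrast_pairs(data$strain_id, contrasts)
  tab <- contrast_table(est, V, pairs, df = rdf, adjust = adjust)
  sigma2 <- sum(fit$residuals^2) / rdf
  n_g <- table(df0$strain)[names(est)]
  fit_result(
    method = "anova",
    fixed_effects = est,
    contrasts = tab,
    intervals = wald_intervals(names(est), est, sqrt(sigma2 / as.numeric(n_g)),
      df = rdf, clamp01 = TRUE
    ),
    converged = TRUE,
    degenerate = sigma2 <= 1e-12,
    log_lik = as.numeric(logLik(fit)),
    n_params = length(est) + 1L,
    param_names = c(paste0("mean:", names(est)), "sigma"),
    diagnostics = list(
      # all-equal data gives 0/0; report F = 0, p = 1 for that degenerate case
      F = if (is.finite(av$`F value`[1])) av$`F value`[1] else 0,
      df1 = av$Df[1], df2 = av$Df[2],
      p = if (is.finite(av$`Pr(>F)`[1])) av$`Pr(>F)`[1] else 1
    )
  )
}
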