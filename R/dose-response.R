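#' Dose-response GLM for pheromone assays
#'
#' Binomial GLM for dauer formation across a pheromone (ascr#5) dose
#' series: `logit Pr(dauer) = intercept + strain + dose`, treatment-coded
#' against the control strain, so `exp(coef)` of a strain term is that
#' strain's odds ratio relative to control at any fixed dose. Reported per
#' term: the Wald chi-square statistic `(coef/se)^2` (or the multi-df block
#' Wald statistic for a multi-level strain factor).
#'
#' `model = "quadratic"` instead fits an ordinary least-squares regression
#' of a continuous response (e.g. fluorescence) on strain plus a quadratic
#' polynomial in dose.
#'
#' @param data for the logit model: an `assay_dataset` (or data.frame with
#'   `strain_id`, `n_total`, `n_dauer`) carrying a per-plate `dose` column;
#'   for the quadratic model: a data.frame with `strain_id`, `dose`,
#'   `response`.
#' @param model `"logit_linear_dose"` or `"quadratic"`.
#' @param control control strain; defaults to the dataset's control (or the
#'   first strain).
#' @return A [fit_result] with `method = "glm_dose"`. `diagnostics` holds
#'   `odds_ratios` (per non-control strain; logit model) and `wald` — a
#'   data.frame of per-term Wald chi-square, df and p.
#' @export
fit_dose_response_glm <- function(data, model = c("logit_linear_dose", "quadratic"),
                                  control = NULL) {
  model <- match.arg(model)
  if (is.null(control)) {
    control <- if (inherits(data, "assay_dataset")) control_strain(data) else data$strain_id[1]
  }
  if (!"dose" %in% names(data)) {
    hid_abort("data needs a per-row 'dose' column", "hid_schema_error")
  }
  if (any(data$dose < 0)) hid_abort("dose must be >= 0", "hid_validation_error")
  if (length(unique(data$dose)) < 2L) {
    hid_abort("dose term requested but only one dose level present", "hid_rank_error")
  }
  strain <- droplevels(factor(data$strain_id))
  multi <- nlevels(strain) > 1L
  if (multi) strain <- stats::relevel(strain, ref = control)
  if (model == "logit_linear_dose") {
    df <- data.frame(
      strain = strain, dose = data$dose,
      prop = data$n_dauer / data$n_total, n = data$n_total
    )
    form <- if (multi) prop ~ strain + dose else prop ~ dose
    fit <- glm(form, family = binomial(), weights = n, data = df)
  } else {
    if (!"response" %in% names(data)) {
      hid_abort("quadratic model needs a 'response' column", "hid_schema_error")
    }
    df <- data.frame(strain = strain, dose = data$dose, y = data$response)
    form <- if (multi) y ~ strain + dose + I(dose^2) else y ~ dose + I(dose^2)
    fit <- lm(form, data = df)
  }
  cf <- coef(fit)
  V <- vcov(fit)
  if (any(is.na(cf))) hid_abort("rank-deficient design", "hid_rank_error")
  # per-term block Wald chi-square
  asgn <- attr(model.matrix(fit), "assign")
  labs <- attr(fit$terms, "term.labels")
  wald <- do.call(rbind, lapply(seq_along(labs), function(k) {
    idx <- which(asgn == k)
    b <- cf[idx]
    W <- as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
    data.frame(
      term = labs[k], wald_chisq = W, df = length(idx),
      p = pchisq(W, length(idx), lower.tail = FALSE)
    )
  }))
  strain_idx <- grep("^strain", names(cf))
  or <- if (model == "logit_linear_dose" && length(strain_idx)) exp(cf[strain_idx]) else NULL
  if (!is.null(or)) names(or) <- sub("^strain", "", names(or))
  se <- sqrt(diag(V))
  tab <- if (length(strain_idx)) {
    data.frame(
      strain_a = sub("^strain", "", names(cf)[strain_idx]),
      strain_b = control,
      estimate = cf[strain_idx], se = se[strain_idx],
      statistic = cf[strain_idx] / se[strain_idx], df = Inf,
      raw_p = 2 * pnorm(-abs(cf[strain_idx] / se[strain_idx])),
      stringsAsFactors = FALSE
    )
  } else {
    empty_contrast_table()
  }
  tab$adjusted_p <- tab$raw_p
  rownames(tab) <- NULL
  fit_result(
    method = "glm_dose",
    fixed_effects = cf,
    contrasts = tab,
    converged = isTRUE(fit$converged) || inherits(fit, "lm"),
    log_lik = as.numeric(logLik(fit)), n_params = attr(logLik(fit), "df"),
    param_names = names(cf),
    diagnostics = list(odds_ratios = or, wald = wald, fit = fit)
  )
}
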