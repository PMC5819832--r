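#' Frequentist binomial GLMM for clustered dauer assays
#'
#' Third analysis route: the model actually matched to the data-generating
#' process. With plate i of strain s on day j,
#' \deqn{logit\,Pr(dauer) = \beta_s + b^{day}_j + b^{hist}_{sj} + b^{plate}_{ij}}
#' with independent Gaussian random intercepts for day (`sD`), strain-by-day
#' culture history (`sG`) and plate (`sP`). Fitting is by maximum likelihood
#' with the Laplace approximation (lme4); variance estimates are reported as
#' standard deviations and are naturally floored at zero.
#'
#' Complete separation (a strain with pooled proportion exactly 0 or 1) is
#' stabilized by a weak pseudo-count ridge: each strain receives one
#' pseudo-plate carrying `ridge` successes and `ridge` failures (default
#' half an animal each), shrinking group log-odds toward 0; such fits are
#' flagged `degenerate`.
#'
#' @param data an `assay_dataset`.
#' @param random_terms subset of `c("day", "history", "plate")`; empty
#'   reduces the model to a pooled binomial GLM whose group estimates equal
#'   the logits of the pooled proportions exactly.
#' @param contrasts a [contrast_spec()]; default Dunnett vs the control.
#' @param ridge pseudo-count ridge strength used under separation.
#' @param adjust apply multivariate-t adjustment across the family.
#' @return A [fit_result] with `method = "glmm_binomial"`: per-strain
#'   log-odds, fitted `sd_day`/`sd_history`/`sd_plate`, Wald z contrasts,
#'   response-scale Wald intervals, `log_lik`/`n_params` for [lrt_nested()].
#' @export
fit_binomial_glmm <- function(data, random_terms = c("day", "history", "plate"),
                              contrasts = NULL, ridge = 0.5, adjust = TRUE) {
  stopifnot(inherits(data, "assay_dataset"))
  if (is.null(contrasts)) {
    contrasts <- contrast_spec("dunnett_vs_control", control = control_strain(data))
  }
  if (length(random_terms)) {
    random_terms <- match.arg(random_terms, c("day", "history", "plate"),
      several.ok = TRUE
    )
  }
  df <- data.frame(
    strain = factor(data$strain_id),
    day = factor(data$day_id),
    plate = factor(paste(data$day_id, data$plate_id, sep = ":")),
    n_total = as.numeric(data$n_total),
    n_dauer = as.numeric(data$n_dauer)
  )
  # separation check on pooled per-strain counts
  pooled <- aggregate(cbind(n_dauer, n_total) ~ strain, df, sum)
  separated <- pooled$n_dauer == 0 | pooled$n_dauer == pooled$n_total
  degenerate <- any(separated)
  if (degenerate && ridge > 0) {
    extra <- data.frame(
      strain = pooled$strain,
      day = factor("ridge_pseudo_day"),
      plate = factor(paste0("ridge_pseudo_", seq_len(nrow(pooled)))),
      n_total = 2 * ridge, n_dauer = ridge
    )
    df <- rbind(df, extra)
  }
  df$hist <- interaction(df$strain, df$day, drop = TRUE)
  df$prop <- df$n_dauer / df$n_total
  df$strain <- droplevels(df$strain)

  re <- c(
    day = "(1 | day)", history = "(1 | hist)", plate = "(1 | plate)"
  )[random_terms]
  # a single-strain dataset has no strain factor to contrast-code
  fe <- if (nlevels(df$strain) > 1L) "prop ~ 0 + strain" else "prop ~ 1"
  conv_issue <- FALSE
  if (length(re) == 0L) {
    fit <- suppress_nonint(glm(as.formula(fe),
      family = binomial(),
      weights = n_total, data = df
    ))
    est <- coef(fit)
    V <- vcov(fit)
    vc <- c(sd_day = NA_real_, sd_plate = NA_real_, sd_history = NA_real_)
    ll <- as.numeric(logLik(fit))
    npar <- attr(logLik(fit), "df")
  } else {
    form <- as.formula(paste(fe, "+", paste(re, collapse = " + ")))
    fit <- withCallingHandlers(
      suppress_nonint(suppressMessages(lme4::glmer(form,
        family = binomial(), weights = n_total,
        data = df, nAGQ = 1L
      ))),
      warning = function(w) {
        if (grepl("converge|Hessian|gradient", conditionMessage(w), ignore.case = TRUE)) {
          conv_issue <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) conv_issue <- TRUE
    est <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    sd_of <- function(g) {
      i <- match(g, vcs$grp)
      if (is.na(i)) NA_real_ else vcs$sdcor[i]
    }
    vc <- c(
      sd_day = sd_of("day"), sd_plate = sd_of("plate"),
      sd_history = sd_of("hist")
    )
    ll <- as.numeric(logLik(fit))
    npar <- attr(logLik(fit), "df")
  }
  names(est) <- if (nlevels(df$strain) > 1L) {
    sub("^strain", "", names(est))
  } else {
    levels(df$strain)
  }
  dimnames(V) <- list(names(est), names(est))
  pairs <- contrast_pairs(data$strain_id, contrasts)
  tab <- contrast_table(est, V, pairs, df = Inf, adjust = adjust)
  fit_result(
    method = "glmm_binomial",
    fixed_effects = est,
    variance_estimates = vc,
    contrasts = tab,
    intervals = wald_intervals(names(est), est, sqrt(diag(V)),
      df = Inf, linkinv = plogis
    ),
    converged = !conv_issue,
    degenerate = degenerate,
    log_lik = ll, n_params = npar,
    param_names = c(
      paste0("beta:", names(est)),
      paste0("sd:", random_terms)
    ),
    diagnostics = list(fit = fit)
  )
}

# binomial/poisson weights with pseudo-counts emit "non-integer" warnings
suppress_nonint <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer", conditionMessage(w))) invokeRestart("muffleWarning")
  })
}

#' Poisson mixed model for grid-entry exploration counts
#'
#' Grid-entry scores are approximately Poisson-distributed counts, with
#' extra variance from assay date and from each worm's plate. The model is
#' \deqn{\log E[score] = \beta_s + b^{date}_j + b^{plate}_i}
#' with a random intercept per date (`sD`) and a per-observation (worm =
#' plate) random intercept absorbing plate-level overdispersion (`sP`).
#' The frequentist fit uses the Laplace approximation; `bayes = TRUE` runs
#' the MCMC analog with the same default weak priors as the binomial
#' Bayesian GLMM.
#'
#' @param data grid-count data.frame with columns `strain_id`, `day_id`,
#'   `worm_id`, `score` (see [read_grid_table()], [simulate_grid_counts()]).
#' @param bayes fit by MCMC instead of maximum likelihood.
#' @param random_terms subset of `c("day", "plate")`; empty reduces to a
#'   Poisson GLM (single-group intercept = log of the sample mean).
#' @param contrasts a [contrast_spec()]; `NULL` means Dunnett vs the first
#'   strain.
#' @param ridge pseudo-observation weight used to stabilize an all-zero
#'   group (flagged `degenerate`).
#' @param draws,chains,seed MCMC settings when `bayes = TRUE`.
#' @param adjust apply multivariate-t adjustment (frequentist route).
#' @return A [fit_result] with method `"glmm_poisson"` or
#'   `"bayes_glmm_poisson"`. Contrast estimates are log rate ratios;
#'   `intervals` are response-scale (rate) intervals.
#' @export
fit_poisson_glmm <- function(data, bayes = FALSE,
                             random_terms = c("day", "plate"),
                             contrasts = NULL, ridge = 0.5,
                             draws = 1000, chains = 4, seed = 1L,
                             adjust = TRUE) {
  need <- c("strain_id", "day_id", "worm_id", "score")
  if (!all(need %in% names(data))) {
    hid_abort("grid data needs columns strain_id, day_id, worm_id, score", "hid_schema_error")
  }
  if (any(data$score < 0)) hid_abort("negative count", "hid_validation_error")
  if (length(random_terms)) {
    random_terms <- match.arg(random_terms, c("day", "plate"), several.ok = TRUE)
  }
  if (is.null(contrasts)) {
    contrasts <- contrast_spec("dunnett_vs_control", control = data$strain_id[1])
  }
  df <- data.frame(
    strain = factor(data$strain_id),
    day = factor(data$day_id),
    obs = factor(paste(data$day_id, data$worm_id, sep = ":")),
    score = as.numeric(data$score),
    w = 1
  )
  zero_group <- tapply(df$score, df$strain, sum) == 0
  degenerate <- any(zero_group)
  if (degenerate && ridge > 0) {
    extra <- data.frame(
      strain = levels(df$strain), day = "ridge_pseudo_day",
      obs = paste0("ridge_pseudo_", seq_along(levels(df$strain))),
      score = 1, w = ridge
    )
    df <- rbind(df, extra)
    df$day <- factor(df$day)
    df$obs <- factor(df$obs)
  }
  if (bayes) {
    return(bayes_glmm_mcmc(df,
      family = "poisson", random_terms = random_terms,
      draws = draws, chains = chains, seed = seed,
      contrasts = contrasts, degenerate = degenerate
    ))
  }
  df$strain <- droplevels(df$strain)
  fe <- if (nlevels(df$strain) > 1L) "score ~ 0 + strain" else "score ~ 1"
  re <- c(day = "(1 | day)", plate = "(1 | obs)")[random_terms]
  conv_issue <- FALSE
  if (length(re) == 0L) {
    fit <- suppress_nonint(
      glm(as.formula(fe), family = poisson(), weights = w, data = df)
    )
    est <- coef(fit)
    V <- vcov(fit)
    vc <- c(sd_day = NA_real_, sd_plate = NA_real_, sd_history = NA_real_)
  } else {
    form <- as.formula(paste(fe, "+", paste(re, collapse = " + ")))
    fit <- withCallingHandlers(
      suppress_nonint(suppressMessages(
        lme4::glmer(form, family = poisson(), weights = w, data = df, nAGQ = 1L)
      )),
      warning = function(w) {
        if (grepl("converge|Hessian|gradient", conditionMessage(w), ignore.case = TRUE)) {
          conv_issue <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    est <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    sd_of <- function(g) {
      i <- match(g, vcs$grp)
      if (is.na(i)) NA_real_ else vcs$sdcor[i]
    }
    vc <- c(sd_day = sd_of("day"), sd_plate = sd_of("obs"), sd_history = NA_real_)
  }
  names(est) <- if (nlevels(df$strain) > 1L) {
    sub("^strain", "", names(est))
  } else {
    levels(df$strain)
  }
  dimnames(V) <- list(names(est), names(est))
  pairs <- contrast_pairs(as.character(df$strain), contrasts)
  tab <- contrast_table(est, V, pairs, df = Inf, adjust = adjust)
  fit_result(
    method = "glmm_poisson",
    fixed_effects = est,
    variance_estimates = vc,
    contrasts = tab,
    intervals = wald_intervals(names(est), est, sqrt(diag(V)), df = Inf, linkinv = exp),
    converged = !conv_issue, degenerate = degenerate,
    log_lik = as.numeric(logLik(fit)), n_params = attr(logLik(fit), "df"),
    param_names = c(paste0("beta:", names(est)), paste0("sd:", random_terms)),
    diagnostics = list(fit = fit)
  )
}

#' Gaussian mixed model on log10-transformed intensities
#'
#' Fluorescence intensity data show variance increasing with the mean; the
#' standard correction is a log10 transform followed by a linear mixed
#' model with random intercepts for assay date (`sD`) and plate (`sP`):
#' \deqn{\log_{10}(intensity) = \beta_s + b^{date}_j + b^{plate}_k + \epsilon}
#' Group means are back-transformed (`10^est`, i.e. geometric means) for
#' reporting. If the mixed fit is degenerate (e.g. zero residual variance
#' in noise-free data) the model falls back to ordinary least squares and
#' is flagged.
#'
#' @param data data.frame with columns `strain_id`, `day_id`, `plate_id`,
#'   `intensity` (strictly positive; floor background-subtracted values
#'   upstream).
#' @param contrasts a [contrast_spec()]; `NULL` means Dunnett vs the first
#'   strain.
#' @param random_terms subset of `c("day", "plate")`.
#' @param adjust apply multivariate-t adjustment.
#' @return A [fit_result] with `method = "lmm_log10"`: fixed effects and
#'   contrasts on the log10 scale, intervals back-transformed to the
#'   intensity scale.
#' @export
fit_lmm_log10 <- function(data, contrasts = NULL,
                          random_terms = c("day", "plate"), adjust = TRUE) {
  need <- c("strain_id", "day_id", "plate_id", "intensity")
  if (!all(need %in% names(data))) {
    hid_abort("intensity data needs strain_id, day_id, plate_id, intensity", "hid_schema_error")
  }
  if (any(data$intensity <= 0)) {
    hid_abort(
      sprintf(
        "non-positive intensity at row(s) %s; floor background-subtracted values upstream",
        paste(which(data$intensity <= 0), collapse = ", ")
      ),
      "hid_validation_error"
    )
  }
  if (length(random_terms)) {
    random_terms <- match.arg(random_terms, c("day", "plate"), several.ok = TRUE)
  }
  if (is.null(contrasts)) {
    contrasts <- contrast_spec("dunnett_vs_control", control = data$strain_id[1])
  }
  df <- data.frame(
    strain = factor(data$strain_id),
    day = factor(data$day_id),
    plate = factor(paste(data$day_id, data$plate_id, sep = ":")),
    y = log10(data$intensity)
  )
  df$strain <- droplevels(df$strain)
  fe <- if (nlevels(df$strain) > 1L) "y ~ 0 + strain" else "y ~ 1"
  re <- c(day = "(1 | day)", plate = "(1 | plate)")[random_terms]
  degenerate <- FALSE
  fit <- NULL
  if (length(re)) {
    form <- as.formula(paste(fe, "+", paste(re, collapse = " + ")))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(lme4::lmer(form, data = df, REML = FALSE))),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    degenerate <- length(re) > 0L
    fit <- lm(as.formula(fe), data = df)
    est <- coef(fit)
    V <- vcov(fit)
    vc <- c(sd_day = NA_real_, sd_plate = NA_real_, sd_history = NA_real_)
    rdf <- fit$df.residual
  } else {
    est <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    sd_of <- function(g) {
      i <- match(g, vcs$grp)
      if (is.na(i)) NA_real_ else vcs$sdcor[i]
    }
    vc <- c(sd_day = sd_of("day"), sd_plate = sd_of("plate"), sd_history = NA_real_)
    rdf <- Inf
  }
  names(est) <- if (nlevels(df$strain) > 1L) {
    sub("^strain", "", names(est))
  } else {
    levels(df$strain)
  }
  dimnames(V) <- list(names(est), names(est))
  pairs <- contrast_pairs(as.character(df$strain), contrasts)
  tab <- contrast_table(est, V, pairs, df = rdf, adjust = adjust)
  fit_result(
    method = "lmm_log10",
    fixed_effects = est,
    variance_estimates = vc,
    contrasts = tab,
    intervals = wald_intervals(names(est), est, sqrt(diag(V)),
      df = rdf, linkinv = function(x) 10^x
    ),
    converged = TRUE, degenerate = degenerate,
    log_lik = as.numeric(logLik(fit)), n_params = attr(logLik(fit), "df"),
    param_names = c(paste0("beta:", names(est)), paste0("sd:", random_terms)),
    diagnostics = list(fit = fit)
  )
}

#' Likelihood-ratio test for nested fits
#'
#' `LRT = 2 (loglik_full - loglik_reduced)`, compared to a chi-square with
#' degrees of freedom equal to the difference in parameter count. By
#' default no boundary correction is applied even when the dropped term is
#' a variance component (the naive chi-square-1 reference); setting
#' `boundary_correction = TRUE` uses the 50:50 mixture of chi-square(df)
#' and chi-square(df - 1), which is conservative-corrected for a single
#' variance parameter on the boundary.
#'
#' @param full,reduced `hid_fit` objects fitted to the same data, the
#'   reduced model's parameters a subset of the full model's.
#' @param boundary_correction use the 50:50 chi-square mixture reference.
#' @param tol tolerance for a negative statistic (indicating the "full"
#'   model found a worse optimum and needs refitting).
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_nested <- function(full, reduced, boundary_correction = FALSE, tol = 1e-6) {
  stopifnot(inherits(full, "hid_fit"), inherits(reduced, "hid_fit"))
  if (!isTRUE(full$converged) || !isTRUE(reduced$converged)) {
    hid_abort("both fits must have converged", "hid_validation_error")
  }
  if (is.na(full$log_lik) || is.na(reduced$log_lik)) {
    hid_abort("both fits must carry a log-likelihood", "hid_validation_error")
  }
  # Nesting check: every random-term sd of the reduced model must appear in
  # the full model. Fixed-effect names are not compared one-to-one, because
  # the standard way to drop a genotype/locus term is to collapse strain
  # labels, which renames the remaining coefficient.
  red_sd <- grep("^sd:", reduced$param_names, value = TRUE)
  if (!all(red_sd %in% full$param_names)) {
    hid_abort("models are not nested (reduced has random terms absent from full)", "hid_nesting_error")
  }
  stat <- 2 * (full$log_lik - reduced$log_lik)
  if (stat < -tol) {
    hid_abort(
      sprintf(
        "full model log-likelihood below reduced (LRT = %.3g); refit with tighter settings",
        stat
      ),
      "hid_refit_error"
    )
  }
  stat <- max(stat, 0)
  df <- full$n_params - reduced$n_params
  if (df < 0) hid_abort("full model has fewer parameters than reduced", "hid_nesting_error")
  p <- if (df == 0L) {
    1
  } else if (boundary_correction) {
    p_hi <- pchisq(stat, df, lower.tail = FALSE)
    p_lo <- if (df > 1L) pchisq(stat, df - 1L, lower.tail = FALSE) else as.numeric(stat <= 0)
    0.5 * (p_hi + p_lo)
  } else {
    pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p = p)
}
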