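#' Run an end-to-end simulate / fit / compare / track pipeline
#'
#' Declarative orchestration of the package's stages with reproducibility
#' plumbing: every stochastic stage receives a sub-seed derived from the
#' root seed, the merged configuration is serialized (and hashed) into the
#' output directory, and a JSON manifest records each stage's status,
#' outputs and seeds. Identical config + seed yields byte-identical
#' deterministic outputs.
#'
#' @param config a named list, or a path to a YAML/JSON file, with
#'   elements:
#'   * `seed` — root seed (default 1).
#'   * `out_dir` — output directory (created if needed).
#'   * `simulate_assays` — optional list of [simulation_scenario()]
#'     arguments plus `variance` (preset name or 3 values).
#'   * `fit` — optional list: `method` (one of the four dauer routes),
#'     `contrasts` (`"dunnett_vs_control"`/`"tukey_all_pairs"`/`"none"`),
#'     `control`, `data` (CSV path; defaults to the simulated dataset),
#'     plus MCMC settings for the Bayesian route.
#'   * `simulate_tracks` — optional list: `n_worms` plus
#'     [track_sim_config()] arguments (`roam_occupancy`, `switch_rate`
#'     build the transition matrix).
#'   * `track_analyze` — optional list of [classifier_config()] arguments.
#'   * `compare` — optional list: `conditions` (list of
#'     [comparison_condition()] argument lists), `methods`, `reps`.
#' @return Invisibly, a list with `status` (0 ok, 2 config error, 3 stage
#'   failure) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  if (is.null(config$out_dir)) {
    hid_abort("config must name an out_dir", "hid_config_error")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg_path <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    root_seed = seed, stages = list()
  )
  status <- 0L
  add_stage <- function(name, fun, stage_seed) {
    res <- tryCatch(fun(), error = function(e) e)
    ok <- !inherits(res, "error")
    if (!ok) {
      writeLines(conditionMessage(res), file.path(out_dir, paste0(name, ".FAILED")))
      status <<- 3L
    }
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "FAILED",
      message = if (ok) NULL else conditionMessage(res),
      seed = stage_seed,
      outputs = if (ok) res else character(0)
    )
    ok
  }

  sim_path <- file.path(out_dir, "assays.csv")
  if (!is.null(config$simulate_assays)) {
    sa <- config$simulate_assays
    sseed <- derive_seed(seed, 1L)
    add_stage("simulate_assays", function() {
      variance <- sa$variance
      vc <- if (is.character(variance)) variance_preset(variance) else do.call(variance_components, as.list(variance))
      sa$variance <- NULL
      gl <- unlist(sa$group_logits)
      sa$group_logits <- NULL
      args <- sa[intersect(names(sa), names(formals(simulation_scenario)))]
      if (!is.null(gl)) args$group_logits <- gl
      ds <- simulate_assay_dataset(do.call(simulation_scenario, args), vc, seed = sseed)
      write_assay_table(ds, sim_path)
      sim_path
    }, sseed)
  }

  if (!is.null(config$fit) && status == 0L) {
    ft <- config$fit
    fseed <- derive_seed(seed, 2L)
    add_stage("fit", function() {
      data_path <- if (!is.null(ft$data)) ft$data else sim_path
      ds <- read_assay_table(data_path, control_strain = ft$control)
      cs <- contrast_spec(
        if (is.null(ft$contrasts)) "dunnett_vs_control" else ft$contrasts,
        control = control_strain(ds)
      )
      method <- if (is.null(ft$method)) "glmm_binomial" else ft$method
      fit <- switch(method,
        welch_t = welch_prop_test(ds, cs),
        anova = anova_prop(ds, cs),
        glmm_binomial = fit_binomial_glmm(ds, contrasts = cs),
        bayes_glmm_binomial = fit_bayes_binomial_glmm(ds,
          contrasts = cs,
          draws = if (is.null(ft$draws)) 1000 else ft$draws,
          chains = if (is.null(ft$chains)) 4 else ft$chains,
          seed = fseed
        ),
        hid_abort(paste("unknown fit method:", method), "hid_config_error")
      )
      out <- file.path(out_dir, paste0("fit_", method, ".csv"))
      write_results(fit, out)
      c(out, paste0(out, ".json"))
    }, fseed)
  }

  tracks_path <- file.path(out_dir, "tracks.csv")
  if (!is.null(config$simulate_tracks) && status == 0L) {
    st <- config$simulate_tracks
    tseed <- derive_seed(seed, 3L)
    add_stage("simulate_tracks", function() {
      tm <- transition_matrix(
        if (is.null(st$roam_occupancy)) 0.5 else st$roam_occupancy,
        if (is.null(st$switch_rate)) 0.01 else st$switch_rate
      )
      args <- st[intersect(names(st), names(formals(track_sim_config)))]
      args$transition <- tm
      cfg <- do.call(track_sim_config, args)
      tracks <- simulate_tracks(cfg, n_worms = if (is.null(st$n_worms)) 5L else st$n_worms, seed = tseed)
      write_track_table(tracks, tracks_path)
      tracks_path
    }, tseed)
  }

  if (!is.null(config$track_analyze) && status == 0L) {
    ta <- config$track_analyze
    add_stage("track_analyze", function() {
      tracks <- read_track_table(if (!is.null(ta$data)) ta$data else tracks_path)
      args <- ta[intersect(names(ta), names(formals(classifier_config)))]
      cc <- do.call(classifier_config, args)
      bins <- analyze_tracks(tracks, cc)
      bins_df <- do.call(rbind, lapply(seq_along(bins), function(i) {
        cbind(worm = attr(bins[[i]], "worm_id"), as.data.frame(bins[[i]]))
      }))
      out <- file.path(out_dir, "track_bins.csv")
      write.csv(bins_df, out, row.names = FALSE)
      fr <- fraction_roaming(bins)
      jsonlite::write_json(
        list(fraction_roaming = fr, n_worms = length(bins)),
        file.path(out_dir, "roaming_summary.json"),
        auto_unbox = TRUE, digits = NA
      )
      c(out, file.path(out_dir, "roaming_summary.json"))
    }, NA_integer_)
  }

  if (!is.null(config$compare) && status == 0L) {
    cp <- config$compare
    cseed <- derive_seed(seed, 4L)
    add_stage("compare", function() {
      conds <- lapply(cp$conditions, function(cc) {
        if (!is.null(cp$reps)) cc$n_reps <- cp$reps
        do.call(comparison_condition, cc)
      })
      methods <- if (is.null(cp$methods)) {
        c("welch_t", "anova", "glmm_binomial", "bayes_glmm_binomial")
      } else {
        unlist(cp$methods)
      }
      res <- run_comparison(conds, methods = methods, seed = cseed)
      out <- file.path(out_dir, "method_comparison.csv")
      write_results(res, out)
      c(out, paste0(out, ".json"))
    }, cseed)
  }

  manifest$outputs_md5 <- as.list(tools::md5sum(
    setdiff(list.files(out_dir, full.names = TRUE), file.path(out_dir, "manifest.json"))
  ))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(status = status, manifest = manifest))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) hid_abort(paste("no such config:", config), "hid_config_error")
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        hid_abort("yaml package required for YAML configs", "hid_config_error")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) hid_abort("config must be a list or file path", "hid_config_error")
  config
}

#' Render a human-readable report from a pipeline manifest
#'
#' @param manifest a manifest list returned by [run_pipeline()], or the
#'   path to a `manifest.json`.
#' @param out_dir where to write `report.md` (defaults next to the
#'   manifest); figures are added when ggplot2 is available.
#' @return The path of the written report, invisibly.
#' @export
render_report <- function(manifest, out_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(out_dir)) out_dir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  if (is.null(out_dir)) hid_abort("out_dir required when manifest is a list", "hid_config_error")
  lines <- c("# Pipeline report", "")
  stages <- manifest$stages
  if (length(stages) == 0L) {
    lines <- c(lines, "_No stages were run._")
  } else {
    for (nm in names(stages)) {
      st <- stages[[nm]]
      lines <- c(lines, sprintf("## %s — %s", nm, st$status))
      if (!is.null(st$message)) lines <- c(lines, "", paste(">", st$message))
      outs <- unlist(st$outputs)
      if (length(outs)) {
        lines <- c(lines, "", paste0("- `", outs, "`"))
      }
      lines <- c(lines, "")
    }
  }
  bins_csv <- file.path(out_dir, "track_bins.csv")
  if (file.exists(bins_csv) && requireNamespace("ggplot2", quietly = TRUE)) {
    bins <- read.csv(bins_csv)
    bins <- bins[!is.na(bins$mean_speed) & !is.na(bins$mean_angular_velocity), ]
    fig <- file.path(out_dir, "roam_dwell.pdf")
    p <- ggplot2::ggplot(bins, ggplot2::aes(
      x = mean_angular_velocity, y = mean_speed,
      colour = label
    )) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::labs(
        x = "angular velocity (deg/frame)", y = "speed (mm/s)",
        colour = NULL
      ) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(fig, p, width = 5, height = 4)
    lines <- c(lines, sprintf("![roam/dwell](%s)", basename(fig)), "")
  }
  report <- file.path(out_dir, "report.md")
  writeLines(lines, report)
  invisible(report)
}
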