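#' Construct an assay dataset of plate-level dauer counts
#'
#' A dauer-formation assay produces clustered binomial data: each plate is a
#' cluster of animals scored as dauer / non-dauer. The dataset is a
#' data.frame with one row per plate and columns `strain_id`, `day_id`,
#' `plate_id`, `n_total`, `n_dauer`, carrying the control strain label as an
#' attribute.
#'
#' @param strain_id,day_id,plate_id character vectors of labels (opaque;
#'   no ordering among days is assumed).
#' @param n_total integer vector, animals scored per plate (>= 1).
#' @param n_dauer integer vector, dauers per plate, `0 <= n_dauer <= n_total`.
#' @param control_strain label of the control group; must occur in
#'   `strain_id`. Defaults to the first strain.
#' @param design_note free-text annotation.
#' @return An object of class `assay_dataset` (a data.frame).
#' @examples
#' ds <- assay_dataset(
#'   strain_id = c("N2", "N2", "rict-1"),
#'   day_id    = c("d1", "d1", "d1"),
#'   plate_id  = c("p1", "p2", "p3"),
#'   n_total   = c(20, 20, 20),
#'   n_dauer   = c(10, 0, 20)
#' )
#' plate_proportions(ds)
#' @export
assay_dataset <- function(strain_id, day_id, plate_id, n_total, n_dauer,
                          control_strain = NULL, design_note = "") {
  df <- data.frame(
    strain_id = as.character(strain_id),
    day_id = as.character(day_id),
    plate_id = as.character(plate_id),
    n_total = as.integer(n_total),
    n_dauer = as.integer(n_dauer),
    stringsAsFactors = FALSE
  )
  validate_assay_dataset(df)
  if (is.null(control_strain)) control_strain <- df$strain_id[1L]
  if (!control_strain %in% df$strain_id) {
    hid_abort(
      sprintf("control strain '%s' not present in dataset", control_strain),
      "hid_validation_error"
    )
  }
  structure(df,
    control_strain = control_strain,
    design_note = design_note,
    class = c("assay_dataset", "data.frame")
  )
}

validate_assay_dataset <- function(df) {
  if (nrow(df) == 0L) hid_abort("assay dataset has no rows", "hid_empty_input_error")
  bad <- which(df$n_total < 1L)
  if (length(bad)) {
    hid_abort(
      sprintf("n_total < 1 at row(s) %s", paste(bad, collapse = ", ")),
      "hid_validation_error"
    )
  }
  bad <- which(df$n_dauer < 0L | df$n_dauer > df$n_total)
  if (length(bad)) {
    hid_abort(
      sprintf(
        "n_dauer outside [0, n_total] at row(s) %s",
        paste(bad, collapse = ", ")
      ),
      "hid_validation_error"
    )
  }
  key <- paste(df$day_id, df$plate_id, sep = "\r")
  if (anyDuplicated(key)) {
    hid_abort(
      sprintf(
        "duplicated (day_id, plate_id) pair at row(s) %s",
        paste(which(duplicated(key)), collapse = ", ")
      ),
      "hid_validation_error"
    )
  }
  invisible(df)
}

#' @rdname assay_dataset
#' @param x an `assay_dataset`.
#' @return `plate_proportions()`: numeric vector of per-plate dauer proportions.
#' @export
plate_proportions <- function(x) x$n_dauer / x$n_total

#' @rdname assay_dataset
#' @export
control_strain <- function(x) attr(x, "control_strain")

#' @export
print.assay_dataset <- function(x, ...) {
  cat(sprintf(
    "Dauer assay dataset: %d plates, %d strains, %d days (control: %s)\n",
    nrow(x), length(unique(x$strain_id)), length(unique(x$day_id)),
    control_strain(x)
  ))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more plates\n", nrow(x) - 10L))
  invisible(x)
}

#' Read / write plate-level assay tables
#'
#' CSV schema: one row per plate with columns `strain`, `day`, `plate`,
#' `n_total`, `n_dauer` (header required, UTF-8, "." decimal separator).
#' Column names can be remapped via `format_spec`.
#'
#' @param path path to a CSV file.
#' @param format_spec optional named list remapping column names, e.g.
#'   `list(strain = "genotype", n_dauer = "dauers")`. Unlisted columns keep
#'   their default names.
#' @param control_strain,design_note passed to [assay_dataset()].
#' @return [read_assay_table()]: an `assay_dataset` with row order preserved.
#' @export
read_assay_table <- function(path, format_spec = NULL, control_strain = NULL,
                             design_note = "") {
  if (!file.exists(path)) hid_abort(paste("no such file:", path), "hid_io_error")
  if (file.size(path) == 0L) hid_abort("empty input file", "hid_empty_input_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) hid_abort("input file has a header but no rows", "hid_empty_input_error")
  cols <- list(
    strain = "strain", day = "day", plate = "plate",
    n_total = "n_total", n_dauer = "n_dauer"
  )
  if (!is.null(format_spec)) cols[names(format_spec)] <- format_spec
  missing <- vapply(cols, function(cn) !cn %in% names(df), logical(1))
  if (any(missing)) {
    hid_abort(
      sprintf(
        "missing required column(s): %s",
        paste(unlist(cols[missing]), collapse = ", ")
      ),
      "hid_schema_error"
    )
  }
  assay_dataset(
    strain_id = df[[cols$strain]],
    day_id = df[[cols$day]],
    plate_id = df[[cols$plate]],
    n_total = df[[cols$n_total]],
    n_dauer = df[[cols$n_dauer]],
    control_strain = control_strain,
    design_note = design_note
  )
}

#' @rdname read_assay_table
#' @param data an `assay_dataset`.
#' @export
write_assay_table <- function(data, path) {
  out <- data.frame(
    strain = data$strain_id, day = data$day_id, plate = data$plate_id,
    n_total = data$n_total, n_dauer = data$n_dauer
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write grid-entry exploration count tables
#'
#' CSV schema: `strain`, `day`, `worm`, `score` — one row per assayed worm,
#' `score` the capped total number of grid-square entries.
#'
#' @param path path to a CSV file.
#' @return data.frame with columns `strain_id`, `day_id`, `worm_id`, `score`.
#' @export
read_grid_table <- function(path) {
  if (!file.exists(path)) hid_abort(paste("no such file:", path), "hid_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "day", "worm", "score")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    hid_abort(
      paste("missing required column(s):", paste(missing, collapse = ", ")),
      "hid_schema_error"
    )
  }
  if (any(df$score < 0)) hid_abort("negative score", "hid_validation_error")
  data.frame(
    strain_id = as.character(df$strain), day_id = as.character(df$day),
    worm_id = as.character(df$worm), score = as.integer(df$score),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_grid_table
#' @param data grid-count data.frame as returned by [read_grid_table()] or
#'   [simulate_grid_counts()].
#' @export
write_grid_table <- function(data, path) {
  out <- data.frame(
    strain = data$strain_id, day = data$day_id,
    worm = data$worm_id, score = data$score
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a fit or method-comparison result
#'
#' Writes a flat CSV (one contrast, or one condition-method pair, per row)
#' plus a JSON sidecar (`<path>.json`) with complete metadata — method,
#' seed, fixed effects, variance estimates — at full floating-point
#' precision, so that re-reading reproduces every numeric field exactly.
#'
#' @param result a `hid_fit` (see [fit_result]) or `hid_method_comparison`
#'   object.
#' @param path output CSV path; the sidecar is written next to it.
#' @return invisibly, a list with elements `csv` and `json`.
#' @export
write_results <- function(result, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) hid_abort(paste("no such directory:", dir), "hid_io_error")
  if (inherits(result, "hid_fit")) {
    tab <- result$contrasts
    meta <- list(
      kind = "fit", method = result$method, seed = result$seed,
      converged = result$converged, degenerate = result$degenerate,
      fixed_effects = as.list(result$fixed_effects),
      variance_estimates = as.list(result$variance_estimates),
      log_lik = result$log_lik, n_params = result$n_params,
      contrasts = lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ])),
      intervals = if (!is.null(result$intervals)) {
        lapply(seq_len(nrow(result$intervals)), function(i) {
          as.list(result$intervals[i, ])
        })
      }
    )
  } else if (inherits(result, "hid_method_comparison")) {
    tab <- result$rates
    meta <- list(
      kind = "method_comparison", seed = result$seed, alpha = result$alpha,
      n_conditions = length(result$conditions),
      rates = lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
    )
  } else {
    hid_abort("unsupported result type", "hid_validation_error")
  }
  write.csv(tab, path, row.names = FALSE)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(meta, json_path,
    auto_unbox = TRUE, digits = NA, null = "null", always_decimal = FALSE
  )
  invisible(list(csv = path, json = json_path))
}

#' @rdname write_results
#' @return [read_results()]: list with elements `table` (the CSV) and
#'   `meta` (the parsed JSON sidecar).
#' @export
read_results <- function(path) {
  list(
    table = read.csv(path, stringsAsFactors = FALSE),
    meta = jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  )
}
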