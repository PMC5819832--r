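#' Logit-scale variance components of a dauer assay
#'
#' Plate-clustered dauer data carry (at least) three extra-binomial sources
#' of variance, all on the log-odds scale: day-to-day variance `sD`
#' (a shared shift of every plate run on the same day), plate-to-plate
#' variance `sP` (independent per plate), and strain culture-history
#' variance `sG` (a strain-by-day effect: independently cultured strains can
#' move in different directions on the same day).
#'
#' @param sd_day,sd_plate,sd_history non-negative standard deviations on the
#'   logit scale (`sD`, `sP`, `sG`).
#' @return A named numeric vector of class `variance_components`.
#' @seealso [variance_preset()] for the low/high presets used in the
#'   method-comparison study.
#' @export
variance_components <- function(sd_day = 0, sd_plate = 0, sd_history = 0) {
  v <- c(sd_day = sd_day, sd_plate = sd_plate, sd_history = sd_history)
  if (any(!is.finite(v)) || any(v < 0)) {
    hid_abort("variance components must be finite and >= 0", "hid_config_error")
  }
  structure(v, class = c("variance_components", "numeric"))
}

#' @rdname variance_components
#' @param name `"low"`, `"high"`, or `"none"`. The low preset is
#'   (0.25, 0.25, 0.25) and the high preset (1.0, 0.5, 0.5): values chosen
#'   so that, with high day and history variance, analyses that ignore
#'   clustering show visibly inflated type-I error while the day-to-day
#'   component dominates the plate component, as observed in wild-type
#'   dauer assay collections.
#' @export
variance_preset <- function(name = c("low", "high", "none")) {
  name <- match.arg(name)
  switch(name,
    none = variance_components(0, 0, 0),
    low = variance_components(0.25, 0.25, 0.25),
    high = variance_components(1.0, 0.5, 0.5)
  )
}

#' Define a dauer-assay simulation scenario
#'
#' A scenario fixes the experimental design the generator emulates: group
#' log-odds of dauer formation, the number of assay days, plates per group,
#' whether the design is balanced across days, the fraction of days whose
#' control means carry a shared systematic bias, and animals scored per
#' plate.
#'
#' The default design matches the simulation layout used for the
#' method-comparison study: three groups (a control and two test
#' genotypes), 6 plates per group collected over 3 days, with the test
#' effect expressed as a shift of 1 on the log-odds scale.
#'
#' @param group_logits named numeric vector of per-strain log-odds; the
#'   first element is the control.
#' @param n_days number of assay days.
#' @param plates_per_group plates per strain (divisible by `n_days` when
#'   `balanced = TRUE`).
#' @param balanced if `TRUE` every strain contributes
#'   `plates_per_group / n_days` plates per day. If `FALSE`, the control is
#'   assayed on every day but each test group is absent on one day (cycling
#'   through days), its plates reallocated evenly to the days it is present.
#' @param bias_fraction fraction of days (rounded up) on which the control
#'   group's day effect receives an additional shared offset of
#'   `bias_magnitude * sd_day`, emulating systematic day-correlated bias in
#'   the control samples.
#' @param bias_magnitude offset applied on bias days, in units of `sd_day`.
#' @param animals_per_plate scalar count, or length-2 vector `c(lo, hi)`
#'   from which per-plate counts are drawn uniformly.
#' @return A list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(group_logits = c(control = 0, mutantA = 1, mutantB = 0),
                                n_days = 3,
                                plates_per_group = 6,
                                balanced = TRUE,
                                bias_fraction = 0,
                                bias_magnitude = 1,
                                animals_per_plate = 50) {
  if (length(group_logits) < 1L) hid_abort("at least one group required", "hid_config_error")
  if (is.null(names(group_logits)) || any(!nzchar(names(group_logits)))) {
    hid_abort("group_logits must be a named vector", "hid_config_error")
  }
  if (balanced && plates_per_group %% n_days != 0) {
    hid_abort(
      "plates_per_group must be divisible by n_days in a balanced design",
      "hid_config_error"
    )
  }
  if (bias_fraction < 0 || bias_fraction > 1) {
    hid_abort("bias_fraction must lie in [0, 1]", "hid_config_error")
  }
  if (!length(animals_per_plate) %in% c(1L, 2L) || any(animals_per_plate < 1)) {
    hid_abort("animals_per_plate must be a positive scalar or c(lo, hi)", "hid_config_error")
  }
  structure(
    list(
      group_logits = group_logits, n_days = as.integer(n_days),
      plates_per_group = as.integer(plates_per_group), balanced = balanced,
      bias_fraction = bias_fraction, bias_magnitude = bias_magnitude,
      animals_per_plate = animals_per_plate
    ),
    class = "simulation_scenario"
  )
}

# Allocate plates of each strain to days. Unbalanced rule: control on all
# days; test group k skips day ((k - 1) mod n_days) + 1 and its plates are
# spread as evenly as possible over the remaining days.
allocate_plates <- function(scenario) {
  strains <- names(scenario$group_logits)
  n_days <- scenario$n_days
  ppg <- scenario$plates_per_group
  alloc <- list()
  for (k in seq_along(strains)) {
    if (scenario$balanced || k == 1L || n_days == 1L) {
      days <- rep(seq_len(n_days), each = ppg / n_days)
      if (length(days) < ppg) { # unbalanced total not divisible: round-robin
        days <- sort(rep_len(seq_len(n_days), ppg))
      }
    } else {
      skip <- ((k - 2L) %% n_days) + 1L
      present <- setdiff(seq_len(n_days), skip)
      days <- sort(rep_len(present, ppg))
    }
    alloc[[strains[k]]] <- days[seq_len(ppg)]
  }
  alloc
}

#' Simulate a plate-clustered binomial dauer assay dataset
#'
#' For plate i of strain s on day j the dauer count is drawn as
#' \deqn{n_{dauer} \sim Binomial(n_{total},\ logistic(\beta_s + d_j + g_{sj} + e_{ij}))}
#' with day effects \eqn{d_j \sim N(0, sD^2)} shared by all strains assayed
#' on day j, culture-history effects \eqn{g_{sj} \sim N(0, sG^2)} drawn
#' independently per strain-by-day cell, and plate effects
#' \eqn{e_{ij} \sim N(0, sP^2)}. Under a systematic-bias condition the
#' control group's day effect is additionally shifted by
#' `bias_magnitude * sd_day` on `ceiling(bias_fraction * n_days)` randomly
#' chosen days (the bias is applied to the control only, so that control and
#' test groups disagree systematically on those days).
#'
#' The generator is deterministic given `seed` and restores the caller's
#' RNG state.
#'
#' @param scenario a [simulation_scenario()].
#' @param variance a [variance_components()] object.
#' @param seed integer seed.
#' @return An `assay_dataset` whose `truth` attribute records the group
#'   logits, realized day/history/plate effects, bias days, scenario,
#'   variance components and seed.
#' @examples
#' ds <- simulate_assay_dataset(
#'   simulation_scenario(),
#'   variance_preset("low"),
#'   seed = 1
#' )
#' aggregate(plate_proportions(ds), list(strain = ds$strain_id), mean)
#' @export
simulate_assay_dataset <- function(scenario = simulation_scenario(),
                                   variance = variance_components(),
                                   seed = 1L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  variance <- as_variance_components(variance)
  strains <- names(scenario$group_logits)
  with_seed(seed, {
    alloc <- allocate_plates(scenario)
    n_days <- scenario$n_days
    d <- rnorm(n_days, 0, variance[["sd_day"]])
    n_bias <- ceiling(scenario$bias_fraction * n_days)
    bias_days <- if (n_bias > 0) sort(sample.int(n_days, n_bias)) else integer(0)
    bias_offset <- scenario$bias_magnitude * variance[["sd_day"]]
    g <- matrix(
      rnorm(length(strains) * n_days, 0, variance[["sd_history"]]),
      nrow = length(strains), ncol = n_days,
      dimnames = list(strains, NULL)
    )
    rows <- vector("list", length(strains))
    plate_counter <- 0L
    for (s in seq_along(strains)) {
      days <- alloc[[strains[s]]]
      np <- length(days)
      e <- rnorm(np, 0, variance[["sd_plate"]])
      n_tot <- if (length(scenario$animals_per_plate) == 1L) {
        rep(as.integer(scenario$animals_per_plate), np)
      } else {
        sample(
          seq(scenario$animals_per_plate[1], scenario$animals_per_plate[2]),
          np,
          replace = TRUE
        )
      }
      bias_s <- if (s == 1L) bias_offset * (days %in% bias_days) else 0
      eta <- scenario$group_logits[s] + d[days] + g[s, days] + e + bias_s
      y <- rbinom(np, n_tot, plogis(eta))
      rows[[s]] <- data.frame(
        strain_id = strains[s],
        day_id = paste0("day", days),
        plate_id = paste0("plate", plate_counter + seq_len(np)),
        n_total = n_tot, n_dauer = y,
        stringsAsFactors = FALSE
      )
      plate_counter <- plate_counter + np
    }
    df <- do.call(rbind, rows)
    ds <- assay_dataset(df$strain_id, df$day_id, df$plate_id,
      df$n_total, df$n_dauer,
      control_strain = strains[1L],
      design_note = sprintf(
        "simulated: %d groups x %d plates over %d days%s",
        length(strains), scenario$plates_per_group, n_days,
        if (scenario$balanced) ", balanced" else ", unbalanced"
      )
    )
    attr(ds, "truth") <- list(
      group_logits = scenario$group_logits, day_effects = d,
      history_effects = g, bias_days = bias_days,
      bias_offset = bias_offset, scenario = scenario,
      variance = variance, seed = seed
    )
    ds
  })
}

as_variance_components <- function(x) {
  if (inherits(x, "variance_components")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    return(variance_components(x[[1]], x[[2]], x[[3]]))
  }
  hid_abort("expected a variance_components object or length-3 numeric", "hid_config_error")
}
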