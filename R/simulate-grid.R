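#' Simulate overdispersed grid-entry exploration counts
#'
#' Per worm i of strain s assayed on day j, the capped grid-entry score is
#' drawn as
#' \deqn{score \sim Poisson(\exp(\log \lambda_s + d_j + e_{ij}))}
#' with a shared day effect \eqn{d_j \sim N(0, sD^2)} (all strains assayed
#' on day j move together) and a per-worm plate effect
#' \eqn{e_{ij} \sim N(0, sP^2)} — each foraging plate holds one worm, so
#' plate and worm coincide. Draws are truncated at `cap_total`, the maximum
#' attainable score (grid cells times the per-cell entry cap; 188 x 10 by
#' default).
#'
#' @param rates named vector of per-strain mean entry rates (> 0); first
#'   name is the control.
#' @param variance a [variance_components()]; `sd_history` is unused here.
#' @param n_worms_per_day worms per strain per day.
#' @param n_days number of assay days.
#' @param seed integer seed.
#' @param cap_total truncation bound on the score.
#' @return data.frame with columns `strain_id`, `day_id`, `worm_id`,
#'   `score`, suitable for [fit_poisson_glmm()]; the `truth` attribute
#'   records rates, realized day effects and the seed.
#' @export
simulate_grid_counts <- function(rates, variance = variance_components(),
                                 n_worms_per_day = 5L, n_days = 3L,
                                 seed = 1L, cap_total = 188L * 10L) {
  if (any(rates <= 0)) hid_abort("rates must be > 0", "hid_config_error")
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    hid_abort("rates must be a named vector", "hid_config_error")
  }
  variance <- as_variance_components(variance)
  strains <- names(rates)
  with_seed(seed, {
    d <- rnorm(n_days, 0, variance[["sd_day"]])
    out <- vector("list", length(strains) * n_days)
    k <- 0L
    worm_counter <- 0L
    for (j in seq_len(n_days)) {
      for (s in strains) {
        e <- rnorm(n_worms_per_day, 0, variance[["sd_plate"]])
        lambda <- exp(log(rates[[s]]) + d[j] + e)
        score <- pmin(rpois(n_worms_per_day, lambda), cap_total)
        k <- k + 1L
        out[[k]] <- data.frame(
          strain_id = s, day_id = paste0("day", j),
          worm_id = paste0("worm", worm_counter + seq_len(n_worms_per_day)),
          score = score, stringsAsFactors = FALSE
        )
        worm_counter <- worm_counter + n_worms_per_day
      }
    }
    res <- do.call(rbind, out)
    attr(res, "truth") <- list(
      rates = rates, day_effects = d, variance = variance, seed = seed
    )
    res
  })
}
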