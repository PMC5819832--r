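#' Configure the two-state locomotion track generator
#'
#' Synthetic worm tracks follow a two-state (roaming / dwelling) hidden
#' Markov model at the frame level: the state evolves by a 2x2 transition
#' matrix per frame; the heading changes by a Normal(0, state turn-sd)
#' angle; the step length is the state's speed draw divided by the frame
#' rate; positions are reflected radially at a circular arena boundary.
#' Defaults mirror the live-tracking assay: 3 frames per second for 90
#' minutes (5400 s) on a 3.5 cm plate, with roaming fast and straight
#' (high speed, low turning) and dwelling slow and tortuous.
#'
#' @param fps frames per second.
#' @param duration_s recording duration in seconds; a track has
#'   `floor(fps * duration_s)` frames.
#' @param transition 2x2 row-stochastic matrix, rows/cols ordered
#'   (roam, dwell); see [transition_matrix()].
#' @param roam_speed,dwell_speed length-2 `c(mean, sd)` of per-frame speed
#'   draws in mm/s (truncated at 0).
#' @param roam_turn_sd,dwell_turn_sd per-frame heading-change sd, degrees.
#' @param arena_radius_mm radius of the circular arena.
#' @return A list of class `track_sim_config`.
#' @export
track_sim_config <- function(fps = 3, duration_s = 5400,
                             transition = transition_matrix(),
                             roam_speed = c(0.15, 0.03),
                             dwell_speed = c(0.02, 0.01),
                             roam_turn_sd = 10, dwell_turn_sd = 50,
                             arena_radius_mm = 17.5) {
  if (fps <= 0 || duration_s <= 0) hid_abort("fps and duration must be > 0", "hid_config_error")
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(2L, 2L)) || any(transition < 0) ||
    any(abs(rowSums(transition) - 1) > 1e-8)) {
    hid_abort("transition must be a 2x2 row-stochastic matrix", "hid_config_error")
  }
  if (any(c(roam_speed[1], dwell_speed[1]) < 0) ||
    any(c(roam_speed[2], dwell_speed[2]) < 0)) {
    hid_abort("speeds must be >= 0", "hid_config_error")
  }
  structure(
    list(
      fps = fps, duration_s = duration_s, transition = transition,
      roam_speed = roam_speed, dwell_speed = dwell_speed,
      roam_turn_sd = roam_turn_sd, dwell_turn_sd = dwell_turn_sd,
      arena_radius_mm = arena_radius_mm
    ),
    class = "track_sim_config"
  )
}

#' @rdname track_sim_config
#' @param roam_occupancy stationary probability of the roaming state.
#' @param switch_rate total per-frame switching intensity
#'   (`P(roam->dwell) + P(dwell->roam)`); small values give long state
#'   episodes.
#' @return [transition_matrix()]: a 2x2 row-stochastic matrix with the
#'   requested stationary roaming occupancy.
#' @export
transition_matrix <- function(roam_occupancy = 0.5, switch_rate = 0.01) {
  if (roam_occupancy <= 0 || roam_occupancy >= 1) {
    hid_abort("roam_occupancy must lie in (0, 1)", "hid_config_error")
  }
  p_rd <- switch_rate * (1 - roam_occupancy) # roam -> dwell
  p_dr <- switch_rate * roam_occupancy # dwell -> roam
  matrix(c(1 - p_rd, p_rd, p_dr, 1 - p_dr),
    2, 2,
    byrow = TRUE, dimnames = list(c("roam", "dwell"), c("roam", "dwell"))
  )
}

#' Simulate two-state worm locomotion tracks
#'
#' @param config a [track_sim_config()].
#' @param n_worms number of independent tracks.
#' @param seed integer seed; one sub-stream per worm, so track k is
#'   reproducible in isolation.
#' @return A list of `worm_track` data.frames with columns `t_s`, `x_mm`,
#'   `y_mm`, `true_state` (`"roam"`/`"dwell"`, the hidden ground truth) and
#'   attributes `worm_id` and `fps`. Frame count is
#'   `floor(fps * duration_s)`; positions never leave the arena.
#' @export
simulate_tracks <- function(config = track_sim_config(), n_worms = 1L, seed = 1L) {
  stopifnot(inherits(config, "track_sim_config"))
  lapply(seq_len(n_worms), function(w) {
    with_seed(derive_seed(seed, w), simulate_one_track(config, paste0("worm", w)))
  })
}

simulate_one_track <- function(cfg, worm_id) {
  n <- floor(cfg$fps * cfg$duration_s)
  R <- cfg$arena_radius_mm
  P <- cfg$transition
  # stationary start state
  pi_roam <- P[2, 1] / (P[1, 2] + P[2, 1])
  if (!is.finite(pi_roam)) pi_roam <- 0.5 # absorbing matrix: arbitrary start
  state <- integer(n) # 1 = roam, 2 = dwell
  u <- runif(n)
  state[1] <- if (u[1] < pi_roam) 1L else 2L
  stay <- c(P[1, 1], P[2, 2])
  for (i in 2:n) {
    s <- state[i - 1]
    state[i] <- if (u[i] < stay[s]) s else 3L - s
  }
  turn_sd <- c(cfg$roam_turn_sd, cfg$dwell_turn_sd)[state]
  sp_mean <- c(cfg$roam_speed[1], cfg$dwell_speed[1])[state]
  sp_sd <- c(cfg$roam_speed[2], cfg$dwell_speed[2])[state]
  turns <- rnorm(n, 0, turn_sd) * pi / 180
  speeds <- pmax(0, rnorm(n, sp_mean, sp_sd))
  heading <- runif(1, 0, 2 * pi) + cumsum(turns)
  step <- speeds / cfg$fps
  dx <- step * cos(heading)
  dy <- step * sin(heading)
  x <- numeric(n)
  y <- numeric(n)
  # start well inside the arena
  r0 <- R * 0.5 * sqrt(runif(1))
  a0 <- runif(1, 0, 2 * pi)
  x[1] <- r0 * cos(a0)
  y[1] <- r0 * sin(a0)
  for (i in 2:n) {
    xi <- x[i - 1] + dx[i]
    yi <- y[i - 1] + dy[i]
    r <- sqrt(xi^2 + yi^2)
    if (r > R) { # radial fold back inside
      f <- (2 * R - r) / r
      if (f < 0) f <- 0
      xi <- xi * f
      yi <- yi * f
    }
    x[i] <- xi
    y[i] <- yi
  }
  tr <- data.frame(
    t_s = (seq_len(n) - 1) / cfg$fps, x_mm = x, y_mm = y,
    true_state = c("roam", "dwell")[state], stringsAsFactors = FALSE
  )
  structure(tr,
    worm_id = worm_id, fps = cfg$fps,
    class = c("worm_track", "data.frame")
  )
}

#' Read / write locomotion track tables
#'
#' CSV schema: `worm`, `frame`, `t_s`, `x_mm`, `y_mm` and optionally
#' `true_state` (synthetic tracks only).
#'
#' @param tracks list of `worm_track` objects.
#' @param path CSV path.
#' @export
write_track_table <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(
      worm = attr(tr, "worm_id"), frame = seq_len(nrow(tr)),
      t_s = tr$t_s, x_mm = tr$x_mm, y_mm = tr$y_mm,
      true_state = if ("true_state" %in% names(tr)) tr$true_state else NA,
      stringsAsFactors = FALSE
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_table
#' @param fps frame rate to attach; if `NULL`, inferred from median frame
#'   spacing.
#' @return [read_track_table()]: a list of `worm_track` objects.
#' @export
read_track_table <- function(path, fps = NULL) {
  if (!file.exists(path)) hid_abort(paste("no such file:", path), "hid_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("worm", "t_s", "x_mm", "y_mm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    hid_abort(
      paste("missing required column(s):", paste(missing, collapse = ", ")),
      "hid_schema_error"
    )
  }
  lapply(split(df, df$worm), function(d) {
    d <- d[order(d$t_s), ]
    f <- if (is.null(fps)) 1 / stats::median(diff(d$t_s)) else fps
    tr <- data.frame(
      t_s = d$t_s, x_mm = d$x_mm, y_mm = d$y_mm,
      stringsAsFactors = FALSE
    )
    if ("true_state" %in% names(d) && !all(is.na(d$true_state))) {
      tr$true_state <- d$true_state
    }
    structure(tr,
      worm_id = as.character(d$worm[1]), fps = f,
      class = c("worm_track", "data.frame")
    )
  })
}
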