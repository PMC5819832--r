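#' Construct a worm track from timestamped positions
#'
#' @param df data.frame with columns `t_s`, `x_mm`, `y_mm` (and optionally
#'   `true_state` for synthetic tracks).
#' @param fps nominal frame rate; frame spacing must match `1/fps` within
#'   10% jitter.
#' @param worm_id label.
#' @return A `worm_track` object.
#' @export
as_track <- function(df, fps, worm_id = "worm1") {
  need <- c("t_s", "x_mm", "y_mm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    hid_abort(
      paste("missing track column(s):", paste(missing, collapse = ", ")),
      "hid_schema_error"
    )
  }
  dt <- diff(df$t_s)
  if (any(dt <= 0)) hid_abort("timestamps must be strictly increasing", "hid_validation_error")
  if (any(abs(dt - 1 / fps) > 0.1 / fps)) {
    hid_abort("frame spacing deviates from 1/fps by more than 10%", "hid_validation_error")
  }
  structure(as.data.frame(df),
    worm_id = worm_id, fps = fps,
    class = c("worm_track", "data.frame")
  )
}

#' Per-frame speed of a track
#'
#' Euclidean step length divided by the frame interval; `speed[i]` is the
#' speed of the displacement into frame `i` (defined for frames 2..n, with
#' `NA` at frame 1).
#'
#' @param track a `worm_track`.
#' @return Numeric vector of length `nrow(track)`, mm/s.
#' @export
track_speed <- function(track) {
  if (nrow(track) < 2L) hid_abort("speed needs >= 2 frames", "hid_validation_error")
  dt <- diff(track$t_s)
  if (any(dt == 0)) hid_abort("duplicated timestamps", "hid_validation_error")
  d <- sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2)
  c(NA_real_, d / dt)
}

#' Three-frame angular velocity of a track
#'
#' For each interior frame, take the two displacement vectors `v12` (frame
#' i-1 to i) and `v23` (frame i to i+1); the turn is
#' `acos(v12 . v23 / (|v12| |v23|))` converted to degrees — the normalized
#' dot product gives the cosine of the angle between successive headings,
#' and expressing the result in degrees per frame takes the arccosine. The
#' cosine is clamped to `[-1, 1]` against rounding; frames where either
#' displacement is below `min_speed / fps` (effectively stationary) have
#' undefined turn angle and return `NA`. The raw cosines are attached as
#' attribute `"cosine"` for audit.
#'
#' @param track a `worm_track` (>= 3 frames).
#' @param min_speed_mm_s stationary-speed threshold.
#' @return Numeric vector of length `nrow(track)` in degrees, `[0, 180]`,
#'   with `NA` at the first and last frame and at stationary frames.
#' @examples
#' tr <- as_track(
#'   data.frame(t_s = 0:2, x_mm = c(0, 1, 1), y_mm = c(0, 0, 1)),
#'   fps = 1
#' )
#' angular_velocity(tr) # 90 degrees at the interior frame
#' @export
angular_velocity <- function(track, min_speed_mm_s = 1e-4) {
  n <- nrow(track)
  if (n < 3L) hid_abort("angular velocity needs >= 3 frames", "hid_validation_error")
  dx <- diff(track$x_mm)
  dy <- diff(track$y_mm)
  dt <- diff(track$t_s)
  nrm <- sqrt(dx^2 + dy^2)
  # v12 = displacement i-1 -> i, v23 = displacement i -> i+1
  dot <- dx[-(n - 1)] * dx[-1] + dy[-(n - 1)] * dy[-1]
  denom <- nrm[-(n - 1)] * nrm[-1]
  cosv <- pmin(1, pmax(-1, dot / denom))
  min_step <- min_speed_mm_s * dt
  still <- nrm < min_step
  undefined <- still[-(n - 1)] | still[-1]
  ang <- acos(cosv) * 180 / pi
  ang[undefined] <- NA_real_
  cosv[undefined] <- NA_real_
  out <- c(NA_real_, ang, NA_real_)
  attr(out, "cosine") <- c(NA_real_, cosv, NA_real_)
  out
}

#' Roaming/dwelling classifier settings
#'
#' The roaming/dwelling partition is a line of slope `slope` through the
#' origin of the (angular velocity, speed) plane: bins whose mean speed
#' (times `speed_scale`) exceeds `slope` times their mean angular velocity
#' (times `angvel_scale`) are roaming, bins below are dwelling. Because
#' the plane's axis units are an assay convention rather than a physical
#' constant, `speed_scale` rescales mm/s into the working unit of the
#' partition; with the default synthetic state parameters,
#' `speed_scale = 1000` (speed in micrometers/s against degrees/frame)
#' places the slope-2 line cleanly between the two behavioral clusters.
#'
#' @param slope boundary slope (> 0).
#' @param bin_seconds bin width in seconds.
#' @param min_speed_mm_s stationary threshold passed to
#'   [angular_velocity()].
#' @param boundary_rule label for bins exactly on the line.
#' @param speed_scale,angvel_scale unit multipliers applied before the
#'   comparison.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(slope = 2, bin_seconds = 10,
                              min_speed_mm_s = 1e-4,
                              boundary_rule = c("dwell_on_line", "roam_on_line"),
                              speed_scale = 1, angvel_scale = 1) {
  if (slope <= 0 || bin_seconds <= 0) {
    hid_abort("slope and bin_seconds must be > 0", "hid_config_error")
  }
  structure(
    list(
      slope = slope, bin_seconds = bin_seconds,
      min_speed_mm_s = min_speed_mm_s,
      boundary_rule = match.arg(boundary_rule),
      speed_scale = speed_scale, angvel_scale = angvel_scale
    ),
    class = "classifier_config"
  )
}

#' Summarize a track into fixed-width time bins
#'
#' Non-overlapping consecutive bins of `bin_seconds`; per bin, the
#' arithmetic mean of the defined per-frame speeds and angular velocities.
#' A trailing partial bin is dropped; a bin with more than 50% undefined
#' angular-velocity frames is labeled `"undefined"`.
#'
#' @param track a `worm_track`.
#' @param config a [classifier_config()].
#' @return data.frame of class `track_bins`: `t_start`, `mean_speed`
#'   (mm/s), `mean_angular_velocity` (degrees/frame), `n_frames`, `label`
#'   (`"undefined"` or `NA` before classification), and, for synthetic
#'   tracks, `true_label` (majority hidden state in the bin).
#' @export
bin_track <- function(track, config = classifier_config()) {
  fps <- attr(track, "fps")
  m <- round(config$bin_seconds * fps)
  n <- nrow(track)
  if (n < m) hid_abort("track shorter than one bin", "hid_validation_error")
  n_bins <- floor(n / m)
  sp <- track_speed(track)
  av <- angular_velocity(track, config$min_speed_mm_s)
  has_truth <- "true_state" %in% names(track)
  idx <- rep(seq_len(n_bins), each = m)
  keep <- seq_len(n_bins * m)
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  # the undefined fraction is judged over interior frames only (angular
  # velocity does not exist at the first and last frame of the track)
  interior <- keep > 1L & keep < n
  frac_undef <- vapply(seq_len(n_bins), function(b) {
    i <- keep[idx == b & interior]
    if (!length(i)) return(1)
    mean(is.na(av[i]))
  }, numeric(1))
  out <- data.frame(
    t_start = track$t_s[seq(1, n_bins * m, by = m)],
    mean_speed = tapply(sp[keep], idx, mean_na),
    mean_angular_velocity = tapply(av[keep], idx, mean_na),
    n_frames = m,
    frac_undefined = frac_undef,
    stringsAsFactors = FALSE
  )
  out$label <- ifelse(out$frac_undefined > 0.5, "undefined", NA_character_)
  if (has_truth) {
    out$true_label <- tapply(track$true_state[keep], idx, function(s) {
      names(sort(table(s), decreasing = TRUE))[1]
    })
  }
  rownames(out) <- NULL
  structure(out, fps = fps, worm_id = attr(track, "worm_id"),
    class = c("track_bins", "data.frame")
  )
}

#' Classify time bins as roaming or dwelling
#'
#' A bin is roaming when
#' `speed_scale * mean_speed > slope * angvel_scale * mean_angular_velocity`
#' (points above the slope line); on-the-line bins follow `boundary_rule`
#' (dwelling by default); `"undefined"` bins keep their label.
#'
#' @param bins a `track_bins` data.frame from [bin_track()].
#' @param config a [classifier_config()].
#' @return `bins` with `label` filled in as `"roam"` / `"dwell"` /
#'   `"undefined"`.
#' @export
classify_bins <- function(bins, config = classifier_config()) {
  s <- config$speed_scale * bins$mean_speed
  a <- config$angvel_scale * bins$mean_angular_velocity
  thr <- config$slope * a
  lab <- ifelse(s > thr, "roam", "dwell")
  if (config$boundary_rule == "roam_on_line") {
    lab[s == thr] <- "roam"
  } # else equality already falls to "dwell"
  lab[is.na(s) | is.na(a)] <- "undefined"
  lab[!is.na(bins$label) & bins$label == "undefined"] <- "undefined"
  bins$label <- lab
  bins
}

#' Proportion of time bins spent roaming
#'
#' @param bins a classified `track_bins` data.frame, or a list of them
#'   (one per worm in an assay); undefined bins are excluded from the
#'   denominator.
#' @return Fraction of defined bins labeled roaming; `NA` with a warning
#'   if every bin is undefined.
#' @export
fraction_roaming <- function(bins) {
  if (is.data.frame(bins)) bins <- list(bins)
  lab <- unlist(lapply(bins, function(b) b$label), use.names = FALSE)
  n_roam <- sum(lab == "roam", na.rm = TRUE)
  n_dwell <- sum(lab == "dwell", na.rm = TRUE)
  if (n_roam + n_dwell == 0L) {
    warning("all bins undefined; roaming fraction is NA")
    return(NA_real_)
  }
  n_roam / (n_roam + n_dwell)
}

#' Bin and classify a set of tracks
#'
#' Convenience wrapper: [bin_track()] then [classify_bins()] per worm.
#'
#' @param tracks a `worm_track` or list of them.
#' @param config a [classifier_config()].
#' @return A list of classified `track_bins`, one per worm.
#' @export
analyze_tracks <- function(tracks, config = classifier_config()) {
  if (inherits(tracks, "worm_track")) tracks <- list(tracks)
  lapply(tracks, function(tr) classify_bins(bin_track(tr, config), config))
}
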