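# Small in-code fixtures shared across test files.

# A hand-sized two-strain dataset with known proportions.
tiny_dataset <- function() {
  assay_dataset(
    strain_id = c("N2", "N2", "N2", "mut", "mut", "mut"),
    day_id = rep(c("d1", "d2", "d3"), 2),
    plate_id = paste0("p", 1:6),
    n_total = rep(20L, 6),
    n_dauer = c(4L, 6L, 8L, 4L, 6L, 8L),
    control_strain = "N2"
  )
}

# Build an assay_dataset directly from per-plate proportions (n = 10).
dataset_from_props <- function(props_by_strain, n = 10L) {
  strains <- rep(names(props_by_strain), lengths(props_by_strain))
  p <- unlist(props_by_strain, use.names = FALSE)
  assay_dataset(
    strain_id = strains,
    day_id = paste0("d", seq_along(p)),
    plate_id = paste0("p", seq_along(p)),
    n_total = rep(n, length(p)),
    n_dauer = as.integer(round(p * n)),
    control_strain = names(props_by_strain)[1]
  )
}

# A straight-line track along x at constant speed (mm/s), 3 fps default.
straight_track <- function(n_frames, speed = 0.15, fps = 3) {
  step <- speed / fps
  as_track(
    data.frame(
      t_s = (seq_len(n_frames) - 1) / fps,
      x_mm = (seq_len(n_frames) - 1) * step,
      y_mm = 0
    ),
    fps = fps
  )
}

# Polygonal path whose heading advances by `turn_deg` every frame.
constant_turn_track <- function(n_frames, turn_deg, step = 0.05, fps = 3) {
  heading <- cumsum(rep(turn_deg * pi / 180, n_frames - 1))
  x <- c(0, cumsum(step * cos(heading)))
  y <- c(0, cumsum(step * sin(heading)))
  as_track(
    data.frame(t_s = (seq_len(n_frames) - 1) / fps, x_mm = x, y_mm = y),
    fps = fps
  )
}

# Track visiting explicit positions at a fixed frame rate.
track_from_xy <- function(x, y, fps = 3) {
  as_track(
    data.frame(t_s = (seq_along(x) - 1) / fps, x_mm = x, y_mm = y),
    fps = fps
  )
}
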