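#' Grid configuration for exploration scoring
#'
#' The exploration assay superimposes a square grid over the circular
#' assay plate and counts entries of the worm track into each square, with
#' a per-square cap (additional entries cannot be distinguished from
#' existing tracks). The ImageJ-style reference grid holds 188 squares;
#' the realized grid here is the square lattice whose kept cells (centers
#' inside the arena circle) come closest to the target count.
#'
#' @param n_cells_target desired number of grid cells inside the arena.
#' @param cap maximum entries counted per cell.
#' @param center arena center, `c(x, y)` in mm.
#' @param radius_mm arena radius.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(n_cells_target = 188L, cap = 10L,
                        center = c(0, 0), radius_mm = 17.5) {
  if (cap < 1) hid_abort("cap must be >= 1", "hid_config_error")
  if (n_cells_target < 1) hid_abort("n_cells_target must be >= 1", "hid_config_error")
  structure(
    list(
      n_cells_target = as.integer(n_cells_target), cap = as.integer(cap),
      center = center, radius_mm = radius_mm
    ),
    class = "grid_config"
  )
}

#' Realize the scoring grid for an arena
#'
#' Chooses the lattice cell size whose number of kept cells (cells with
#' center inside the circular arena) is closest to the target; the
#' realized count is reported alongside the target since an exact match is
#' generally unattainable on a disk.
#'
#' @param config a [grid_config()].
#' @return list with `cell_size_mm`, `cells` (data.frame of kept cell
#'   indices `ix`, `iy` and centers), `n_cells` (realized) and
#'   `n_cells_target`.
#' @export
exploration_grid <- function(config = grid_config()) {
  R <- config$radius_mm
  target <- config$n_cells_target
  s0 <- R * sqrt(pi / target) # cell area ~ disk area / target
  candidates <- seq(0.8 * s0, 1.3 * s0, length.out = 500)
  count_for <- function(s) nrow(kept_cells(s, R))
  counts <- vapply(candidates, count_for, numeric(1))
  s <- candidates[which.min(abs(counts - target))]
  cells <- kept_cells(s, R)
  cells$cx <- cells$cx + config$center[1]
  cells$cy <- cells$cy + config$center[2]
  list(
    cell_size_mm = s, cells = cells, n_cells = nrow(cells),
    n_cells_target = target, center = config$center, radius_mm = R
  )
}

# lattice cells [i*s, (i+1)*s) whose centers lie inside the circle of
# radius R about the origin
kept_cells <- function(s, R) {
  k <- ceiling(R / s) + 1L
  ix <- rep(-k:k, each = 2L * k + 1L)
  iy <- rep(-k:k, times = 2L * k + 1L)
  cx <- (ix + 0.5) * s
  cy <- (iy + 0.5) * s
  inside <- cx^2 + cy^2 <= R^2
  data.frame(ix = ix[inside], iy = iy[inside], cx = cx[inside], cy = cy[inside])
}

#' Capped grid-entry exploration score of a track
#'
#' Frames are mapped to grid cells; an entry is a transition into a cell
#' from a different cell, and the starting cell counts as one entry.
#' Repeated frames within the same cell do not accumulate, so the score is
#' invariant to temporal upsampling of the same geometric path. Per-cell
#' counts are capped at `config$cap`; the total is the sum of capped
#' counts. Frames falling outside every kept cell (outside the arena) are
#' clipped to the nearest kept cell and counted in `n_clipped`.
#'
#' @param track a `worm_track`.
#' @param config a [grid_config()].
#' @param grid optionally a pre-computed [exploration_grid()] (reused
#'   across worms of one assay).
#' @return A list of class `grid_score`: `total`, `per_cell` (data.frame
#'   `ix`, `iy`, `entries`, `capped`), `n_cells` (realized grid size),
#'   `cell_size_mm`, `n_clipped`.
#' @export
grid_entry_score <- function(track, config = grid_config(), grid = NULL) {
  if (is.null(grid)) grid <- exploration_grid(config)
  s <- grid$cell_size_mm
  cx <- track$x_mm - grid$center[1]
  cy <- track$y_mm - grid$center[2]
  ix <- floor(cx / s)
  iy <- floor(cy / s)
  key <- paste(ix, iy)
  kept_key <- paste(grid$cells$ix, grid$cells$iy)
  outside <- !(key %in% kept_key)
  n_clipped <- sum(outside)
  if (n_clipped) {
    warning(sprintf("%d frame(s) outside the arena clipped to nearest cell", n_clipped))
    gx <- grid$cells$cx - grid$center[1]
    gy <- grid$cells$cy - grid$center[2]
    for (i in which(outside)) {
      j <- which.min((gx - cx[i])^2 + (gy - cy[i])^2)
      ix[i] <- grid$cells$ix[j]
      iy[i] <- grid$cells$iy[j]
      key[i] <- kept_key[j]
    }
  }
  # collapse consecutive frames in the same cell, then count visits per cell
  change <- c(TRUE, key[-1] != key[-length(key)])
  visits <- key[change]
  counts <- table(visits)
  entries <- as.integer(counts)
  capped <- pmin(entries, config$cap)
  ij <- do.call(rbind, strsplit(names(counts), " "))
  per_cell <- data.frame(
    ix = as.integer(ij[, 1]), iy = as.integer(ij[, 2]),
    entries = entries, capped = capped
  )
  structure(
    list(
      total = sum(capped), per_cell = per_cell, n_cells = grid$n_cells,
      cell_size_mm = s, n_clipped = n_clipped
    ),
    class = "grid_score"
  )
}

#' @export
print.grid_score <- function(x, ...) {
  cat(sprintf(
    "<grid_score> total %d entries over %d visited cells (grid of %d cells, %.2f mm)\n",
    x$total, nrow(x$per_cell), x$n_cells, x$cell_size_mm
  ))
  invisible(x)
}

#' Score a set of tracks into a grid-count table
#'
#' Maps each worm's track to its capped exploration score and returns the
#' `strain`/`day`/`worm`/`score` layout consumed by [fit_poisson_glmm()].
#'
#' @param tracks list of `worm_track` objects.
#' @param config a [grid_config()].
#' @param strain_id,day_id labels attached to every worm (vectors recycled
#'   across worms).
#' @return data.frame with columns `strain_id`, `day_id`, `worm_id`,
#'   `score`.
#' @export
grid_scores_table <- function(tracks, config = grid_config(),
                              strain_id = "N2", day_id = "day1") {
  grid <- exploration_grid(config)
  data.frame(
    strain_id = rep_len(strain_id, length(tracks)),
    day_id = rep_len(day_id, length(tracks)),
    worm_id = vapply(tracks, function(tr) attr(tr, "worm_id"), character(1)),
    score = vapply(tracks, function(tr) {
      grid_entry_score(tr, config, grid)$total
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}
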