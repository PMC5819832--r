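test_that("angular velocity is exact on canonical geometries", {
  collinear <- track_from_xy(c(0, 1, 2), c(0, 0, 0))
  expect_lt(abs(angular_velocity(collinear)[2] - 0), 1e-9)

  right_angle <- track_from_xy(c(0, 1, 1), c(0, 0, 1))
  expect_lt(abs(angular_velocity(right_angle)[2] - 90), 1e-9)

  reversal <- track_from_xy(c(0, 1, 0), c(0, 0, 0))
  expect_lt(abs(angular_velocity(reversal)[2] - 180), 1e-9)

  turn15 <- constant_turn_track(200, 15)
  av <- angular_velocity(turn15)
  expect_lt(max(abs(av[2:199] - 15)), 1e-9)

  # the raw cosine of the turn is exposed for audit
  expect_equal(attr(angular_velocity(right_angle), "cosine")[2], 0, tolerance = 1e-12)
  expect_error(angular_velocity(track_from_xy(c(0, 1), c(0, 0))), class = "hid_validation_error")
})

test_that("angular velocity is invariant to rotation, translation, and rescaling", {
  set.seed(8)
  base <- constant_turn_track(60, 25)
  av0 <- angular_velocity(base)
  th <- 0.7
  rot <- track_from_xy(
    cos(th) * base$x_mm - sin(th) * base$y_mm + 5,
    sin(th) * base$x_mm + cos(th) * base$y_mm - 2
  )
  expect_equal(angular_velocity(rot), av0, tolerance = 1e-9, ignore_attr = TRUE)
  scaled <- track_from_xy(3 * base$x_mm, 3 * base$y_mm)
  expect_equal(angular_velocity(scaled), av0, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(av0[!is.na(av0)] >= 0 & av0[!is.na(av0)] <= 180))
})

test_that("speed computes step length over time and scales linearly", {
  tr <- track_from_xy(c(0, 0.05, 0.10, 0.15), c(0, 0, 0, 0), fps = 3)
  sp <- track_speed(tr)
  expect_equal(sp[-1], rep(0.15, 3))
  still <- track_from_xy(rep(1, 5), rep(2, 5))
  expect_equal(track_speed(still)[-1], rep(0, 4))
  scaled <- track_from_xy(2 * tr$x_mm, 2 * tr$y_mm, fps = 3)
  expect_equal(track_speed(scaled)[-1], 2 * sp[-1])
  dup <- data.frame(t_s = c(0, 1, 1, 2), x_mm = 0:3, y_mm = 0)
  expect_error(as_track(dup, fps = 1), class = "hid_validation_error")
})

test_that("stationary interludes give undefined turn angles, not zeros", {
  xs <- c(0, 1, 1, 1, 2)
  tr <- track_from_xy(xs, rep(0, 5))
  av <- angular_velocity(tr)
  expect_true(all(is.na(av[2:4]))) # every interior frame touches a zero step
})

test_that("a 90-minute 3-fps track yields exactly 540 complete 10-s bins", {
  tr <- straight_track(n_frames = floor(3 * 5400))
  bins <- bin_track(tr)
  expect_equal(nrow(bins), 540L)
  expect_true(all(bins$n_frames == 30L))
})

test_that("trailing partial bins are dropped and constant tracks bin to constants", {
  tr95 <- constant_turn_track(n_frames = 95 * 3, turn_deg = 10)
  bins <- bin_track(tr95)
  expect_equal(nrow(bins), 9L)
  expect_equal(unname(bins$mean_angular_velocity), rep(10, 9), tolerance = 1e-9)
  expect_equal(unname(bins$mean_speed), rep(0.05 * 3, 9), tolerance = 1e-6)
})

test_that("the slope-2 partition follows the stated rule and tie-break", {
  mk_bin <- function(speed, angvel) {
    data.frame(
      t_start = 0, mean_speed = speed, mean_angular_velocity = angvel,
      n_frames = 30, frac_undefined = 0, label = NA_character_
    )
  }
  cfg <- classifier_config()
  expect_equal(classify_bins(mk_bin(10, 2), cfg)$label, "roam") # 10 > 4
  expect_equal(classify_bins(mk_bin(1, 5), cfg)$label, "dwell") # 1 < 10
  expect_equal(classify_bins(mk_bin(4, 2), cfg)$label, "dwell") # on the line
  cfg_r <- classifier_config(boundary_rule = "roam_on_line")
  expect_equal(classify_bins(mk_bin(4, 2), cfg_r)$label, "roam")

  # monotone in speed at fixed angular velocity: roam never flips to dwell
  speeds <- seq(0, 20, by = 0.5)
  labs <- vapply(speeds, function(s) classify_bins(mk_bin(s, 4), cfg)$label, character(1))
  expect_true(all(diff(labs == "roam") >= 0))

  und <- mk_bin(10, 2)
  und$label <- "undefined"
  expect_equal(classify_bins(und, cfg)$label, "undefined")
})

test_that("roaming fraction excludes undefined bins and warns when empty", {
  bins <- data.frame(label = c(rep("roam", 3), rep("dwell", 7), rep("undefined", 2)))
  expect_equal(fraction_roaming(bins), 0.3)
  expect_equal(fraction_roaming(data.frame(label = rep("roam", 4))), 1.0)
  expect_warning(
    out <- fraction_roaming(data.frame(label = rep("undefined", 3))),
    "undefined"
  )
  expect_true(is.na(out))
})

test_that("roam/dwell recovery works on short synthetic tracks", {
  cfg <- track_sim_config(
    duration_s = 1200,
    transition = transition_matrix(roam_occupancy = 0.5, switch_rate = 0.01)
  )
  tracks <- simulate_tracks(cfg, n_worms = 6, seed = 99)
  bins <- analyze_tracks(tracks, classifier_config(speed_scale = 1000))
  fr <- fraction_roaming(bins)
  expect_gt(fr, 0.38)
  expect_lt(fr, 0.62)
  acc <- mean(unlist(lapply(bins, function(b) {
    ok <- b$label %in% c("roam", "dwell")
    b$label[ok] == b$true_label[ok]
  })))
  expect_gt(acc, 0.85)
})
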