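test_that("zero-variance generator is plate-wise iid binomial", {
  ds <- simulate_assay_dataset(
    simulation_scenario(
      group_logits = c(control = 0), n_days = 4,
      plates_per_group = 4000, animals_per_plate = 100
    ),
    variance_components(0, 0, 0),
    seed = 101
  )
  p <- plate_proportions(ds)
  expect_equal(mean(p), 0.5, tolerance = 0.01)
  expect_equal(sd(p), sqrt(0.25 / 100), tolerance = 0.1)
})

test_that("a 1-logit group lands at logistic(1) and bias shifts only control days", {
  ds <- simulate_assay_dataset(
    simulation_scenario(
      group_logits = c(control = 0, mut = 1), n_days = 4,
      plates_per_group = 2000, animals_per_plate = 100
    ),
    variance_components(0, 0, 0),
    seed = 7
  )
  m <- tapply(plate_proportions(ds), ds$strain_id, mean)
  expect_equal(unname(m["mut"]), plogis(1), tolerance = 0.01)
  expect_equal(unname(m["control"]), 0.5, tolerance = 0.01)

  # systematic bias: control day effects offset by bias_magnitude * sd_day
  # on ceil(bias_fraction * n_days) days
  ds_b <- simulate_assay_dataset(
    simulation_scenario(
      group_logits = c(control = 0, mut = 0), n_days = 3,
      plates_per_group = 6, bias_fraction = 1 / 3
    ),
    variance_preset("high"),
    seed = 3
  )
  truth <- attr(ds_b, "truth")
  expect_length(truth$bias_days, 1L)
  expect_equal(truth$bias_offset, 1.0) # 1 x sd_day on the high preset
})

test_that("logit-scale variance of plate means decomposes into sD2 + sP2 + sG2", {
  vc <- variance_components(1, 0.3, 0.3)
  n <- 400L
  ds <- simulate_assay_dataset(
    simulation_scenario(
      group_logits = c(control = 0), n_days = 3000,
      plates_per_group = 3000, animals_per_plate = n
    ),
    vc,
    seed = 55
  )
  # empirical logit per plate; subtract the delta-method binomial term
  p_hat <- (ds$n_dauer + 0.5) / (ds$n_total + 1)
  total_var <- var(qlogis(p_hat))
  binom_term <- mean(1 / (n * p_hat * (1 - p_hat)))
  target <- sum(vc^2)
  expect_equal(total_var - binom_term, target, tolerance = 0.12)
})

test_that("generators are deterministic in the seed and independent across seeds", {
  sc <- simulation_scenario()
  a <- simulate_assay_dataset(sc, variance_preset("low"), seed = 9)
  b <- simulate_assay_dataset(sc, variance_preset("low"), seed = 9)
  c <- simulate_assay_dataset(sc, variance_preset("low"), seed = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$n_dauer, c$n_dauer))

  # generator restores the caller's RNG stream
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(simulate_assay_dataset(sc, variance_preset("low"), seed = 2))
  expect_identical(runif(1), before)

  tr1 <- simulate_tracks(track_sim_config(duration_s = 30), n_worms = 2, seed = 4)
  tr2 <- simulate_tracks(track_sim_config(duration_s = 30), n_worms = 2, seed = 4)
  expect_identical(tr1, tr2)
})

test_that("unbalanced designs keep the control on all days and drop each test group from one", {
  sc <- simulation_scenario(
    group_logits = c(control = 0, a = 0, b = 0),
    n_days = 3, plates_per_group = 6, balanced = FALSE
  )
  ds <- simulate_assay_dataset(sc, variance_preset("low"), seed = 1)
  days_by_strain <- tapply(ds$day_id, ds$strain_id, function(d) length(unique(d)))
  expect_equal(as.vector(days_by_strain[c("control", "a", "b")]), c(3L, 2L, 2L))
  counts <- table(ds$strain_id)
  expect_true(all(counts == 6L)) # plates reallocated, totals preserved
})

test_that("track generator conserves frame count, arena bounds, and state structure", {
  cfg <- track_sim_config(fps = 3, duration_s = 100, arena_radius_mm = 5)
  tr <- simulate_tracks(cfg, n_worms = 3, seed = 12)
  for (t in tr) {
    expect_equal(nrow(t), floor(3 * 100))
    expect_true(all(t$x_mm^2 + t$y_mm^2 <= 5^2 + 1e-9))
  }

  # dwell-only chain: mean per-frame displacement = dwell speed / fps
  cfg_d <- track_sim_config(
    duration_s = 600,
    transition = matrix(c(1, 0, 0, 1), 2, 2), # absorbing states
    dwell_speed = c(0.02, 0), roam_speed = c(0.02, 0)
  )
  t_d <- simulate_tracks(cfg_d, 1, seed = 3)[[1]]
  disp <- sqrt(diff(t_d$x_mm)^2 + diff(t_d$y_mm)^2)
  expect_equal(mean(disp), 0.02 / 3, tolerance = 1e-6)

  # roam-only, zero turning: straight path, length = speed x duration
  cfg_r <- track_sim_config(
    duration_s = 600,
    transition = matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE),
    roam_speed = c(0.1, 0), roam_turn_sd = 0,
    arena_radius_mm = 500 # large arena: no reflections
  )
  t_r <- simulate_tracks(cfg_r, 1, seed = 3)[[1]]
  path_len <- sum(sqrt(diff(t_r$x_mm)^2 + diff(t_r$y_mm)^2))
  expect_equal(path_len, 0.1 * 600, tolerance = 0.01)
  # collinearity: all interior turn angles zero
  av <- angular_velocity(t_r)
  expect_lt(max(abs(av[!is.na(av)])), 1e-6)

  expect_error(
    track_sim_config(transition = matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2)),
    class = "hid_config_error"
  )
})

test_that("symmetric switching yields the Markov stationary occupancy", {
  # stationary occupancy oracle: pi_roam = p_dr / (p_rd + p_dr) = 0.5
  cfg <- track_sim_config(
    duration_s = 5400,
    transition = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE)
  )
  tr <- simulate_tracks(cfg, n_worms = 6, seed = 21)
  occ <- mean(unlist(lapply(tr, function(t) t$true_state == "roam")))
  expect_equal(occ, 0.5, tolerance = 0.06)
})

test_that("grid-count generator has Poisson moments and day-driven overdispersion", {
  g0 <- simulate_grid_counts(c(N2 = 20), variance_components(0, 0, 0),
    n_worms_per_day = 500, n_days = 2, seed = 31
  )
  expect_equal(mean(g0$score), 20, tolerance = 0.5 / sqrt(10)) # 1000 worms
  expect_equal(var(g0$score) / mean(g0$score), 1, tolerance = 0.15)

  g2 <- simulate_grid_counts(c(N2 = 20, mut = 40), variance_components(0, 0, 0),
    n_worms_per_day = 400, n_days = 2, seed = 32
  )
  m <- tapply(g2$score, g2$strain_id, mean)
  expect_equal(unname(m["mut"] / m["N2"]), 2, tolerance = 0.05)

  # lognormal day mixture: var/mean = 1 + rate * (exp(sd^2) - 1) * exp(sd^2) > 1.2
  g_od <- simulate_grid_counts(c(N2 = 20), variance_components(0.5, 0, 0),
    n_worms_per_day = 300, n_days = 30, seed = 33
  )
  expect_gt(var(g_od$score) / mean(g_od$score), 1.2)

  # truncation at the capped maximum
  g_cap <- simulate_grid_counts(c(N2 = 50), variance_components(0, 0, 0),
    n_worms_per_day = 50, n_days = 1, seed = 34, cap_total = 40
  )
  expect_true(all(g_cap$score <= 40))
  expect_error(simulate_grid_counts(c(N2 = -1), seed = 1), class = "hid_config_error")
})
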