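test_that("invalid configurations are rejected", {
  expect_error(clone_config(n_cells = 0), class = "bimodyn_invalid_config")
  expect_error(clone_config(dt_h = 0), class = "bimodyn_invalid_config")
  expect_error(clone_config(frac_up = 1.5), class = "bimodyn_invalid_config")
  expect_error(clone_config(p_death_up = -0.1), class = "bimodyn_invalid_config")
  expect_error(clone_config(horizon_h = 10, t_switch_h = 12),
               class = "bimodyn_invalid_config")
  expect_error(simulate_panel(0, 0.5), class = "bimodyn_invalid_config")
  expect_error(simulate_panel(10, 1.2), class = "bimodyn_invalid_config")
})

test_that("zero-noise, zero-slope clone is constant at baseline", {
  sim <- simulate_clone(quiet_config(n_cells = 5, noise_sd = 0,
                                     common_drift = 0, slope_down = 0))
  expect_true(all(abs(sim$trajectories$yfp - 1000) < 1e-9))
  expect_equal(nrow(sim$trajectories), 5 * 49)
})

test_that("noiseless bimodal assignment is exactly countable", {
  sim <- simulate_clone(quiet_config(n_cells = 100, noise_sd = 0,
                                     is_bimodal = TRUE, frac_up = 0.5,
                                     seed = 2))
  s <- slope_summaries(sim$trajectories)
  expect_equal(sum(abs(s$mean_slope - 45) < 1e-9), 50)
  expect_equal(sum(abs(s$mean_slope + 45) < 1e-9), 50)
  # rounding rule for uneven fractions
  sim2 <- simulate_clone(quiet_config(n_cells = 10, is_bimodal = TRUE,
                                      frac_up = 0.26))
  expect_equal(sum(sim2$truth$subpop == "up"), 3)
})

test_that("noiseless post-switch interval slopes equal the configured slope", {
  sim <- simulate_clone(quiet_config(n_cells = 20, noise_sd = 0,
                                     is_bimodal = TRUE, frac_up = 0.5,
                                     common_drift = -10, seed = 5))
  tr <- dplyr::filter(sim$trajectories, time_h >= 12)
  for (cl in split(tr, tr$cell_id)) {
    sl <- diff(cl$yfp) / diff(cl$time_h)
    target <- if (sim$truth$subpop[sim$truth$cell_id == cl$cell_id[1]] == "up")
      45 else -45
    expect_equal(mean(sl), target, tolerance = 1e-10)
  }
})

test_that("identical seeds give bit-identical datasets, different seeds differ", {
  cfg <- clone_config(n_cells = 30, is_bimodal = TRUE, seed = 42)
  a <- simulate_clone(cfg); b <- simulate_clone(cfg)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$truth, b$truth)
  c <- simulate_clone(clone_config(n_cells = 30, is_bimodal = TRUE, seed = 43))
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("death times follow the truncated normal law and truncate trajectories", {
  sim <- simulate_clone(clone_config(n_cells = 1000, p_death_up = 1,
                                     p_death_down = 1, mitosis_rate = 0,
                                     seed = 5))
  died <- sim$truth[sim$truth$fate == "died", ]
  expect_equal(nrow(died), 1000)
  expect_true(all(died$death_time_h > 12 & died$death_time_h <= 24))
  ref <- bimodyn:::trunc_norm_moments(15, 3, 12, 24)
  se <- ref$sd / sqrt(nrow(died))
  expect_lt(abs(mean(died$death_time_h) - ref$mean), 3 * se)
  # no samples at or after the death time
  last <- dplyr::summarise(dplyr::group_by(sim$trajectories, cell_id),
                           t_last = max(time_h))
  last <- dplyr::left_join(last, sim$truth, by = "cell_id")
  expect_true(all(last$t_last < last$death_time_h))
})

test_that("fate coupling matches the configured death probabilities", {
  sim <- simulate_clone(clone_config(n_cells = 10000, is_bimodal = TRUE,
                                     frac_up = 0.5, p_death_up = 0.7,
                                     p_death_down = 0.2, mitosis_rate = 0,
                                     seed = 8))
  for (grp in c("up", "down")) {
    sub <- sim$truth[sim$truth$subpop == grp, ]
    p <- if (grp == "up") 0.7 else 0.2
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lt(abs(mean(sub$fate == "died") - p), 3 * se)
  }
})

test_that("mitosis halves the level of the followed lineage", {
  sim <- simulate_clone(quiet_config(n_cells = 200, noise_sd = 0,
                                     common_drift = 0, slope_down = 0,
                                     mitosis_rate = 2, seed = 9))
  with_mit <- sim$truth[lengths(sim$truth$mitosis_times) == 1, ]
  expect_gt(nrow(with_mit), 0)
  for (i in seq_len(min(5, nrow(with_mit)))) {
    tr <- sim$trajectories[sim$trajectories$cell_id == with_mit$cell_id[i], ]
    mt <- with_mit$mitosis_times[[i]]
    expect_true(all(abs(tr$yfp[tr$time_h < mt] - 1000) < 1e-9))
    expect_true(all(abs(tr$yfp[tr$time_h >= mt] - 500) < 1e-9))
  }
})

test_that("panel composition, per-clone seeds and determinism", {
  base <- clone_config(n_cells = 20)
  p <- simulate_panel(100, 0.25, base, seed = 7)
  expect_equal(sum(p$clone_truth$is_bimodal), 25)
  expect_equal(dplyr::n_distinct(p$clone_truth$seed), 100)
  p2 <- simulate_panel(100, 0.25, base, seed = 7)
  expect_identical(p$trajectories, p2$trajectories)
  p3 <- simulate_panel(1, 0, base, seed = 7)
  expect_false(any(p3$clone_truth$is_bimodal))
  expect_equal(nrow(p3$clone_truth), 1)
})

test_that("per-cell level scatter shifts curves without changing slopes", {
  sim <- simulate_clone(quiet_config(n_cells = 50, noise_sd = 0,
                                     is_bimodal = TRUE, frac_up = 0.5,
                                     cell_level_sd = 0.35, seed = 12))
  s <- slope_summaries(sim$trajectories)
  expect_true(all(abs(abs(s$mean_slope) - 45) < 1e-9))
  t0 <- dplyr::filter(sim$trajectories, time_h == 0)
  expect_gt(sd(t0$yfp), 100)
})
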