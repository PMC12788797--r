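test_that("config validation rejects degenerate state mixtures", {
  expect_error(smt_sim_config(states = data.frame(D = numeric(), weight = numeric())),
               "at least one state")
  expect_error(smt_sim_config(states = data.frame(D = 1, weight = 0)),
               "positive sum")
  expect_error(smt_sim_config(states = data.frame(D = c(1, 2), weight = c(0.5, 0.4))),
               "sum to 1")
  expect_error(smt_sim_config(states = data.frame(D = -1, weight = 1)), ">= 0")
  expect_error(smt_sim_config(frame_interval = 0), "> 0")
})

test_that("mean squared jump matches the closed form 4(D dt + sigma^2)", {
  # immobile molecules: displacement is localization error only
  sim0 <- sim_single_state(D = 0, seed = 21)
  j0 <- sim_jumps(sim0)
  expect_gt(nrow(j0), 1e4)
  expect_equal(mean(j0$r^2), 4 * 0.03^2, tolerance = 0.05)

  # fast molecules: 4 (D dt + sigma^2) at D = 2, dt = 7.48 ms
  sim2 <- sim_single_state(D = 2, seed = 22)
  j2 <- sim_jumps(sim2)
  expect_gt(nrow(j2), 1e4)
  expect_equal(mean(j2$r^2), 4 * (2 * 0.00748 + 0.03^2), tolerance = 0.05)
})

test_that("simulators are deterministic given a seed", {
  cfg <- smt_sim_config(cells_per_day = 3, mean_mols_per_cell = 30, seed = 7)
  expect_identical(simulate_smt_dataset(cfg)$trajectories,
                   simulate_smt_dataset(cfg)$trajectories)

  pcfg <- papa_sim_config(n_cells = 10, seed = 7)
  expect_identical(as.data.frame(simulate_papa_dataset(pcfg)),
                   as.data.frame(simulate_papa_dataset(pcfg)))

  fcfg <- frap_sim_config(n_post = 10, seed = 7)
  expect_identical(simulate_frap_movie(fcfg)$stack, simulate_frap_movie(fcfg)$stack)
})

test_that("state assignment frequencies converge to the configured weights", {
  sim <- sim_two_state(seed = 30, cells_per_day = 20, mols = 100)
  mols <- sim$ground_truth$molecules
  n <- nrow(mols)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(mols$state == 1) - 0.3), 3 * se)
})

test_that("localizations stay inside the field of view", {
  sim <- sim_two_state(seed = 31, cells_per_day = 5)
  fov <- sim$ground_truth$config$fov_size
  expect_true(all(sim$trajectories$x >= 0 & sim$trajectories$x <= fov))
  expect_true(all(sim$trajectories$y >= 0 & sim$trajectories$y <= fov))
  expect_true(all(sim$trajectories$frame >= 0))
})

test_that("with no defocalization or bleaching, trajectories are gap-free and movie-limited", {
  cfg <- smt_sim_config(states = data.frame(D = 1, weight = 1),
                        focal_depth = 1e6, bleach_mean_frames = 1e9,
                        n_frames = 50, n_days = 1, cells_per_day = 2,
                        mean_mols_per_cell = 30, seed = 8)
  sim <- simulate_smt_dataset(cfg)
  by_traj <- split(sim$trajectories$frame, sim$trajectories$trajectory)
  # each molecule yields exactly one trajectory running to the movie end
  expect_true(all(vapply(by_traj, function(f) all(diff(sort(f)) == 1), logical(1))))
  expect_true(all(vapply(by_traj, max, numeric(1)) == 49))
})

test_that("PAPA counting model: control baseline and interaction linearity", {
  base <- papa_sim_config(interaction = 0, control_ratio = 0.25)
  expect_equal(papa_expected_ratio(base), 0.25)

  # the interaction-driven excess is linear in the multiplier
  r1 <- papa_expected_ratio(papa_sim_config(interaction = 1, control_ratio = 0.25))
  r2 <- papa_expected_ratio(papa_sim_config(interaction = 2, control_ratio = 0.25))
  expect_equal(r2 - 0.25, 2 * (r1 - 0.25))

  # with no control background the green excess itself doubles exactly
  c1 <- papa_sim_config(interaction = 1, control_ratio = 0, cell_lognorm_sd = 0)
  c2 <- papa_sim_config(interaction = 2, control_ratio = 0, cell_lognorm_sd = 0)
  ex <- function(cfg) cfg$interaction * cfg$green_rate * cfg$cycles
  expect_equal(ex(c2), 2 * ex(c1))
})

test_that("pooled corrected G/V of a large PAPA simulation matches its own expectation", {
  cfg <- papa_sim_config(n_cells = 5000, n_days = 2, interaction = 0.8,
                         control_ratio = 0.25, cell_lognorm_sd = 0, seed = 44)
  counts <- simulate_papa_dataset(cfg)
  g <- sum(counts$n_green) - sum(counts$n_spont2)
  v <- sum(counts$n_violet) - sum(counts$n_spont1)
  ratio <- g / v
  expected <- papa_expected_ratio(cfg)
  # delta-method s.e. of the ratio of two independent Poisson differences
  n <- nrow(counts)
  cyc <- cfg$cycles
  var_g <- n * cyc * (2 * cfg$spont_rate + cfg$control_ratio * cfg$violet_rate +
                        cfg$interaction * cfg$green_rate)
  var_v <- n * cyc * (2 * cfg$spont_rate + cfg$violet_rate)
  mu_v <- n * cyc * cfg$violet_rate
  se <- abs(expected) * sqrt(var_g / (expected * mu_v)^2 + var_v / mu_v^2)
  expect_lt(abs(ratio - expected), 3 * se)
})

test_that("FRAP simulator: bleach-depth limits and recovery plateau", {
  # nothing bleached: curve stays at 1
  mv0 <- simulate_frap_movie(frap_sim_config(bleach_depth = 0, noise_sd = 0,
                                             obs_bleach_rate = 0, n_post = 30, seed = 2))
  res0 <- analyze_frap_movie(mv0)
  expect_true(all(abs(res0$curve$value - 1) < 1e-6))

  # plateau approaches A1 + A2 of the bleached amount
  mv <- simulate_frap_movie(frap_sim_config(noise_sd = 0, obs_bleach_rate = 0,
                                            tau2 = 5, n_post = 200, seed = 2))
  mask <- nuclear_mask(mv)
  curve <- extract_frap_curve(photobleach_correct(background_subtract(mv, mask), mask), mask)
  late <- curve$value[curve$phase == "post"]
  expect_equal(tail(late, 1), 0.8, tolerance = 1e-3)
})

test_that("FRAP simulator rejects a bleach spot outside the nucleus", {
  expect_error(frap_sim_config(spot_offset_um = c(4, 0)), "inside the nucleus")
})
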