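test_that("jump likelihood is a normalized Rayleigh with the documented scale", {
  s <- sqrt(2 * (0 * 0.00748 + 0.03^2))
  # mode of the Rayleigh density sits at its scale parameter
  mode <- optimize(function(r) jump_likelihood(r, D = 0, sigma_loc = 0.03, dt = 0.00748),
                   c(0, 0.5), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(mode, s, tolerance = 1e-4)
  expect_equal(mode, 0.042426, tolerance = 1e-4)

  # normalization
  s2 <- sqrt(2 * (2 * 0.00748 + 0.03^2))
  total <- stats::integrate(function(r) jump_likelihood(r, 2, 0.03, 0.00748),
                            0, 10 * s2, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)

  # second moment equals 2 s^2 = 4 (D dt + sigma^2)
  m2 <- stats::integrate(function(r) r^2 * jump_likelihood(r, 2, 0.03, 0.00748),
                         0, 20 * s2, rel.tol = 1e-12)$value
  expect_equal(m2, 0.06344, tolerance = 1e-4)

  expect_error(jump_likelihood(0.1, 0, 0, 0.01), "degenerate")
})

test_that("trajectory splitting bounds segment sizes without sharing jumps", {
  jumps <- tibble::tibble(r = rep(0.1, 9), dt = 0.00748,
                          trajectory = c(rep(1L, 7), 2L, 2L))
  s3 <- split_trajectories(jumps, 3)
  expect_equal(as.integer(table(s3$segment[s3$trajectory == 1])), c(3L, 3L, 1L))
  expect_equal(dplyr::n_distinct(s3$segment[s3$trajectory == 2]), 1L)

  s1 <- split_trajectories(jumps, 1)
  expect_equal(dplyr::n_distinct(s1$segment), nrow(jumps))
  expect_error(split_trajectories(jumps, 0), ">= 1")
})

test_that("slab retention: limits, monotonicity, and Monte-Carlo agreement", {
  expect_equal(defocalization_retention(0, 0.0224, 0.7), 1)
  # identity in the infinite-slab limit (up to series truncation)
  expect_equal(defocalization_retention(c(0.1, 1, 10), 0.0224, 1e6),
               rep(1, 3), tolerance = 1e-5)
  # stochastic dominance: faster molecules escape more (strictly, until the
  # numerical floor is reached)
  vals <- defocalization_retention(10^seq(-2, 2, by = 0.5), 0.0224, 0.7)
  expect_true(all(diff(vals) <= 0))
  unclipped <- vals[vals > 1e-6]
  expect_true(all(diff(unclipped) < 0))
  # brute-force walker oracle (reduced walker count; the full-scale
  # comparison runs in the acceptance suite)
  for (D in c(0.1, 2)) {
    mc <- mc_defocalization_retention(D, 3 * 0.00748, 0.7, n_walkers = 2e5,
                                      n_substeps = 50, seed = 9)
    expect_lt(abs(defocalization_retention(D, 3 * 0.00748, 0.7) - mc), 0.005)
  }
})

test_that("EM recovers a single diffusive state and is deterministic", {
  sim <- sim_single_state(D = 1, seed = 50, n_cells = 4, mols = 300,
                          bleach_mean = 10)
  jumps <- sim_jumps(sim)
  expect_gt(nrow(jumps), 1e4)
  spec <- infer_spectrum(jumps, defoc_correct = FALSE)
  occ <- spec$spectrum
  # at least 80% of mass within a factor of 2 of the true D
  expect_gte(sum(occ$occupation[occ$D > 0.5 & occ$D < 2]), 0.8)

  spec2 <- infer_spectrum(jumps, defoc_correct = FALSE)
  expect_identical(spec$spectrum$occupation, spec2$spectrum$occupation)
})

test_that("EM log-likelihood is non-decreasing and occupations stay normalized", {
  sim <- sim_two_state(seed = 51, cells_per_day = 5, mols = 40)
  spec <- infer_spectrum(sim_jumps(sim))
  for (trace in spec$loglik) {
    expect_true(all(diff(trace) >= -1e-7 * abs(trace[1])))
  }
  expect_equal(sum(spec$spectrum$occupation), 1, tolerance = 1e-9)
  expect_equal(sum(spec$spectrum$occupation_raw), 1, tolerance = 1e-9)
  expect_true(all(spec$spectrum$occupation >= 0))
})

test_that("estimated bound fraction increases with the simulated bound weight", {
  fb <- vapply(c(0.1, 0.3, 0.5, 0.7), function(p) {
    sim <- sim_two_state(seed = 60 + round(100 * p), cells_per_day = 15,
                         mols = 50, p_bound = p)
    bound_fraction(infer_spectrum(sim_jumps(sim)))
  }, numeric(1))
  expect_true(all(diff(fb) > 0))
})

test_that("bound fraction sums occupations strictly below the threshold", {
  grid_d <- diffusion_grid()$D
  at <- function(d) {
    occ <- rep(0, length(grid_d))
    occ[which.min(abs(grid_d - d))] <- 1
    tibble::tibble(D = grid_d, occupation = occ)
  }
  expect_equal(bound_fraction(at(0.01)), 1)
  expect_equal(bound_fraction(at(10)), 0)
  uniform <- tibble::tibble(D = grid_d, occupation = rep(1 / 100, 100))
  expect_equal(bound_fraction(uniform), 0.25)
})

test_that("two-state jump-length fit recovers mixtures and degenerates cleanly", {
  # 50/50 mixture with negligible defocalization
  sim <- simulate_smt_dataset(smt_sim_config(
    states = data.frame(D = c(0.005, 2), weight = c(0.5, 0.5)),
    focal_depth = 100, bleach_mean_frames = 10,
    n_days = 1, cells_per_day = 12, mean_mols_per_cell = 250,
    cell_sd = 0, day_sd = 0, seed = 52))
  jumps <- sim_jumps(sim)
  fit <- two_state_jumplength_fit(jumps)
  expect_lt(abs(fit$f_bound - 0.5), 0.03)
  expect_lt(fit$D_bound, fit$D_free)

  # single free state: mixture collapses
  fit1 <- two_state_jumplength_fit(sim_jumps(sim_single_state(D = 2, seed = 53,
                                                              mols = 300)))
  expect_lte(fit1$f_bound, 0.05)

  expect_error(two_state_jumplength_fit(tibble::tibble(r = runif(10))), "1000")
})

test_that("spectrum and corrected two-state bound fractions cross-validate", {
  sim <- sim_two_state(seed = 54, cells_per_day = 30, mols = 60)
  jumps <- compute_jumps(filter_trajectories(sim$trajectories))
  fb_spec <- bound_fraction(infer_spectrum(jumps))
  fb_two <- two_state_jumplength_fit(jumps)$f_bound_corrected
  expect_lt(abs(fb_spec - fb_two), 0.05)
})
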