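test_that("phase map lays out readout blocks and cycles as acquired", {
  pm <- build_phase_map()
  expect_equal(nrow(pm), 600L)
  lookup <- function(f) pm$phase[pm$frame == f]
  expect_equal(lookup(35), "violet_readout")
  expect_equal(pm$cycle[pm$frame == 35], 0L)
  expect_equal(lookup(90), "papa_readout")
  expect_equal(lookup(120), "spont1")
  expect_equal(pm$cycle[pm$frame == 120], 1L)
  expect_error(smtkit:::phase_of_frame(600L, pm), "outside")
})

test_that("reactivations are tallied to the phase of the first localization", {
  # five trajectories starting in the violet block of cycle 0
  trajs <- tibble::tibble(
    frame = as.integer(c(30:34, 31:35, 29, 30, 31)),
    trajectory = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L),
    cell_id = "c1")
  counts <- count_reactivations(trajs)
  # trajectories 1 and 2 start in violet; 3 starts at frame 29 (spont1)
  expect_equal(counts$n_violet, 2L)
  expect_equal(counts$n_spont1, 1L)
  expect_equal(counts$n_spont2, 0L)
  expect_equal(counts$n_green, 0L)
  # per-phase tallies sum to the number of trajectories
  expect_equal(counts$n_spont1 + counts$n_violet + counts$n_spont2 + counts$n_green,
               dplyr::n_distinct(trajs$trajectory))
})

test_that("corrected G/V ratio follows the subtraction rule with flooring", {
  counts <- tibble::tibble(
    n_spont1 = c(10, 10, 10, 20),
    n_violet = c(50, 50, 10, 10),
    n_spont2 = c(10, 30, 10, 10),
    n_green = c(30, 30, 30, 30))
  out <- corrected_gv_ratio(counts)
  expect_equal(out$gv_ratio[1], 0.5)      # (30-10)/(50-10)
  expect_equal(out$gv_ratio[2], 0)        # green excess floored at 0
  expect_true(is.na(out$gv_ratio[3]))     # violet excess zero -> missing
  expect_true(is.na(out$gv_ratio[4]))     # negative violet excess floored -> missing
})

test_that("day-matched normalization reproduces the worked ratio of 1.4", {
  cell <- tibble::tibble(day_id = "day01", n_spont1 = 0, n_violet = 100,
                         n_spont2 = 0, n_green = 36)
  ctrl <- tibble::tibble(day_id = "day01", n_spont1 = 0, n_violet = 100,
                         n_spont2 = 0, n_green = 26)
  out <- normalize_to_control(cell, ctrl)
  expect_equal(out$gv_ratio, 0.36)
  expect_equal(out$control_ratio, 0.26)
  expect_equal(round(out$normalized_ratio, 1), 1.4)
})

test_that("normalization is day-matched and self-normalization centres at 1", {
  # identical cells on two days with different control aggregates
  cells <- tibble::tibble(day_id = c("d1", "d2"), n_spont1 = 0, n_violet = 100,
                          n_spont2 = 0, n_green = 40)
  ctrl <- tibble::tibble(day_id = c("d1", "d2"), n_spont1 = 0, n_violet = c(100, 100),
                         n_spont2 = 0, n_green = c(20, 40))
  out <- normalize_to_control(cells, ctrl)
  expect_equal(out$normalized_ratio, c(2, 1))

  # a control condition normalized to itself has combined ratio exactly 1
  ctrl_cells <- simulate_papa_dataset(papa_sim_config(interaction = 0, seed = 80))
  pb <- papa_bootstrap(ctrl_cells, ctrl_cells, n_trials = 24, seed = 81)
  expect_equal(pb$estimate, 1)

  expect_warning(
    normalize_to_control(
      tibble::tibble(day_id = "d9", n_spont1 = 0, n_violet = 10,
                     n_spont2 = 0, n_green = 5),
      ctrl),
    "no control")
})

test_that("PAPA bootstrap: degenerate CI and interaction recovery", {
  single <- tibble::tibble(day_id = "d1", n_spont1 = 5, n_violet = 60,
                           n_spont2 = 5, n_green = 30)
  ctrl <- tibble::tibble(day_id = "d1", n_spont1 = 0, n_violet = 100,
                         n_spont2 = 0, n_green = 25)
  pb1 <- papa_bootstrap(single, ctrl, n_trials = 24, seed = 82)
  expect_equal(pb1$ci_high - pb1$ci_low, 0)

  # interaction chosen to double the green excess relative to the control
  cond <- simulate_papa_dataset(papa_sim_config(n_cells = 120, interaction = 0.25,
                                                control_ratio = 0.25, seed = 83))
  ctrl2 <- simulate_papa_dataset(papa_sim_config(n_cells = 120, interaction = 0,
                                                 control_ratio = 0.25, seed = 84))
  pb2 <- papa_bootstrap(cond, ctrl2, seed = 85)
  expect_true(pb2$ci_low <= 2 && 2 <= pb2$ci_high + 0.1)
  expect_equal(pb2$estimate, 2, tolerance = 0.1)
})

test_that("non-interacting conditions have CIs that cover 1", {
  # the control aggregate is held fixed during the bootstrap (only condition
  # cells are resampled), so the control pool is sized to make its own
  # sampling noise small relative to the condition CI width
  covered <- vapply(1:100, function(i) {
    cond <- simulate_papa_dataset(papa_sim_config(n_cells = 25, interaction = 0,
                                                  seed = 1000 + i))
    ctrl <- simulate_papa_dataset(papa_sim_config(n_cells = 80, interaction = 0,
                                                  seed = 2000 + i))
    pb <- papa_bootstrap(cond, ctrl, seed = 3000 + i)
    pb$ci_low <= 1 && 1 <= pb$ci_high
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("trajectory segregation splits green- from violet-reactivated molecules", {
  pm <- build_phase_map()
  trajs <- tibble::tibble(frame = c(100L, 101L, 10L, 11L, 40L),
                          trajectory = c(1L, 1L, 2L, 2L, 3L))
  seg <- segregate_papa_trajectories(trajs, pm)
  expect_equal(unique(seg$green$trajectory), 1L)
  expect_equal(unique(seg$violet$trajectory), 3L)  # frame 40: violet block
  expect_false(2L %in% c(seg$green$trajectory, seg$violet$trajectory))
})

test_that("bound-enriched green molecules yield a higher green-set bound fraction", {
  # reactivation is state-dependent: green-reactivated molecules are drawn
  # bound-enriched, violet-reactivated molecules from the bulk
  shift_into_block <- function(trajs, start_frame) {
    trajs |>
      dplyr::group_by(.data$trajectory) |>
      dplyr::mutate(frame = .data$frame - min(.data$frame) + start_frame) |>
      dplyr::ungroup()
  }
  green_sim <- sim_two_state(seed = 86, cells_per_day = 10, mols = 60, p_bound = 0.7)
  violet_sim <- sim_two_state(seed = 87, cells_per_day = 10, mols = 60, p_bound = 0.2)
  g <- shift_into_block(green_sim$trajectories, 95L)
  v <- shift_into_block(violet_sim$trajectories, 35L)
  v$trajectory <- v$trajectory + max(g$trajectory)
  seg <- segregate_papa_trajectories(dplyr::bind_rows(g, v))
  fb_green <- bound_fraction(infer_spectrum(compute_jumps(seg$green)))
  fb_violet <- bound_fraction(infer_spectrum(compute_jumps(seg$violet)))
  expect_gt(fb_green, fb_violet)
})
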