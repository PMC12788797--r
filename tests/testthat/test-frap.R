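noiseless_cfg <- function(...) {
  frap_sim_config(noise_sd = 0, obs_bleach_rate = 0, ...)
}

test_that("isodata threshold is the intermeans fixed point", {
  expect_equal(isodata_threshold(c(rep(10, 70), rep(100, 30))), 55)
  expect_true(is.na(isodata_threshold(rep(3, 10))))
})

test_that("nuclear mask recovers a known disk geometry", {
  cfg <- noiseless_cfg(n_post = 30, seed = 100)
  mv <- simulate_frap_movie(cfg)
  mask <- nuclear_mask(mv)
  # ground-truth disk at the image center
  px <- cfg$pixel_size
  coord <- (seq_len(cfg$size_px) - 0.5) * px
  ctr <- (cfg$size_px + 1) / 2 * px
  truth <- outer(coord, coord, function(y, x) sqrt((x - ctr)^2 + (y - ctr)^2)) <=
    cfg$nucleus_radius_um
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.95)

  flat <- mv
  flat$stack[] <- 7
  expect_error(nuclear_mask(flat), "no foreground")
})

test_that("background subtraction removes each frame's own background", {
  mv <- simulate_frap_movie(noiseless_cfg(n_post = 3, background = 0, seed = 101))
  mask <- nuclear_mask(mv)
  # add a frame-varying offset and check it is removed exactly
  offsets <- c(50, 60, 70)
  n_pre <- mv$bleach_frame - 1
  for (f in 1:3) mv$stack[, , n_pre + f] <- mv$stack[, , n_pre + f] + offsets[f]
  out <- background_subtract(mv, mask)
  for (f in 1:3) {
    expect_equal(median(out$stack[, , n_pre + f][!mask]), 0, tolerance = 1e-9)
  }
  expect_error(background_subtract(mv, matrix(TRUE, 64, 64)), "full frame")
})

test_that("photobleach correction anchors in-mask sums within each phase", {
  mv <- simulate_frap_movie(frap_sim_config(noise_sd = 0, obs_bleach_rate = 0.01,
                                            n_post = 40, seed = 102))
  mask <- nuclear_mask(mv)
  corr <- photobleach_correct(background_subtract(mv, mask), mask)
  sums <- vapply(seq_len(dim(corr$stack)[3]),
                 function(f) sum(corr$stack[, , f][mask]), numeric(1))
  b <- mv$bleach_frame
  expect_equal(sums[1:(b - 1)], rep(sums[b - 1], b - 1), tolerance = 1e-9)
  expect_equal(sums[b:length(sums)], rep(sums[b], length(sums) - b + 1),
               tolerance = 1e-9)
})

test_that("curve extraction round-trips the generating recovery function", {
  mv <- simulate_frap_movie(noiseless_cfg(n_post = 400, seed = 103))
  res <- analyze_frap_movie(mv)
  expect_true(all(abs(res$curve$value[res$curve$phase == "pre"] - 1) < 1e-9))
  truth <- function(t) 0.5 * (1 - exp(-t / 2)) + 0.3 * (1 - exp(-t / 30))
  expect_lt(max(abs(res$binned$value - truth(res$binned$time))), 1e-3)

  # full bleach with no recovery: post-bleach values sit at zero
  mv0 <- simulate_frap_movie(noiseless_cfg(A1 = 0, A2 = 0, n_post = 20, seed = 104))
  mask0 <- nuclear_mask(mv0)
  c0 <- extract_frap_curve(photobleach_correct(background_subtract(mv0, mask0), mask0),
                           mask0)
  expect_true(all(abs(c0$value[c0$phase == "post"]) < 1e-6))
})

test_that("log binning preserves values and caps the bin count", {
  mv <- simulate_frap_movie(noiseless_cfg(n_post = 600, seed = 105))
  mask <- nuclear_mask(mv)
  curve <- extract_frap_curve(photobleach_correct(background_subtract(mv, mask), mask),
                              mask)
  binned <- log_bin_resample(curve)
  expect_lte(nrow(binned), 100)
  expect_true(all(diff(binned$time) > 0))
  # each binned value lies within the range of its member samples
  post <- curve[curve$phase == "post", ]
  expect_true(all(binned$value >= min(post$value) - 1e-12 &
                    binned$value <= max(post$value) + 1e-12))

  # constant curve: every bin averages to the constant
  const <- tibble::tibble(time = seq(0.25, 100, by = 0.1), value = 0.7,
                          phase = "post")
  class(const) <- c("frap_curve", class(const))
  cb <- log_bin_resample(const)
  expect_true(all(cb$value == 0.7))

  # samples already one per bin pass through unchanged
  sparse <- tibble::tibble(time = exp(seq(log(0.3), log(90), length.out = 20)),
                           value = runif(20), phase = "post")
  class(sparse) <- c("frap_curve", class(sparse))
  sb <- log_bin_resample(sparse)
  expect_equal(sb$time, sparse$time)
  expect_equal(sb$value, sparse$value)
})

test_that("gradient-smoothing test separates reaction- from diffusion-type recovery", {
  mv_r <- simulate_frap_movie(noiseless_cfg(n_post = 30, seed = 106))
  mask <- nuclear_mask(mv_r)
  corr_r <- photobleach_correct(background_subtract(mv_r, mask), mask)
  gr <- gradient_smoothing_test(corr_r)
  expect_false(gr$flag)

  mv_d <- simulate_frap_movie(noiseless_cfg(recovery = "diffusion", D_frap = 0.2,
                                            n_post = 30, seed = 107))
  mask_d <- nuclear_mask(mv_d)
  corr_d <- photobleach_correct(background_subtract(mv_d, mask_d), mask_d)
  gd <- gradient_smoothing_test(corr_d)
  expect_true(gd$flag)

  g1 <- gradient_smoothing_test(corr_r, n_frames = 1)
  expect_true(is.na(g1$flag))
  expect_gt(nrow(g1$profiles), 0)
})

test_that("diffusion timescale follows r^2 / (4 D)", {
  expect_equal(diffusion_timescale(0.75, 2), 0.0703125)
  expect_equal(round(diffusion_timescale(0.75, 2) * 1000 / 10) * 10, 70)
  expect_equal(diffusion_timescale(1.5, 2), 4 * diffusion_timescale(0.75, 2))
  expect_lt(diffusion_timescale(0.75, 1e9), 1e-9)
})

test_that("exponential fits recover known parameters under constraints", {
  # single-exponential self-consistency
  c1 <- make_binned_curve(function(t) 0.8 * (1 - exp(-t / 5)))
  f1 <- fit_single_exp(c1)
  expect_equal(unname(f1$par["A"]), 0.8, tolerance = 1e-4)
  expect_equal(unname(f1$par["tau"]), 5, tolerance = 1e-4)

  # double-exponential self-consistency and model selection
  c2 <- make_binned_curve(function(t) 0.5 * (1 - exp(-t / 2)) + 0.3 * (1 - exp(-t / 30)))
  f2 <- fit_double_exp(c2)
  expect_equal(unname(f2$par), c(0.5, 2, 0.3, 30), tolerance = 1e-3)
  expect_lte(f2$par[["tau1"]], f2$par[["tau2"]])
  expect_gt(fit_single_exp(c2)$rss, f2$rss)

  # infeasible generating amplitudes: fit saturates at A1 + A2 = 1
  c3 <- make_binned_curve(function(t) 0.7 * (1 - exp(-t / 2)) + 0.5 * (1 - exp(-t / 30)))
  f3 <- fit_double_exp(c3)
  expect_equal(f3$par[["A1"]] + f3$par[["A2"]], 1, tolerance = 1e-6)

  # unbinned curves are rejected by default
  raw <- tibble::tibble(time = 1:20, value = runif(20))
  expect_error(fit_single_exp(raw), "log-binned")
})
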