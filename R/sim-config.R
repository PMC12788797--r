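#' Configuration for the SMT trajectory simulator
#'
#' Defines the ground-truth mixture of Brownian states and the acquisition
#' model used by [simulate_smt_dataset()]: molecules diffuse in 3-D, are
#' localized with Gaussian error, are only detected while inside a finite
#' axial slab, photobleach with a geometric lifetime, and photoactivate at
#' uniformly random frames across the movie.
#'
#' Between-cell and between-day heterogeneity is modelled on the bound-state
#' weight: the summed weight of states with `D < 0.1` is perturbed per day by
#' `N(0, day_sd)` and per cell by `N(0, cell_sd)` (clipped to (0, 1)), with
#' the relative weights inside the bound and free groups preserved. Live-cell
#' SMT data show cell-to-cell variance far in excess of day-to-day variance,
#' so the defaults make the cell term dominant.
#'
#' @param states data frame with columns `D` (diffusion coefficient,
#'   um^2/s) and `weight` (occupation fraction, summing to 1). Default is a
#'   two-state chromatin-binding mixture: 30% bound at D = 0.005 and 70%
#'   free at D = 2.
#' @param sigma_loc localization error, um (1 s.d. per coordinate).
#' @param frame_interval frame interval, s.
#' @param focal_depth full thickness of the axial detection slab, um.
#' @param bleach_mean_frames expected fluorophore lifetime, frames.
#' @param n_frames movie length, frames.
#' @param n_days,cells_per_day dataset structure.
#' @param mean_mols_per_cell Poisson mean of molecules per cell.
#' @param fov_size field-of-view side length, um (reflecting boundaries).
#' @param cell_sd,day_sd s.d. of the per-cell / per-day perturbation of the
#'   bound-state weight (0 disables).
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return A list of class `smt_sim_config`.
#' @export
#' @examples
#' cfg <- smt_sim_config(cells_per_day = 2, mean_mols_per_cell = 20)
#' sim <- simulate_smt_dataset(cfg)
#' head(sim$trajectories)
smt_sim_config <- function(states = data.frame(D = c(0.005, 2), weight = c(0.3, 0.7)),
                           sigma_loc = 0.03,
                           frame_interval = 0.00748,
                           focal_depth = 0.7,
                           bleach_mean_frames = 8,
                           n_frames = 1200,
                           n_days = 2,
                           cells_per_day = 10,
                           mean_mols_per_cell = 60,
                           fov_size = 10,
                           cell_sd = 0.05,
                           day_sd = 0.005,
                           seed = NULL) {
  states <- as.data.frame(states)
  assert_columns(states, c("D", "weight"), "states")
  if (nrow(states) == 0) abort("states must contain at least one state")
  if (any(states$D < 0)) abort("diffusion coefficients must be >= 0")
  if (any(states$weight < 0) || sum(states$weight) <= 0) {
    abort("state weights must be >= 0 with a positive sum")
  }
  if (abs(sum(states$weight) - 1) > 1e-9) {
    abort("state weights must sum to 1")
  }
  if (sigma_loc < 0) abort("sigma_loc must be >= 0")
  if (frame_interval <= 0) abort("frame_interval must be > 0")
  if (focal_depth <= 0) abort("focal_depth must be > 0")
  if (bleach_mean_frames < 1) abort("bleach_mean_frames must be >= 1")

  structure(list(states = tibble::as_tibble(states), sigma_loc = sigma_loc,
                 frame_interval = frame_interval, focal_depth = focal_depth,
                 bleach_mean_frames = bleach_mean_frames, n_frames = as.integer(n_frames),
                 n_days = as.integer(n_days), cells_per_day = as.integer(cells_per_day),
                 mean_mols_per_cell = mean_mols_per_cell, fov_size = fov_size,
                 cell_sd = cell_sd, day_sd = day_sd, seed = seed),
            class = "smt_sim_config")
}

#' @export
print.smt_sim_config <- function(x, ...) {
  cat("<smt_sim_config>\n")
  cat(sprintf("  %d state(s): D = %s um^2/s, weights = %s\n",
              nrow(x$states), paste(signif(x$states$D, 3), collapse = "/"),
              paste(signif(x$states$weight, 3), collapse = "/")))
  cat(sprintf("  dt = %g s, sigma_loc = %g um, slab = %g um, bleach mean = %g frames\n",
              x$frame_interval, x$sigma_loc, x$focal_depth, x$bleach_mean_frames))
  cat(sprintf("  %d day(s) x %d cell(s), ~%g molecules/cell, %d frames\n",
              x$n_days, x$cells_per_day, x$mean_mols_per_cell, x$n_frames))
  invisible(x)
}

#' Configuration for the PAPA phase-count simulator
#'
#' Models per-cell reactivation tallies for the four saved readout phases of
#' a proximity-assisted photoactivation (PAPA) acquisition. Counts are
#' Poisson with per-cycle rates:
#' \itemize{
#'   \item spontaneous phases: `spont_rate`
#'   \item violet readout: `spont_rate + violet_rate` (direct reactivation)
#'   \item green readout: `spont_rate + control_ratio * violet_rate +
#'     interaction * green_rate`
#' }
#' so the expected corrected green-to-violet ratio is
#' `control_ratio + interaction * green_rate / violet_rate`: a non-interacting
#' control (`interaction = 0`) sits at `control_ratio`, and the excess above
#' that baseline is exactly linear in `interaction`.
#'
#' A per-cell log-normal brightness factor (s.d. `cell_lognorm_sd`) scales all
#' four rates together, mimicking expression-level differences; the corrected
#' ratio is invariant to it in expectation.
#'
#' @param n_cells cells per day.
#' @param n_days number of imaging days.
#' @param spont_rate,violet_rate,green_rate mean molecule counts per cycle.
#' @param interaction multiplier (>= 0) scaling green reactivation above the
#'   control baseline.
#' @param control_ratio expected corrected G/V ratio of a non-interacting
#'   control.
#' @param cycles number of illumination cycles per movie.
#' @param cell_lognorm_sd s.d. (log scale) of the per-cell brightness factor.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return A list of class `papa_sim_config`.
#' @export
papa_sim_config <- function(n_cells = 30, n_days = 2,
                            spont_rate = 10, violet_rate = 40, green_rate = 40,
                            interaction = 0.5, control_ratio = 0.25,
                            cycles = 5, cell_lognorm_sd = 0.3, seed = NULL) {
  for (r in c(spont_rate, violet_rate, green_rate, interaction, control_ratio)) {
    if (r < 0) abort("PAPA rates, interaction and control_ratio must be >= 0")
  }
  structure(list(n_cells = as.integer(n_cells), n_days = as.integer(n_days),
                 spont_rate = spont_rate, violet_rate = violet_rate,
                 green_rate = green_rate, interaction = interaction,
                 control_ratio = control_ratio, cycles = as.integer(cycles),
                 cell_lognorm_sd = cell_lognorm_sd, seed = seed),
            class = "papa_sim_config")
}

#' Expected corrected G/V ratio implied by a PAPA simulation config
#'
#' Deterministic function of the config: `control_ratio +
#' interaction * green_rate / violet_rate`.
#'
#' @param config a [papa_sim_config()].
#' @return A single number.
#' @export
papa_expected_ratio <- function(config) {
  stopifnot(inherits(config, "papa_sim_config"))
  if (config$violet_rate == 0) return(NA_real_)
  config$control_ratio + config$interaction * config$green_rate / config$violet_rate
}

#' Configuration for the FRAP movie simulator
#'
#' Ground truth for [simulate_frap_movie()]: a disk nucleus at unit plateau
#' intensity, a circular bleach spot whose intensity drops by `bleach_depth`
#' at the bleach frame and recovers as
#' `A1 * (1 - exp(-t/tau1)) + A2 * (1 - exp(-t/tau2))` of the bleached
#' amount, conservation of total nuclear intensity (recovered signal is drawn
#' from the rest of the nucleus), multiplicative observational photobleaching,
#' a constant background offset, and Gaussian pixel noise.
#'
#' `recovery = "diffusion"` instead relaxes a Gaussian bleach profile by free
#' diffusion (widening while refilling), the regime the gradient-smoothing
#' test is designed to flag.
#'
#' @param size_px image side, pixels.
#' @param pixel_size um per pixel.
#' @param nucleus_radius_um,spot_radius_um geometry, um. The bleach spot
#'   (default 0.75 um radius) must lie inside the nucleus.
#' @param spot_offset_um spot center offset from the nucleus center (x, y), um.
#' @param bleach_frame 1-based index of the first post-bleach frame; frames
#'   `1:(bleach_frame - 1)` are pre-bleach.
#' @param n_post number of post-bleach frames.
#' @param frame_interval frame interval, s.
#' @param A1,tau1,A2,tau2 recovery amplitudes (A1 + A2 <= 1) and time
#'   constants (s).
#' @param bleach_depth fraction of spot intensity removed by the bleach, in
#'   \[0, 1\].
#' @param background additive background level.
#' @param obs_bleach_rate observational photobleaching rate per frame
#'   (intensity is scaled by `exp(-rate * frame)`).
#' @param noise_sd Gaussian pixel noise s.d. (plateau intensity is 1).
#' @param recovery `"reaction"` (uniform spot refill; default) or
#'   `"diffusion"` (relaxing Gaussian profile).
#' @param D_frap diffusion coefficient for `recovery = "diffusion"`, um^2/s.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return A list of class `frap_sim_config`.
#' @export
frap_sim_config <- function(size_px = 64, pixel_size = 0.16,
                            nucleus_radius_um = 4, spot_radius_um = 0.75,
                            spot_offset_um = c(0, 0),
                            bleach_frame = 16, n_post = 400,
                            frame_interval = 0.25,
                            A1 = 0.5, tau1 = 2, A2 = 0.3, tau2 = 30,
                            bleach_depth = 1, background = 0.1,
                            obs_bleach_rate = 0.002, noise_sd = 0.02,
                            recovery = c("reaction", "diffusion"),
                            D_frap = 0.05, seed = NULL) {
  recovery <- match.arg(recovery)
  if (A1 < 0 || A2 < 0) abort("A1 and A2 must be >= 0")
  if (A1 + A2 > 1 + 1e-12) abort("A1 + A2 must be <= 1")
  if (tau1 <= 0 || tau2 <= 0) abort("tau1 and tau2 must be > 0")
  if (bleach_depth < 0 || bleach_depth > 1) abort("bleach_depth must be in [0, 1]")
  if (bleach_frame < 2) abort("bleach_frame must leave at least one pre-bleach frame")
  d <- sqrt(sum(spot_offset_um^2))
  if (d + spot_radius_um > nucleus_radius_um) {
    abort("bleach spot must lie entirely inside the nucleus")
  }
  half_fov <- size_px * pixel_size / 2
  if (nucleus_radius_um >= half_fov) abort("nucleus does not fit in the image")

  structure(list(size_px = as.integer(size_px), pixel_size = pixel_size,
                 nucleus_radius_um = nucleus_radius_um,
                 spot_radius_um = spot_radius_um, spot_offset_um = spot_offset_um,
                 bleach_frame = as.integer(bleach_frame), n_post = as.integer(n_post),
                 frame_interval = frame_interval,
                 A1 = A1, tau1 = tau1, A2 = A2, tau2 = tau2,
                 bleach_depth = bleach_depth, background = background,
                 obs_bleach_rate = obs_bleach_rate, noise_sd = noise_sd,
                 recovery = recovery, D_frap = D_frap, seed = seed),
            class = "frap_sim_config")
}
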