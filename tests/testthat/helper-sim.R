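# Shared fixture builders. All fixtures are generated in code at test time.

# A single-state dataset with negligible defocalization (very thick slab),
# convenient for checking jump statistics against closed forms.
sim_single_state <- function(D, seed, n_cells = 4, mols = 400,
                             sigma_loc = 0.03, focal_depth = 100,
                             bleach_mean = 20) {
  cfg <- smt_sim_config(states = data.frame(D = D, weight = 1),
                        sigma_loc = sigma_loc, focal_depth = focal_depth,
                        bleach_mean_frames = bleach_mean,
                        n_days = 1, cells_per_day = n_cells,
                        mean_mols_per_cell = mols, seed = seed)
  simulate_smt_dataset(cfg)
}

# The two-state chromatin-binding mixture at exactly the configured weights
# (no between-cell or between-day spread).
sim_two_state <- function(seed, cells_per_day = 25, mols = 60,
                          p_bound = 0.3, cell_sd = 0, day_sd = 0) {
  cfg <- smt_sim_config(states = data.frame(D = c(0.005, 2),
                                            weight = c(p_bound, 1 - p_bound)),
                        cells_per_day = cells_per_day,
                        mean_mols_per_cell = mols,
                        cell_sd = cell_sd, day_sd = day_sd, seed = seed)
  simulate_smt_dataset(cfg)
}

# Jump table straight from simulated trajectories (no QC filters).
sim_jumps <- function(sim) {
  compute_jumps(sim$trajectories)
}

# Minimal localization table builder.
make_locs <- function(frame, x, y, trajectory = NULL, cell_id = NULL) {
  out <- tibble::tibble(frame = as.integer(frame), x = x, y = y)
  if (!is.null(trajectory)) out$trajectory <- trajectory
  if (!is.null(cell_id)) out$cell_id <- cell_id
  out
}

# A binned FRAP curve built directly from a functional form (bypasses the
# imaging pipeline; used to test the fitters in isolation).
make_binned_curve <- function(f, t = exp(seq(log(0.25), log(100), length.out = 60))) {
  out <- tibble::tibble(time = t, value = f(t), n = 1L)
  class(out) <- c("frap_curve_binned", class(out))
  out
}
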