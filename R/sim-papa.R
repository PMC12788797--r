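#' Simulate per-cell PAPA reactivation counts
#'
#' Draws Poisson molecule tallies for the four saved readout phases of a
#' PAPA acquisition (spontaneous 1, violet readout, spontaneous 2, green
#' readout), summed over illumination cycles, for `n_cells` cells on each of
#' `n_days` days. See [papa_sim_config()] for the counting model; the
#' expected corrected G/V ratio implied by the config is attached as
#' attribute `expected_ratio` and is also available from
#' [papa_expected_ratio()].
#'
#' @param config a [papa_sim_config()].
#' @param condition label stored in the `condition` column.
#' @return A tibble with columns `condition`, `cell_id`, `day_id`,
#'   `n_spont1`, `n_violet`, `n_spont2`, `n_green`.
#' @export
#' @examples
#' counts <- simulate_papa_dataset(papa_sim_config(n_cells = 5, seed = 1))
#' counts
simulate_papa_dataset <- function(config, condition = "condition") {
  stopifnot(inherits(config, "papa_sim_config"))
  with_seed_if(config$seed, {
    n <- config$n_cells * config$n_days
    bright <- exp(rnorm(n, 0, config$cell_lognorm_sd))
    cyc <- config$cycles
    s <- config$spont_rate * bright * cyc
    v <- (config$spont_rate + config$violet_rate) * bright * cyc
    g <- (config$spont_rate +
            config$control_ratio * config$violet_rate +
            config$interaction * config$green_rate) * bright * cyc
    day <- rep(seq_len(config$n_days), each = config$n_cells)
    tibble::tibble(
      condition = condition,
      cell_id = sprintf("%s_day%02d_cell%03d", condition, day,
                        rep(seq_len(config$n_cells), config$n_days)),
      day_id = sprintf("day%02d", day),
      n_spont1 = rpois(n, s),
      n_violet = rpois(n, v),
      n_spont2 = rpois(n, s),
      n_green = rpois(n, g)) |>
      structure(expected_ratio = papa_expected_ratio(config))
  })
}
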