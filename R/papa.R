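#' Saved-frame phase map for a PAPA acquisition
#'
#' In a PAPA movie only the stroboscopic readout frames are saved; shelving
#' and reactivation-pulse frames are not. The saved stream therefore cycles
#' through four blocks of `frames_per_block` frames — spontaneous readout 1,
#' violet (direct-reactivation) readout, spontaneous readout 2, green (PAPA)
#' readout — repeated `cycles` times (default 4 x 30 x 5 = 600 saved
#' frames).
#'
#' @param frames_per_block saved frames per readout block.
#' @param blocks block labels, in acquisition order.
#' @param cycles number of cycle repeats.
#' @return A tibble of class `papa_phase_map` with columns `frame`
#'   (0-based saved-frame index), `phase`, `cycle` (0-based).
#' @export
#' @examples
#' pm <- build_phase_map()
#' pm[pm$frame == 35, ]  # violet readout, cycle 0
build_phase_map <- function(frames_per_block = 30,
                            blocks = c("spont1", "violet_readout",
                                       "spont2", "papa_readout"),
                            cycles = 5) {
  n <- frames_per_block * length(blocks) * cycles
  map <- tibble::tibble(
    frame = seq_len(n) - 1L,
    phase = rep(rep(blocks, each = frames_per_block), cycles),
    cycle = rep(seq_len(cycles) - 1L, each = frames_per_block * length(blocks)))
  class(map) <- c("papa_phase_map", class(map))
  map
}

# Phase labels for saved-frame indices; errors outside the mapped range.
phase_of_frame <- function(frame, phase_map) {
  idx <- match(frame, phase_map$frame)
  if (anyNA(idx)) {
    abort(sprintf("saved-frame index %s outside the phase map (0..%d)",
                  frame[which(is.na(idx))[1]], max(phase_map$frame)))
  }
  phase_map$phase[idx]
}

#' Tally reactivated molecules per readout phase and cell
#'
#' A reactivated molecule is one new trajectory; each trajectory is tallied
#' to the phase containing its first localization (a trajectory spanning a
#' phase boundary counts once, in its starting phase). Counts are summed
#' over cycles. Cells with no trajectories in some phase get explicit zero
#' counts.
#'
#' @param trajs data frame with columns `frame` (saved-frame index),
#'   `trajectory`, `cell_id` and optionally `day_id`.
#' @param phase_map a [build_phase_map()].
#' @return A tibble with one row per cell: `cell_id`, (`day_id`,)
#'   `n_spont1`, `n_violet`, `n_spont2`, `n_green`.
#' @export
count_reactivations <- function(trajs, phase_map = build_phase_map()) {
  assert_columns(trajs, c("frame", "trajectory", "cell_id"), "trajs")
  trajs <- tibble::as_tibble(trajs)
  keep <- intersect(c("cell_id", "day_id"), names(trajs))
  firsts <- trajs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keep, "trajectory")))) |>
    dplyr::summarise(frame = min(.data$frame), .groups = "drop")
  firsts$phase <- phase_of_frame(firsts$frame, phase_map)
  col_of <- c(spont1 = "n_spont1", violet_readout = "n_violet",
              spont2 = "n_spont2", papa_readout = "n_green")
  counts <- firsts |>
    dplyr::count(dplyr::across(dplyr::all_of(keep)), .data$phase) |>
    dplyr::mutate(phase = col_of[.data$phase]) |>
    tidyr::pivot_wider(names_from = "phase", values_from = "n", values_fill = 0L)
  for (cc in unname(col_of)) {
    if (!cc %in% names(counts)) counts[[cc]] <- 0L
  }
  counts[, c(keep, unname(col_of))]
}

#' Spontaneous-corrected green-to-violet ratio per cell
#'
#' Subtracts the matched spontaneous-readout tallies from the violet and
#' green tallies and forms the corrected ratio
#' `(n_green - n_spont2) / (n_violet - n_spont1)`. Negative excesses are
#' floored at zero before division; cells whose floored violet excess is
#' zero have no direct-reactivation signal to normalize against and get a
#' missing ratio (they are excluded from any aggregation).
#'
#' @param counts tibble from [count_reactivations()] (columns `n_spont1`,
#'   `n_violet`, `n_spont2`, `n_green`).
#' @return `counts` with columns `green_excess`, `violet_excess` and
#'   `gv_ratio` (NA where undefined) appended.
#' @export
#' @examples
#' corrected_gv_ratio(tibble::tibble(n_spont1 = 10, n_violet = 50,
#'                                   n_spont2 = 10, n_green = 30))$gv_ratio  # 0.5
corrected_gv_ratio <- function(counts) {
  assert_columns(counts, c("n_spont1", "n_violet", "n_spont2", "n_green"), "counts")
  counts <- tibble::as_tibble(counts)
  counts$green_excess <- pmax(counts$n_green - counts$n_spont2, 0)
  counts$violet_excess <- pmax(counts$n_violet - counts$n_spont1, 0)
  counts$gv_ratio <- ifelse(counts$violet_excess > 0,
                            counts$green_excess / counts$violet_excess,
                            NA_real_)
  counts
}

# Aggregate corrected G/V ratio of a set of cells: computed on pooled
# (summed) counts, not as a mean of per-cell ratios.
pooled_gv_ratio <- function(counts) {
  g <- max(sum(counts$n_green) - sum(counts$n_spont2), 0)
  v <- max(sum(counts$n_violet) - sum(counts$n_spont1), 0)
  if (v == 0) NA_real_ else g / v
}

#' Normalize corrected G/V ratios to same-day controls
#'
#' Each experimental day's control cells (a construct with no expected
#' proximity partner) are pooled; their aggregate corrected G/V ratio is the
#' day's normalizer. Every experimental cell's corrected ratio is divided by
#' its own day's control aggregate. Days without control cells yield missing
#' normalized ratios (with a warning).
#'
#' @param counts per-cell counts of the condition of interest (see
#'   [count_reactivations()]); must carry `day_id`.
#' @param control_counts per-cell counts of the same-day control cells.
#' @return `counts` with `gv_ratio`, `control_ratio` (the day aggregate) and
#'   `normalized_ratio` appended; per-day control aggregates in attribute
#'   `control_aggregates`.
#' @export
normalize_to_control <- function(counts, control_counts) {
  assert_columns(counts, c("day_id", "n_spont1", "n_violet", "n_spont2", "n_green"),
                 "counts")
  assert_columns(control_counts,
                 c("day_id", "n_spont1", "n_violet", "n_spont2", "n_green"),
                 "control_counts")
  agg <- control_counts |>
    dplyr::group_by(.data$day_id) |>
    dplyr::summarise(control_ratio = pooled_gv_ratio(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
  counts <- corrected_gv_ratio(counts)
  missing_days <- setdiff(unique(counts$day_id), agg$day_id)
  if (length(missing_days) > 0) {
    warn(sprintf("no control cells for day(s): %s; their ratios are missing",
                 paste(missing_days, collapse = ", ")))
  }
  out <- dplyr::left_join(counts, agg, by = "day_id")
  out$normalized_ratio <- out$gv_ratio / out$control_ratio
  attr(out, "control_aggregates") <- agg
  out
}

#' Bootstrap confidence interval for the normalized PAPA ratio
#'
#' The condition-level normalized G/V ratio and its 95% CI. Each trial
#' resamples the condition's n cells with replacement (control aggregates
#' stay fixed), pools the resampled counts within each day, forms the
#' day-wise corrected ratio normalized by that day's control aggregate, and
#' combines days by weighting with the pooled violet-excess counts. The
#' point estimate applies the same combination to the original cells.
#'
#' @param counts per-cell condition counts with `day_id`.
#' @param control_counts per-cell same-day control counts.
#' @param n_trials bootstrap trials.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @param min_success minimum successful trials.
#' @return A list of class `papa_result`: `estimate`, `trials`, `mean`,
#'   `sd`, `ci_low`, `ci_high`, `n_cells`, `control_aggregates`.
#' @export
papa_bootstrap <- function(counts, control_counts, n_trials = 96, seed = NULL,
                           min_success = ceiling(0.9375 * n_trials)) {
  counts <- tibble::as_tibble(counts)
  agg <- attr(normalize_to_control(counts, control_counts), "control_aggregates")

  combined_ratio <- function(cells) {
    day <- cells |>
      dplyr::group_by(.data$day_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(
        c("n_spont1", "n_violet", "n_spont2", "n_green")), sum), .groups = "drop") |>
      corrected_gv_ratio() |>
      dplyr::inner_join(agg, by = "day_id")
    day <- day[!is.na(day$gv_ratio) & !is.na(day$control_ratio) &
                 day$control_ratio > 0 & day$violet_excess > 0, ]
    if (nrow(day) == 0) return(NA_real_)
    sum(day$violet_excess * day$gv_ratio / day$control_ratio) / sum(day$violet_excess)
  }

  n <- nrow(counts)
  if (n < 1) abort("need at least one cell")
  trials <- with_seed_if(seed, {
    vapply(seq_len(n_trials), function(i) {
      combined_ratio(counts[sample.int(n, n, replace = TRUE), ])
    }, numeric(1))
  })
  n_ok <- sum(!is.na(trials))
  if (n_ok < min_success) {
    abort(sprintf("only %d of %d PAPA bootstrap trials succeeded (need >= %d)",
                  n_ok, n_trials, min_success))
  }
  ok <- trials[!is.na(trials)]
  ci <- quantile(ok, c(0.025, 0.975), names = FALSE)
  structure(list(estimate = combined_ratio(counts), trials = trials,
                 mean = mean(ok), sd = sd(ok),
                 ci_low = ci[1], ci_high = ci[2],
                 n_cells = n, control_aggregates = agg),
            class = "papa_result")
}

#' @export
print.papa_result <- function(x, ...) {
  cat("<papa_result>\n")
  cat(sprintf("  normalized G/V ratio %.3f; 95%% CI [%.3f, %.3f] (%d cells, %d trials)\n",
              x$estimate, x$ci_low, x$ci_high, x$n_cells, length(x$trials)))
  invisible(x)
}

#' @method glance papa_result
#' @export
glance.papa_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, mean = x$mean, sd = x$sd,
                 ci_low = x$ci_low, ci_high = x$ci_high, n_cells = x$n_cells)
}

#' Segregate trajectories by the reactivation pulse that produced them
#'
#' Trajectories starting in a green (PAPA) readout block report molecules
#' reactivated by proximity to the sender fluorophore; those starting in a
#' violet readout block report directly reactivated molecules. Trajectories
#' starting in a spontaneous block are discarded. Each returned set can feed
#' [infer_spectrum()] independently to compare the diffusive behaviour of
#' proximal vs bulk molecules.
#'
#' @param trajs data frame with columns `frame`, `trajectory` (plus any
#'   labels, preserved).
#' @param phase_map a [build_phase_map()].
#' @return A list with tibbles `green` and `violet`.
#' @export
segregate_papa_trajectories <- function(trajs, phase_map = build_phase_map()) {
  assert_columns(trajs, c("frame", "trajectory"), "trajs")
  trajs <- tibble::as_tibble(trajs)
  first_phase <- trajs |>
    dplyr::group_by(.data$trajectory) |>
    dplyr::summarise(first_frame = min(.data$frame), .groups = "drop")
  first_phase$phase <- phase_of_frame(first_phase$first_frame, phase_map)
  lab <- setNames(first_phase$phase, first_phase$trajectory)
  ph <- lab[as.character(trajs$trajectory)]
  list(green = trajs[ph == "papa_readout", , drop = FALSE],
       violet = trajs[ph == "violet_readout", , drop = FALSE])
}
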