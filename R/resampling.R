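#' Cell-wise bootstrap of an arbitrary scalar statistic
#'
#' For a dataset of n cells, each trial resamples n cells with replacement,
#' pools their rows, and evaluates `statistic` on the pool. Reported are the
#' point estimate (statistic of the full dataset), the per-trial values,
#' their mean and s.d., and a percentile 95% confidence interval
#' (2.5/97.5%, linearly interpolated). When the same cell is drawn more than
#' once its `trajectory` ids (if present) are suffixed per copy so that
#' downstream segmenting treats copies as distinct trajectories.
#'
#' A trial whose statistic errors or returns a non-finite value is recorded
#' as missing; at least `min_success` successful trials are required.
#'
#' @param data data frame with a `cell_id` column.
#' @param statistic function mapping a data frame to a single number.
#' @param n_trials number of bootstrap trials.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @param min_success minimum successful trials (default ~94% of
#'   `n_trials`, i.e. 90 of 96).
#' @return A list of class `bootstrap_result` with `estimate`, `trials`,
#'   `mean`, `sd`, `ci_low`, `ci_high`, `n_cells`, `n_trials`.
#' @export
#' @examples
#' df <- tibble::tibble(cell_id = rep(c("a", "b"), each = 5), v = 1:10)
#' cellwise_bootstrap(df, function(d) mean(d$v), n_trials = 20, seed = 1)
cellwise_bootstrap <- function(data, statistic, n_trials = 96, seed = NULL,
                               min_success = ceiling(0.9375 * n_trials)) {
  assert_columns(data, "cell_id", "data")
  cells <- unique(data$cell_id)
  if (length(cells) < 1) abort("need at least one cell")
  pieces <- split(tibble::as_tibble(data), factor(data$cell_id, levels = cells))
  has_traj <- "trajectory" %in% names(data)

  trial_values <- with_seed_if(seed, {
    vapply(seq_len(n_trials), function(trial) {
      take <- sample.int(length(cells), length(cells), replace = TRUE)
      pool <- dplyr::bind_rows(purrr::imap(pieces[take], function(piece, copy) {
        if (has_traj) {
          piece$trajectory <- paste0(piece$trajectory, ".", copy)
        }
        piece
      }))
      val <- tryCatch(statistic(pool), error = function(e) NA_real_)
      if (length(val) != 1 || !is.finite(val)) NA_real_ else as.numeric(val)
    }, numeric(1))
  })

  n_ok <- sum(!is.na(trial_values))
  if (n_ok < min_success) {
    abort(sprintf("only %d of %d bootstrap trials succeeded (need >= %d)",
                  n_ok, n_trials, min_success))
  }
  ok <- trial_values[!is.na(trial_values)]
  ci <- quantile(ok, c(0.025, 0.975), names = FALSE)
  structure(list(estimate = statistic(tibble::as_tibble(data)),
                 trials = trial_values,
                 mean = mean(ok), sd = sd(ok),
                 ci_low = ci[1], ci_high = ci[2],
                 n_cells = length(cells), n_trials = n_trials),
            class = "bootstrap_result")
}

#' Fast cell-wise bootstrap of the spectrum bound fraction
#'
#' Specialized path for the statistic used throughout SMT figures: the
#' chromatin-bound fraction of the inferred diffusion spectrum. The
#' per-segment likelihood matrix is computed once; each trial reweights
#' segments by the resampled cell multiplicities and re-runs the EM. Trials
#' optionally warm-start from the full-data occupations, which shortens the
#' EM path without changing its fixed point.
#'
#' @param jumps jump table with columns `r`, `trajectory`, `cell_id`.
#' @param grid a [diffusion_grid()].
#' @param splitsize maximum jumps per segment.
#' @param threshold bound-fraction cutoff, um^2/s.
#' @param n_trials number of bootstrap trials.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @param dt_total defocalization-correction residence time, s (default one
#'   frame interval).
#' @param tol,max_iter EM controls for the full-data fit, matching
#'   [infer_spectrum()] so the point estimate is identical.
#' @param trial_tol relative log-likelihood tolerance for the per-trial EMs.
#'   Trial statistics feed a percentile CI read at ~0.005 resolution, so the
#'   trials stop earlier than the full-data fit; with the warm start this
#'   changes trial values by well under the CI granularity.
#' @param warm_start start trials from the full-data occupations.
#' @return A `bootstrap_result` (see [cellwise_bootstrap()]).
#' @export
bootstrap_bound_fraction <- function(jumps, grid = diffusion_grid(),
                                     splitsize = 3, threshold = 0.1,
                                     n_trials = 96, seed = NULL,
                                     dt_total = NULL,
                                     tol = 1e-8, max_iter = 1000,
                                     trial_tol = 1e-6,
                                     warm_start = TRUE) {
  assert_columns(jumps, c("r", "trajectory", "cell_id"), "jumps")
  if (nrow(jumps) == 0) abort("empty jump table")
  jumps <- split_trajectories(jumps, splitsize)
  strata <- stratified_loglik_matrices(jumps, grid)
  K <- length(grid$D)
  cells <- unique(jumps$cell_id)
  # the cell owning each segment, per stratum (segments sorted as in the matrices)
  seg_cell_all <- tapply(jumps$cell_id, jumps$segment, function(s) s[1])
  seg_cell_all <- seg_cell_all[order(as.integer(names(seg_cell_all)))]
  seg_ids <- as.integer(names(seg_cell_all))
  cell_of_seg <- lapply(strata, function(m) {
    match(seg_cell_all[match(m$segments, seg_ids)], cells)
  })

  dt_total <- dt_total %||% grid$frame_interval
  ret <- defocalization_retention(grid$D, dt_total, grid$focal_depth)
  bf_from_w <- function(w) {
    w <- w / ret
    sum((w / sum(w))[grid$D < threshold])
  }

  uniform <- rep(1 / K, K)
  # weighted stratified EM: returns the combined raw occupation vector
  fit_occ <- function(wgt_list, starts) {
    acc <- rep(0, K)
    tot <- 0
    for (s in seq_along(strata)) {
      wgt <- wgt_list[[s]]
      n_s <- sum(wgt)
      if (n_s == 0) next
      fit <- em_mixture_cpp(strata[[s]]$A, strata[[s]]$offset, as.numeric(wgt),
                            starts[[s]], trial_tol, as.integer(max_iter))
      acc <- acc + n_s * fit$occupations
      tot <- tot + n_s
    }
    acc / tot
  }

  ones <- lapply(strata, function(m) rep(1, ncol(m$A)))
  unif_starts <- lapply(strata, function(m) uniform)
  full_by_stratum <- lapply(seq_along(strata), function(s) {
    em_mixture_cpp(strata[[s]]$A, strata[[s]]$offset, ones[[s]],
                   uniform, tol, as.integer(max_iter))$occupations
  })
  full_occ <- {
    acc <- rep(0, K); tot <- 0
    for (s in seq_along(strata)) {
      n_s <- ncol(strata[[s]]$A)
      acc <- acc + n_s * full_by_stratum[[s]]
      tot <- tot + n_s
    }
    acc / tot
  }
  starts <- if (warm_start) full_by_stratum else unif_starts

  trial_values <- with_seed_if(seed, {
    vapply(seq_len(n_trials), function(trial) {
      take <- sample.int(length(cells), length(cells), replace = TRUE)
      mult <- tabulate(take, nbins = length(cells))
      bf_from_w(fit_occ(lapply(cell_of_seg, function(cs) mult[cs]), starts))
    }, numeric(1))
  })

  ci <- quantile(trial_values, c(0.025, 0.975), names = FALSE)
  structure(list(estimate = bf_from_w(full_occ),
                 trials = trial_values,
                 mean = mean(trial_values), sd = sd(trial_values),
                 ci_low = ci[1], ci_high = ci[2],
                 n_cells = length(cells), n_trials = n_trials),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result>\n")
  cat(sprintf("  estimate %.4f; %d trials over %d cells: mean %.4f, sd %.4f\n",
              x$estimate, x$n_trials, x$n_cells, x$mean, x$sd))
  cat(sprintf("  95%% CI [%.4f, %.4f]\n", x$ci_low, x$ci_high))
  invisible(x)
}

#' @method tidy bootstrap_result
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(trial = seq_along(x$trials), value = x$trials)
}

#' @method glance bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, mean = x$mean, sd = x$sd,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_cells = x$n_cells, n_trials = x$n_trials)
}

#' Three-scheme variance decomposition of jump data
#'
#' Quantifies where the variance of a jump statistic comes from by
#' subsampling `n` jumps `n_trials` times under three schemes and recording
#' the s.d. of the trial statistics:
#' \describe{
#'   \item{pool}{n jumps from the entire pool — the law-of-large-numbers
#'     baseline, s.d. falling as `n^-1/2`.}
#'   \item{cell}{pick one cell uniformly, then n jumps (with replacement)
#'     from that cell only — plateaus at the between-cell spread.}
#'   \item{day}{pick one imaging day uniformly, then n jumps from that day —
#'     plateaus at the between-day spread.}
#' }
#' Where the cell or day curve detaches upward from the pool curve, that
#' level of the hierarchy contributes variance beyond counting noise.
#' Cells or days with zero jumps are excluded from selection.
#'
#' @param jumps jump table with columns `r`, `cell_id`, `day_id`.
#' @param statistic function mapping a numeric vector of jump lengths to a
#'   scalar; default mean jump length.
#' @param n_values subsample sizes.
#' @param n_trials trials per (scheme, n).
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return A tibble of class `variance_curves` with columns `scheme`, `n`,
#'   `sd`, `mean`.
#' @export
variance_decomposition <- function(jumps,
                                   statistic = mean,
                                   n_values = round(10^seq(0.5, 3.5, by = 0.5)),
                                   n_trials = 1000, seed = NULL) {
  assert_columns(jumps, c("r", "cell_id", "day_id"), "jumps")
  if (nrow(jumps) == 0) abort("empty jump table")
  r <- jumps$r
  by_cell <- split(r, jumps$cell_id)
  by_day <- split(r, jumps$day_id)
  by_cell <- by_cell[lengths(by_cell) > 0]
  by_day <- by_day[lengths(by_day) > 0]

  draw <- function(groups, n) {
    g <- groups[[sample.int(length(groups), 1)]]
    statistic(g[sample.int(length(g), n, replace = TRUE)])
  }

  with_seed_if(seed, {
    res <- purrr::map_dfr(n_values, function(n) {
      pool_vals <- vapply(seq_len(n_trials), function(i)
        statistic(r[sample.int(length(r), n, replace = TRUE)]), numeric(1))
      cell_vals <- vapply(seq_len(n_trials), function(i)
        draw(by_cell, n), numeric(1))
      day_vals <- vapply(seq_len(n_trials), function(i)
        draw(by_day, n), numeric(1))
      tibble::tibble(scheme = c("pool", "cell", "day"),
                     n = n,
                     sd = c(sd(pool_vals), sd(cell_vals), sd(day_vals)),
                     mean = c(mean(pool_vals), mean(cell_vals), mean(day_vals)))
    })
    class(res) <- c("variance_curves", class(res))
    res
  })
}
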