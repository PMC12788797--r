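#' Link localizations into trajectories by greedy nearest-neighbor matching
#'
#' Links localizations between consecutive frames, closest pairs first, with
#' links longer than `search_radius` forbidden. With `max_blinks = 0` (the
#' only supported value, matching the tracking settings used for fast SMT
#' movies) a one-frame gap terminates a trajectory. Ties at equal distance
#' are resolved in favor of the lowest localization index, making the result
#' deterministic. Linking is performed independently within each
#' `cell_id`/`day_id` group when those columns are present.
#'
#' @param locs data frame with columns `frame`, `x`, `y` (um) and optionally
#'   `cell_id`, `day_id`.
#' @param search_radius maximum link length, um.
#' @param max_blinks allowed detection gap within a trajectory; only 0 is
#'   supported.
#' @return A tibble like `locs` with a `trajectory` integer column added.
#' @export
#' @examples
#' locs <- tibble::tibble(frame = c(0L, 1L, 2L), x = c(0, 0.3, 0.6), y = 0)
#' link_localizations(locs)
link_localizations <- function(locs, search_radius = 1.0, max_blinks = 0) {
  if (search_radius < 0) abort("search_radius must be >= 0")
  if (max_blinks != 0) abort("only max_blinks = 0 is supported")
  assert_columns(locs, c("frame", "x", "y"), "locs")
  locs <- tibble::as_tibble(locs)
  if (nrow(locs) == 0) {
    locs$trajectory <- integer()
    return(locs)
  }
  grp_cols <- intersect(c("cell_id", "day_id"), names(locs))
  if (length(grp_cols) == 0) {
    locs$trajectory <- link_one_group(locs, search_radius)
    return(locs)
  }
  key <- do.call(paste, c(locs[grp_cols], sep = "\r"))
  out <- vector("list", length(unique(key)))
  offset <- 0L
  pieces <- split(seq_len(nrow(locs)), key)
  traj <- integer(nrow(locs))
  for (idx in pieces) {
    t <- link_one_group(locs[idx, ], search_radius)
    traj[idx] <- t + offset
    offset <- offset + max(t)
  }
  locs$trajectory <- traj
  locs
}

# Greedy frame-to-frame linker for one group; returns 1-based trajectory ids
# in input row order.
link_one_group <- function(locs, search_radius) {
  n <- nrow(locs)
  ord <- order(locs$frame, seq_len(n))
  frame <- locs$frame[ord]
  x <- locs$x[ord]
  y <- locs$y[ord]
  traj <- integer(n)
  next_id <- 0L
  frames <- unique(frame)
  prev_idx <- which(frame == frames[1])
  traj[prev_idx] <- seq_along(prev_idx)
  next_id <- length(prev_idx)
  if (length(frames) > 1) {
    for (fi in 2:length(frames)) {
      cur_idx <- which(frame == frames[fi])
      if (frames[fi] - frames[fi - 1] == 1) {
        # candidate links sorted by distance, ties by (prev index, cur index)
        d <- outer(x[prev_idx], x[cur_idx], `-`)^2 +
          outer(y[prev_idx], y[cur_idx], `-`)^2
        cand <- which(d <= search_radius^2, arr.ind = TRUE)
        if (length(cand) > 0) {
          o <- order(d[cand], cand[, 1], cand[, 2])
          used_prev <- logical(length(prev_idx))
          used_cur <- logical(length(cur_idx))
          for (ci in o) {
            i <- cand[ci, 1]; j <- cand[ci, 2]
            if (!used_prev[i] && !used_cur[j]) {
              used_prev[i] <- TRUE
              used_cur[j] <- TRUE
              traj[cur_idx[j]] <- traj[prev_idx[i]]
            }
          }
        }
      }
      unlinked <- cur_idx[traj[cur_idx] == 0L]
      if (length(unlinked) > 0) {
        traj[unlinked] <- next_id + seq_along(unlinked)
        next_id <- next_id + length(unlinked)
      }
      prev_idx <- cur_idx
    }
  }
  out <- integer(n)
  out[ord] <- traj
  # renumber to consecutive ids in order of first appearance
  match(out, unique(out[ord]))
}

#' Keep only trajectories lying entirely within a single nuclear mask
#'
#' Trajectories with any localization outside every mask, or with
#' localizations in two different masks, are dropped; survivors inherit the
#' mask label as `cell_id`. Masks are given as a labeled integer matrix
#' (0 = background) indexed as `mask[row, col]` with `row ~ y`, `col ~ x`;
#' coordinates in um are rasterized at `pixel_size`.
#'
#' @param locs data frame with columns `trajectory`, `x`, `y` (um).
#' @param masks labeled integer matrix.
#' @param pixel_size um per mask pixel.
#' @return A tibble of surviving localizations with `cell_id` set to the
#'   mask label (as character).
#' @export
assign_to_masks <- function(locs, masks, pixel_size = 0.16) {
  assert_columns(locs, c("trajectory", "x", "y"), "locs")
  if (!is.matrix(masks)) abort("masks must be a labeled integer matrix")
  locs <- tibble::as_tibble(locs)
  if (nrow(locs) == 0) {
    locs$cell_id <- character()
    return(locs)
  }
  col <- floor(locs$x / pixel_size) + 1L
  row <- floor(locs$y / pixel_size) + 1L
  inside <- row >= 1 & row <= nrow(masks) & col >= 1 & col <= ncol(masks)
  lab <- rep(0L, nrow(locs))
  lab[inside] <- masks[cbind(row[inside], col[inside])]
  keep <- locs |>
    dplyr::mutate(.lab = lab) |>
    dplyr::group_by(.data$trajectory) |>
    dplyr::filter(all(.data$.lab > 0) && dplyr::n_distinct(.data$.lab) == 1) |>
    dplyr::ungroup()
  keep$cell_id <- as.character(keep$.lab)
  keep$.lab <- NULL
  keep
}

#' Truncate dense frames from the start of each cell's movie
#'
#' For every cell whose movie contains frames with more than `max_per_frame`
#' localizations, removes the smallest prefix of frames such that all
#' remaining frames have at most `max_per_frame` localizations. Truncation is
#' strictly a prefix: an early dense burst costs all frames up to and
#' including the last offending frame, even if compliant frames precede it.
#' Trajectories losing points are implicitly re-split at the cut (the
#' surviving tail keeps its id and remains consecutive in frame).
#'
#' @param locs data frame with columns `frame`, `trajectory` and (optionally)
#'   `cell_id`; applied per cell when `cell_id` is present.
#' @param max_per_frame maximum tolerated localizations per frame (the QC
#'   rule "fewer than seven" corresponds to the default 6).
#' @return A tibble with offending prefixes removed.
#' @export
truncate_dense_frames <- function(locs, max_per_frame = 6) {
  assert_columns(locs, c("frame", "trajectory"), "locs")
  locs <- tibble::as_tibble(locs)
  if (nrow(locs) == 0) return(locs)
  grp <- if ("cell_id" %in% names(locs)) locs$cell_id else rep("", nrow(locs))
  keep <- unlist(lapply(split(seq_len(nrow(locs)), grp), function(idx) {
    fr <- locs$frame[idx]
    counts <- table(fr)
    over <- as.integer(names(counts))[counts > max_per_frame]
    if (length(over) == 0) return(idx)
    idx[fr > max(over)]
  }), use.names = FALSE)
  locs[sort(keep), ]
}

#' Drop cells with fewer than a minimum number of displacements
#'
#' Displacements are consecutive-frame jumps within trajectories, counted
#' after all other filters. Cells below the threshold are removed and listed
#' in the `dropped_cells` attribute.
#'
#' @param locs data frame with columns `frame`, `trajectory`, `cell_id`.
#' @param min_disp minimum displacement count for a cell to be retained
#'   (cells with exactly `min_disp` are kept).
#' @return A tibble restricted to retained cells, with attribute
#'   `dropped_cells`.
#' @export
filter_min_displacements <- function(locs, min_disp = 100) {
  assert_columns(locs, c("frame", "trajectory", "cell_id"), "locs")
  locs <- tibble::as_tibble(locs)
  if (nrow(locs) == 0) return(structure(locs, dropped_cells = character()))
  counts <- compute_jumps(locs) |> dplyr::count(.data$cell_id)
  all_cells <- unique(locs$cell_id)
  kept <- counts$cell_id[counts$n >= min_disp]
  dropped <- setdiff(all_cells, kept)
  structure(locs[locs$cell_id %in% kept, ], dropped_cells = dropped)
}

#' Apply the full trajectory QC filter chain
#'
#' Convenience wrapper running, in order: mask assignment (optional),
#' dense-frame truncation, and the minimum-displacement cell filter. The
#' chain is idempotent.
#'
#' @param locs localization table with `trajectory` ids (see
#'   [link_localizations()]).
#' @param masks optional labeled mask matrix for [assign_to_masks()].
#' @param pixel_size um per mask pixel.
#' @param max_per_frame,min_disp filter thresholds.
#' @return A filtered tibble.
#' @export
filter_trajectories <- function(locs, masks = NULL, pixel_size = 0.16,
                                max_per_frame = 6, min_disp = 100) {
  if (!is.null(masks)) locs <- assign_to_masks(locs, masks, pixel_size)
  locs |>
    truncate_dense_frames(max_per_frame = max_per_frame) |>
    filter_min_displacements(min_disp = min_disp)
}

#' Compute single-lag jumps from a trajectory table
#'
#' One record per consecutive-frame pair within each trajectory;
#' `r` is the 2-D Euclidean displacement in um and `dt` the frame interval.
#'
#' @param trajs data frame with columns `frame`, `trajectory`, `x`, `y` and
#'   optionally `cell_id`, `day_id`.
#' @param frame_interval frame interval, s.
#' @return A tibble with columns `r`, `dt`, `trajectory` and any cell/day
#'   labels present.
#' @export
#' @examples
#' tr <- tibble::tibble(frame = 0:1, trajectory = 1L, x = c(0, 0.3), y = c(0, 0.4))
#' compute_jumps(tr)$r  # 0.5
compute_jumps <- function(trajs, frame_interval = 0.00748) {
  assert_columns(trajs, c("frame", "trajectory", "x", "y"), "trajs")
  trajs <- tibble::as_tibble(trajs)
  keep_cols <- intersect(c("cell_id", "day_id"), names(trajs))
  if (nrow(trajs) == 0) {
    out <- tibble::tibble(r = double(), dt = double(), trajectory = integer())
    for (cc in keep_cols) out[[cc]] <- character()
    return(out)
  }
  trajs <- dplyr::arrange(trajs, .data$trajectory, .data$frame)
  n <- nrow(trajs)
  if (n < 2) {
    out <- tibble::tibble(r = double(), dt = double(),
                          trajectory = trajs$trajectory[0])
    for (cc in keep_cols) out[[cc]] <- trajs[[cc]][0]
    return(out)
  }
  same <- trajs$trajectory[-1] == trajs$trajectory[-n] &
    diff(trajs$frame) == 1L
  idx <- which(same)
  out <- tibble::tibble(
    r = sqrt((trajs$x[idx + 1L] - trajs$x[idx])^2 +
               (trajs$y[idx + 1L] - trajs$y[idx])^2),
    dt = frame_interval,
    trajectory = trajs$trajectory[idx])
  for (cc in keep_cols) out[[cc]] <- trajs[[cc]][idx]
  out
}
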