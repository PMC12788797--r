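#' Simulate an SMT trajectory dataset with known ground truth
#'
#' Generates localization tables for a multi-day, multi-cell fast-SMT
#' experiment. Each molecule draws a diffusive state once (no switching),
#' photoactivates at a uniformly random frame, performs 3-D Brownian motion
#' with per-axis step variance `2 * D * dt`, and is localized (with Gaussian
#' error `sigma_loc` per coordinate) only on frames where its axial position
#' lies inside the detection slab `|z| < focal_depth / 2`. Fluorophore
#' lifetime is geometric with mean `bleach_mean_frames`. A gap of one or more
#' undetected frames starts a new trajectory id (no blinking recovery,
#' matching `max_blinks = 0` tracking). Lateral positions reflect at the
#' field-of-view boundary.
#'
#' @param config an [smt_sim_config()].
#' @return A list of class `smt_dataset` with elements
#'   \describe{
#'     \item{trajectories}{tibble with columns `frame`, `trajectory`, `x`,
#'       `y` (um), `cell_id`, `day_id`.}
#'     \item{ground_truth}{list with `molecules` (per-molecule state
#'       assignment), `cells` (per-cell true and realized bound fractions)
#'       and the `config`.}
#'   }
#' @export
#' @examples
#' sim <- simulate_smt_dataset(smt_sim_config(cells_per_day = 1, n_days = 1,
#'                                            mean_mols_per_cell = 20, seed = 1))
#' dplyr::count(sim$trajectories, cell_id)
simulate_smt_dataset <- function(config) {
  stopifnot(inherits(config, "smt_sim_config"))
  with_seed_if(config$seed, simulate_smt_dataset_impl(config))
}

simulate_smt_dataset_impl <- function(config) {
  st <- config$states
  bound <- st$D < 0.1
  p0 <- sum(st$weight[bound])
  perturb <- p0 > 0 && p0 < 1 && (config$cell_sd > 0 || config$day_sd > 0)

  traj_offset <- 0L
  traj_list <- list()
  mol_list <- list()
  cell_list <- list()

  for (d in seq_len(config$n_days)) {
    day_id <- sprintf("day%02d", d)
    day_shift <- if (perturb) rnorm(1, 0, config$day_sd) else 0
    for (ci in seq_len(config$cells_per_day)) {
      cell_id <- sprintf("%s_cell%03d", day_id, ci)
      w <- st$weight
      p_cell <- p0
      if (perturb) {
        p_cell <- min(max(p0 + day_shift + rnorm(1, 0, config$cell_sd), 0.005), 0.995)
        w[bound] <- st$weight[bound] * p_cell / p0
        w[!bound] <- st$weight[!bound] * (1 - p_cell) / (1 - p0)
      }
      n_mol <- rpois(1, config$mean_mols_per_cell)
      cell <- simulate_cell(n_mol, st$D, w, config)
      if (!is.null(cell$locs) && nrow(cell$locs) > 0) {
        cell$locs$trajectory <- cell$locs$trajectory + traj_offset
        traj_offset <- max(cell$locs$trajectory)
        cell$locs$cell_id <- cell_id
        cell$locs$day_id <- day_id
        traj_list[[length(traj_list) + 1L]] <- cell$locs
      }
      if (n_mol > 0) {
        mol_list[[length(mol_list) + 1L]] <- tibble::tibble(
          cell_id = cell_id, day_id = day_id,
          molecule = seq_len(n_mol), state = cell$states,
          D = st$D[cell$states])
      }
      cell_list[[length(cell_list) + 1L]] <- tibble::tibble(
        cell_id = cell_id, day_id = day_id, n_molecules = n_mol,
        bound_weight = p_cell,
        realized_bound_fraction = if (n_mol > 0) mean(bound[cell$states]) else NA_real_)
    }
  }

  trajectories <- if (length(traj_list) > 0) {
    dplyr::bind_rows(traj_list)[, c("frame", "trajectory", "x", "y", "cell_id", "day_id")]
  } else {
    tibble::tibble(frame = integer(), trajectory = integer(), x = double(),
                   y = double(), cell_id = character(), day_id = character())
  }

  structure(list(trajectories = tibble::as_tibble(trajectories),
                 ground_truth = list(molecules = dplyr::bind_rows(mol_list),
                                     cells = dplyr::bind_rows(cell_list),
                                     config = config)),
            class = "smt_dataset")
}

# One cell: vectorized over molecules. Returns observed localizations with
# within-cell trajectory ids (1-based) plus the per-molecule state draws.
simulate_cell <- function(n_mol, D, w, config) {
  if (n_mol == 0) return(list(locs = NULL, states = integer()))
  dt <- config$frame_interval
  depth <- config$focal_depth
  fov <- config$fov_size

  states <- sample.int(length(w), n_mol, replace = TRUE, prob = w)
  act <- sample.int(config$n_frames, n_mol, replace = TRUE) - 1L
  life <- 1L + rgeom(n_mol, 1 / config$bleach_mean_frames)
  nf <- pmin(life, config$n_frames - act)

  id <- rep.int(seq_len(n_mol), nf)
  N <- length(id)
  step_sd <- sqrt(2 * D[states] * dt)[id]
  starts <- cumsum(nf) - nf + 1L
  first <- logical(N)
  first[starts] <- TRUE

  walk <- function(init) {
    s <- rnorm(N, 0, step_sd)
    s[first] <- 0
    cs <- cumsum(s)
    init[id] + cs - rep.int(cs[starts], nf)
  }
  z <- walk(runif(n_mol, -depth / 2, depth / 2))
  x <- reflect_into(walk(runif(n_mol, 0, fov)), fov)
  y <- reflect_into(walk(runif(n_mol, 0, fov)), fov)
  frame <- act[id] + sequence(nf) - 1L

  obs <- abs(z) < depth / 2
  if (!any(obs)) return(list(locs = NULL, states = states))
  idx <- which(obs)
  mol <- id[idx]
  fr <- frame[idx]
  new_run <- c(TRUE, diff(mol) != 0 | diff(fr) != 1L)
  # observed positions carry localization error, clamped to the field of view
  locs <- tibble::tibble(
    frame = fr,
    trajectory = cumsum(new_run),
    x = pmin(pmax(x[idx] + rnorm(length(idx), 0, config$sigma_loc), 0), fov),
    y = pmin(pmax(y[idx] + rnorm(length(idx), 0, config$sigma_loc), 0), fov))
  list(locs = locs, states = states)
}

# Fold coordinates into [0, L] by reflection.
reflect_into <- function(p, L) {
  p <- p %% (2 * L)
  ifelse(p > L, 2 * L - p, p)
}

#' @export
print.smt_dataset <- function(x, ...) {
  tr <- x$trajectories
  cat("<smt_dataset>\n")
  cat(sprintf("  %d localizations, %d trajectories, %d cells, %d day(s)\n",
              nrow(tr), dplyr::n_distinct(tr$trajectory),
              dplyr::n_distinct(tr$cell_id), dplyr::n_distinct(tr$day_id)))
  invisible(x)
}
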