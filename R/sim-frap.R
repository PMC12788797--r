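#' Simulate a FRAP movie with known recovery kinetics
#'
#' Builds a grayscale image stack (H x W x T) of a disk-shaped nucleus at unit
#' plateau intensity. At the bleach frame the bleach-spot intensity drops by
#' `bleach_depth` and then recovers as
#' `A1 * (1 - exp(-t / tau1)) + A2 * (1 - exp(-t / tau2))` of the bleached
#' amount (`recovery = "reaction"`), with total nuclear intensity conserved:
#' the signal refilling the spot is debited uniformly from the rest of the
#' nucleus. The whole signal additionally decays by the observational
#' photobleaching rate, a constant background is added to all pixels, and
#' Gaussian noise is applied last. With `recovery = "diffusion"` the bleach
#' instead leaves a Gaussian profile that relaxes by free diffusion
#' (variance growing as `2 * D * t`), producing the changing radial shapes
#' the gradient-smoothing test detects.
#'
#' @param config a [frap_sim_config()].
#' @return A list of class `frap_movie` with elements `stack` (H x W x T
#'   array), `timestamps` (s), `bleach_frame` (1-based index of the first
#'   post-bleach frame), `spot_center_px` (x, y), `spot_radius_px`,
#'   `pixel_size` and `config` (the generating config, or `NULL` for movies
#'   read from disk).
#' @export
#' @examples
#' mv <- simulate_frap_movie(frap_sim_config(n_post = 20, seed = 1))
#' dim(mv$stack)
simulate_frap_movie <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  with_seed_if(config$seed, simulate_frap_movie_impl(config))
}

simulate_frap_movie_impl <- function(config) {
  n_px <- config$size_px
  px <- config$pixel_size
  n_pre <- config$bleach_frame - 1L
  n_t <- n_pre + config$n_post
  center <- (n_px + 1) / 2 * px
  spot_center <- center + config$spot_offset_um

  # pixel-center coordinates in um
  coord <- (seq_len(n_px) - 0.5) * px
  xg <- matrix(coord, n_px, n_px, byrow = TRUE)
  yg <- matrix(coord, n_px, n_px)
  r_nuc <- sqrt((xg - center)^2 + (yg - center)^2)
  r_spot2 <- (xg - spot_center[1])^2 + (yg - spot_center[2])^2
  nucleus <- r_nuc <= config$nucleus_radius_um
  spot <- r_spot2 <= config$spot_radius_um^2
  spot_n <- sum(spot & nucleus)
  rest_n <- sum(nucleus) - spot_n

  # the bleach event sits one frame interval before the first post-bleach
  # frame, so recovery has already run for dt when that frame is acquired
  t_post <- seq_len(config$n_post) * config$frame_interval
  depth <- config$bleach_depth
  stack <- array(0, dim = c(n_px, n_px, n_t))

  for (f in seq_len(n_t)) {
    signal <- matrix(0, n_px, n_px)
    if (f <= n_pre) {
      signal[nucleus] <- 1
    } else if (config$recovery == "reaction") {
      tt <- t_post[f - n_pre]
      rec <- config$A1 * (1 - exp(-tt / config$tau1)) +
        config$A2 * (1 - exp(-tt / config$tau2))
      spot_val <- 1 - depth * (1 - rec)
      # conserve total nuclear intensity: refill is debited from the rest
      rest_val <- (sum(nucleus) - spot_val * spot_n) / rest_n
      signal[nucleus] <- rest_val
      signal[spot & nucleus] <- spot_val
    } else {
      tt <- t_post[f - n_pre]
      s2 <- (config$spot_radius_um / 2)^2 + 2 * config$D_frap * tt
      amp <- depth * (config$spot_radius_um / 2)^2 / s2
      signal[nucleus] <- 1
      prof <- amp * exp(-r_spot2 / (2 * s2))
      signal[nucleus] <- signal[nucleus] - prof[nucleus]
    }
    decay <- exp(-config$obs_bleach_rate * (f - 1L))
    frame <- signal * decay + config$background
    if (config$noise_sd > 0) {
      frame <- frame + matrix(rnorm(n_px * n_px, 0, config$noise_sd), n_px, n_px)
    }
    stack[, , f] <- frame
  }

  structure(list(stack = stack,
                 timestamps = (seq_len(n_t) - 1L) * config$frame_interval,
                 bleach_frame = config$bleach_frame,
                 spot_center_px = spot_center / px,
                 spot_radius_px = config$spot_radius_um / px,
                 pixel_size = px,
                 config = config),
            class = "frap_movie")
}

#' @export
print.frap_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<frap_movie> %d x %d px, %d frames (bleach at frame %d), %.3g um/px\n",
              d[1], d[2], d[3], x$bleach_frame, x$pixel_size))
  invisible(x)
}
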