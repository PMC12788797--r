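#' Isodata (intermeans) threshold
#'
#' Iterates `t <- (mean(x[x <= t]) + mean(x[x > t])) / 2` from the overall
#' mean until the threshold is stationary — the classic isodata fixed point
#' separating foreground from background.
#'
#' @param x numeric values (an image or any sample).
#' @param tol convergence tolerance.
#' @return The threshold, or `NA` if the values are all equal.
#' @export
#' @examples
#' isodata_threshold(c(rep(10, 50), rep(100, 20)))  # 55
isodata_threshold <- function(x, tol = 1e-8) {
  x <- x[is.finite(x)]
  if (length(x) == 0 || diff(range(x)) == 0) return(NA_real_)
  t <- mean(x)
  repeat {
    lo <- x[x <= t]
    hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t
}

#' Segment the nucleus of a FRAP movie
#'
#' Pipeline: z-normalize each frame (subtract its mean, divide by its
#' s.d.), sum-project over time, Gaussian-blur the projection, threshold by
#' the isodata rule, fill holes, and keep the largest connected component.
#'
#' @param movie a `frap_movie` (see [simulate_frap_movie()]).
#' @param blur_sigma Gaussian blur s.d., px.
#' @return A logical matrix (TRUE = nucleus).
#' @export
nuclear_mask <- function(movie, blur_sigma = 2) {
  stack <- movie$stack
  if (dim(stack)[3] < 2) abort("need at least 2 frames")
  proj <- matrix(0, dim(stack)[1], dim(stack)[2])
  for (f in seq_len(dim(stack)[3])) {
    fr <- stack[, , f]
    s <- sd(fr)
    if (s > 0) proj <- proj + (fr - mean(fr)) / s
  }
  blurred <- EBImage::gblur(proj, sigma = blur_sigma)
  thr <- isodata_threshold(as.numeric(blurred))
  if (is.na(thr)) abort("no foreground found (image is constant)")
  bin <- blurred > thr
  if (!any(bin)) abort("no foreground found")
  filled <- EBImage::fillHull(EBImage::Image(bin * 1))
  labels <- EBImage::bwlabel(filled)
  lab_mat <- EBImage::imageData(labels)
  tab <- tabulate(lab_mat[lab_mat > 0])
  lab_mat == which.max(tab)
}

#' Subtract per-frame background from a FRAP movie
#'
#' The background of each frame is the median of its non-nuclear pixels;
#' it is subtracted from every pixel of that frame.
#'
#' @param movie a `frap_movie`.
#' @param mask nuclear mask from [nuclear_mask()].
#' @return The movie with corrected stack.
#' @export
background_subtract <- function(movie, mask) {
  if (all(mask)) abort("mask covers the full frame; no background pixels")
  stack <- movie$stack
  for (f in seq_len(dim(stack)[3])) {
    fr <- stack[, , f]
    stack[, , f] <- fr - median(fr[!mask])
  }
  movie$stack <- stack
  movie
}

#' Correct a FRAP movie for observational photobleaching
#'
#' Anchors nuclear intensity within each phase: every pre-bleach frame is
#' scaled so its in-mask sum equals that of the last pre-bleach frame, and
#' every post-bleach frame so its in-mask sum equals that of the first
#' post-bleach frame. Run after [background_subtract()].
#'
#' @param movie a `frap_movie` (background-subtracted).
#' @param mask nuclear mask.
#' @param bleach_frame 1-based index of the first post-bleach frame
#'   (default from the movie).
#' @return The movie with corrected stack.
#' @export
photobleach_correct <- function(movie, mask, bleach_frame = movie$bleach_frame) {
  stack <- movie$stack
  n_t <- dim(stack)[3]
  if (bleach_frame < 2 || bleach_frame > n_t) abort("bleach_frame outside the stack")
  sums <- vapply(seq_len(n_t), function(f) sum(stack[, , f][mask]), numeric(1))
  pre_anchor <- sums[bleach_frame - 1L]
  post_anchor <- sums[bleach_frame]
  if (pre_anchor <= 0 || post_anchor <= 0) {
    abort("zero in-mask intensity on an anchor frame")
  }
  for (f in seq_len(n_t)) {
    anchor <- if (f < bleach_frame) pre_anchor else post_anchor
    stack[, , f] <- stack[, , f] * (anchor / sums[f])
  }
  movie$stack <- stack
  movie
}

#' Extract the normalized FRAP recovery curve
#'
#' The mean intensity inside the bleach-spot disk at each frame, divided by
#' its mean over the pre-bleach frames (normalizing the pre-bleach level to
#' 1). Post-bleach times are measured from the bleach event, taken to occur
#' one frame interval before the first post-bleach frame.
#'
#' @param movie a background-subtracted, photobleach-corrected `frap_movie`.
#' @param mask nuclear mask (the spot center must lie inside it).
#' @param bleach_frame 1-based index of the first post-bleach frame.
#' @return A tibble of class `frap_curve` with columns `time` (s, relative
#'   to the bleach event), `value`, `phase` (`"pre"`/`"post"`).
#' @export
extract_frap_curve <- function(movie, mask = NULL,
                               bleach_frame = movie$bleach_frame) {
  stack <- movie$stack
  n_t <- dim(stack)[3]
  cx <- movie$spot_center_px[1]
  cy <- movie$spot_center_px[2]
  if (!is.null(mask)) {
    if (!mask[round(cy), round(cx)]) abort("bleach spot lies outside the nuclear mask")
  }
  coord_x <- matrix(seq_len(dim(stack)[2]) - 0.5, dim(stack)[1], dim(stack)[2],
                    byrow = TRUE)
  coord_y <- matrix(seq_len(dim(stack)[1]) - 0.5, dim(stack)[1], dim(stack)[2])
  spot <- (coord_x - cx)^2 + (coord_y - cy)^2 <= movie$spot_radius_px^2
  vals <- vapply(seq_len(n_t), function(f) mean(stack[, , f][spot]), numeric(1))
  pre <- seq_len(bleach_frame - 1L)
  vals <- vals / mean(vals[pre])
  dt_frame <- if (n_t > 1) movie$timestamps[2] - movie$timestamps[1] else 0
  bleach_time <- movie$timestamps[bleach_frame] - dt_frame
  out <- tibble::tibble(time = movie$timestamps - bleach_time,
                        value = vals,
                        phase = ifelse(seq_len(n_t) < bleach_frame, "pre", "post"))
  class(out) <- c("frap_curve", class(out))
  out
}

#' Resample a FRAP curve into log-spaced time bins
#'
#' Prevents the long recovery tail from dominating the fit: post-bleach
#' samples are grouped into `n_bins` log-spaced bins between `t_min` and the
#' maximum time, and each non-empty bin contributes the arithmetic mean of
#' its timestamps and of its values. Empty bins are dropped.
#'
#' @param curve a `frap_curve` from [extract_frap_curve()].
#' @param n_bins number of log-spaced bins.
#' @param t_min left edge of the first bin, s.
#' @return A tibble of class `frap_curve_binned` with columns `time`,
#'   `value`, `n` (samples per bin).
#' @export
log_bin_resample <- function(curve, n_bins = 100, t_min = 0.01) {
  assert_columns(curve, c("time", "value"), "curve")
  post <- curve[curve$phase == "post" & curve$time >= t_min, ]
  if (nrow(post) == 0) abort("no post-bleach samples at or above t_min")
  t_max <- max(post$time)
  if (t_max <= t_min) abort("post-bleach samples span no time range above t_min")
  edges <- exp(seq(log(t_min), log(t_max), length.out = n_bins + 1))
  bin <- findInterval(post$time, edges, rightmost.closed = TRUE)
  out <- tibble::tibble(time = post$time, value = post$value, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(time = mean(.data$time), value = mean(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::select(!"bin")
  class(out) <- c("frap_curve_binned", class(out))
  out
}

#' Gradient-smoothing test for diffusion-coupled recovery
#'
#' If recovery is reaction-dominant (binding-exchange limited), the shape of
#' the radial bleach profile is constant while its amplitude fills in; if
#' diffusion contributes, the profile smooths and widens. The test computes
#' the radial mean-intensity profile (1 px annuli from the spot center) for
#' the first `n_frames` post-bleach frames, min-max normalizes each profile
#' to \[0, 1\], and flags when the maximum absolute difference between
#' successive normalized profiles exceeds `tol`.
#'
#' @param movie a corrected `frap_movie`.
#' @param n_frames number of post-bleach frames to compare.
#' @param tol shape-change tolerance on normalized profiles.
#' @param max_radius_px profile extent (default 3x the spot radius).
#' @param bleach_frame 1-based index of the first post-bleach frame.
#' @return A list with `profiles` (tibble: `frame`, `radius_px`, `value`,
#'   `value_norm`), `max_change` and `flag` (`NA` when fewer than two
#'   profiles are available).
#' @export
gradient_smoothing_test <- function(movie, n_frames = 5, tol = 0.1,
                                    max_radius_px = NULL,
                                    bleach_frame = movie$bleach_frame) {
  stack <- movie$stack
  n_t <- dim(stack)[3]
  frames <- seq(bleach_frame, min(bleach_frame + n_frames - 1L, n_t))
  max_radius_px <- max_radius_px %||% (3 * movie$spot_radius_px)
  cx <- movie$spot_center_px[1]
  cy <- movie$spot_center_px[2]
  coord_x <- matrix(seq_len(dim(stack)[2]) - 0.5, dim(stack)[1], dim(stack)[2],
                    byrow = TRUE)
  coord_y <- matrix(seq_len(dim(stack)[1]) - 0.5, dim(stack)[1], dim(stack)[2])
  rr <- sqrt((coord_x - cx)^2 + (coord_y - cy)^2)
  annulus <- floor(rr)
  keep <- annulus < floor(max_radius_px)
  radii <- sort(unique(annulus[keep]))

  prof_list <- purrr::map(frames, function(f) {
    fr <- stack[, , f]
    v <- vapply(radii, function(a) mean(fr[keep & annulus == a]), numeric(1))
    rng <- range(v)
    vn <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    tibble::tibble(frame = f, radius_px = radii + 0.5, value = v, value_norm = vn)
  })
  profiles <- dplyr::bind_rows(prof_list)

  if (length(prof_list) < 2) {
    return(list(profiles = profiles, max_change = NA_real_, flag = NA))
  }
  changes <- vapply(seq_len(length(prof_list) - 1), function(i) {
    max(abs(prof_list[[i + 1]]$value_norm - prof_list[[i]]$value_norm))
  }, numeric(1))
  list(profiles = profiles, max_change = max(changes), flag = max(changes) > tol)
}

#' Characteristic diffusion timescale across a bleach spot
#'
#' Time for a molecule with diffusion coefficient `D` to traverse
#' `radius_um` by 2-D diffusion, from the mean-squared displacement relation
#' `r^2 = 4 D t`: `t = r^2 / (4 D)`. Used to judge whether diffusive
#' refilling could masquerade as binding-exchange recovery.
#'
#' @param radius_um bleach-spot radius, um.
#' @param D diffusion coefficient, um^2/s.
#' @return Time in seconds.
#' @export
#' @examples
#' diffusion_timescale(0.75, 2)  # ~0.07 s
diffusion_timescale <- function(radius_um, D) {
  if (any(radius_um <= 0) || any(D <= 0)) abort("radius_um and D must be > 0")
  radius_um^2 / (4 * D)
}

#' Fit exponential recovery models to a binned FRAP curve
#'
#' Nonlinear least squares with box constraints, multi-started from a fixed
#' lattice of initial values (the best residual wins, so fits are
#' deterministic). The single-exponential model is
#' `FRAP(t) = A (1 - exp(-t / tau))` with `A` in \[0, 1\]; the
#' double-exponential model is
#' `FRAP(t) = A1 (1 - exp(-t / tau1)) + A2 (1 - exp(-t / tau2))` with
#' `A1, A2 >= 0` and `A1 + A2 <= 1` (enforced by the reparameterization
#' `A1 = S p`, `A2 = S (1 - p)` with `S, p` in \[0, 1\]), reported with
#' `tau1 <= tau2`. The amplitude-sum constraint realizes the implicit
#' plateau bound: recovery cannot exceed the pre-bleach level.
#'
#' By default only log-binned curves ([log_bin_resample()]) are accepted —
#' fitting unbinned curves lets the dense tail dominate — and at least 5
#' (single) or 8 (double) points are required.
#'
#' @param curve a `frap_curve_binned`.
#' @param allow_unbinned accept a raw post-bleach curve (not recommended).
#' @return A list of class `frap_fit`: `model`, `par` (named vector),
#'   `rss`, `converged`, `data`, `fitted` (function of time).
#' @export
fit_single_exp <- function(curve, allow_unbinned = FALSE) {
  d <- check_fit_curve(curve, 5, allow_unbinned)
  starts <- expand.grid(A = c(0.3, 0.6, 0.9), tau = c(0.1, 1, 10, 100))
  obj <- function(p) sum((d$value - p[1] * (1 - exp(-d$time / exp(p[2]))))^2)
  best <- multi_start(obj,
                      lapply(seq_len(nrow(starts)),
                             function(i) c(starts$A[i], log(starts$tau[i]))),
                      lower = c(0, log(1e-3)), upper = c(1, log(1e5)))
  par <- c(A = best$par[1], tau = exp(best$par[2]))
  new_frap_fit("single", par, best$objective, best$ok, d,
               function(t) par["A"] * (1 - exp(-t / par["tau"])))
}

#' @rdname fit_single_exp
#' @export
fit_double_exp <- function(curve, allow_unbinned = FALSE) {
  d <- check_fit_curve(curve, 8, allow_unbinned)
  taus <- c(0.1, 1, 10, 100)
  grid <- expand.grid(i = 1:4, j = 1:4, p = c(0.3, 0.5, 0.7), S = c(0.6, 0.9))
  grid <- grid[grid$i < grid$j, ]
  obj <- function(q) {
    S <- q[1]; p <- q[2]; t1 <- exp(q[3]); t2 <- exp(q[4])
    pred <- S * (p * (1 - exp(-d$time / t1)) + (1 - p) * (1 - exp(-d$time / t2)))
    sum((d$value - pred)^2)
  }
  best <- multi_start(obj,
                      lapply(seq_len(nrow(grid)), function(k)
                        c(grid$S[k], grid$p[k], log(taus[grid$i[k]]), log(taus[grid$j[k]]))),
                      lower = c(0, 0, log(1e-3), log(1e-3)),
                      upper = c(1, 1, log(1e5), log(1e5)))
  S <- best$par[1]; p <- best$par[2]
  t1 <- exp(best$par[3]); t2 <- exp(best$par[4])
  A1 <- S * p; A2 <- S * (1 - p)
  if (t1 > t2) {  # canonical ordering tau1 <= tau2
    tmp <- t1; t1 <- t2; t2 <- tmp
    tmp <- A1; A1 <- A2; A2 <- tmp
  }
  par <- c(A1 = A1, tau1 = t1, A2 = A2, tau2 = t2)
  new_frap_fit("double", par, best$objective, best$ok, d,
               function(t) A1 * (1 - exp(-t / t1)) + A2 * (1 - exp(-t / t2)))
}

check_fit_curve <- function(curve, min_points, allow_unbinned) {
  if (!inherits(curve, "frap_curve_binned") && !allow_unbinned) {
    abort(paste("expected a log-binned curve (log_bin_resample());",
                "set allow_unbinned = TRUE to override"))
  }
  assert_columns(curve, c("time", "value"), "curve")
  d <- curve[curve$time > 0, c("time", "value")]
  if (nrow(d) < min_points) {
    abort(sprintf("need at least %d positive-time points, got %d",
                  min_points, nrow(d)))
  }
  d
}

multi_start <- function(obj, starts, lower, upper) {
  best <- NULL
  any_ok <- FALSE
  for (s in starts) {
    fit <- tryCatch(nlminb(s, obj, lower = lower, upper = upper),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$convergence == 0
    any_ok <- any_ok || ok
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) abort("fit failed from all starts")
  best$ok <- any_ok
  best
}

new_frap_fit <- function(model, par, rss, converged, data, fitted) {
  structure(list(model = model, par = par, rss = rss, converged = converged,
                 data = data, fitted = fitted),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit: %s-exponential>\n", x$model))
  cat("  ", paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "), "\n")
  cat(sprintf("  rss = %.4g on %d points; %s\n", x$rss, nrow(x$data),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$par))
  out$rss <- x$rss
  out$model <- x$model
  out$converged <- x$converged
  out$n <- nrow(x$data)
  out
}

#' Run the full FRAP analysis pipeline on one movie
#'
#' Steps, in order: nuclear masking, per-frame background subtraction,
#' two-anchor photobleach correction, recovery-curve extraction, log-binned
#' resampling, the gradient-smoothing diffusion test, and single- plus
#' double-exponential fits.
#'
#' @param movie a `frap_movie`.
#' @param n_bins,t_min binning controls ([log_bin_resample()]).
#' @param blur_sigma mask blur ([nuclear_mask()]).
#' @param gradient_frames,gradient_tol gradient-smoothing controls.
#' @return A list with `mask`, `curve`, `binned`, `gradient`, `fit_single`,
#'   `fit_double`.
#' @export
analyze_frap_movie <- function(movie, n_bins = 100, t_min = 0.01,
                               blur_sigma = 2, gradient_frames = 5,
                               gradient_tol = 0.1) {
  mask <- nuclear_mask(movie, blur_sigma = blur_sigma)
  corrected <- movie |>
    background_subtract(mask) |>
    photobleach_correct(mask)
  curve <- extract_frap_curve(corrected, mask)
  binned <- log_bin_resample(curve, n_bins = n_bins, t_min = t_min)
  gradient <- gradient_smoothing_test(corrected, n_frames = gradient_frames,
                                      tol = gradient_tol)
  list(mask = mask, curve = curve, binned = binned, gradient = gradient,
       fit_single = fit_single_exp(binned), fit_double = fit_double_exp(binned))
}
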