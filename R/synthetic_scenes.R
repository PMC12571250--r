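# Synthetic scene generator.
#
# Emulates the statistical structure of annotated natural-scene motion and
# distance maps: a mostly-slow ground with a threshold-censored speed floor,
# fast horizontally-biased figure motion (giving a bimodal global speed
# distribution), bimodal distances with figures nearer than a receding
# ground plane, spatially contiguous irregular figure regions, and a sky
# band.  Every downstream stage of the pipeline is testable against scenes
# from this module without any external data.

#' Parameters of the synthetic scene generator
#'
#' Defaults correspond to the study conditions the pipeline is meant to
#' emulate: above-threshold ground speeds with median ~1 deg/s and ~70%
#' of ground pixels censored below the 0.5 deg/s validity threshold;
#' figure speeds offset by `fg_logspeed_offset` in log10 units (default
#' 1.3, i.e. median ~20 deg/s); figure directions strongly horizontal
#' (two-lobe axial von Mises, `kappa_f`) and ground directions weakly so
#' (`kappa_g`); a ground plane receding from ~3 m to ~30 m with figures
#' nearer by the multiplicative factor `figure_depth_offset`.
#'
#' `fg_logspeed_offset` is the recoverable ground truth of the generator:
#' figure log10 speeds are drawn as ground (above-threshold) log10 speeds
#' plus this offset, so the expected valid-pixel mean log10 speed
#' difference between figure and ground in the world frame equals the
#' configured offset exactly.
#'
#' @param height,width canvas size in pixels.
#' @param fov_deg field of view in degrees (square canvas assumed).
#' @param frame_rate frame rate in Hz.
#' @param n_figures integer range (length 1 or 2) of figure counts.
#' @param figure_radius_deg figure blob radius range in degrees.
#' @param figure_roughness boundary roughness of the figure blobs (0 =
#'   circles; harmonic perturbation amplitude).
#' @param ground_speed_median median of above-threshold ground speeds,
#'   deg/s.  Above-threshold ground log10 speeds follow an exponential
#'   decay away from the validity threshold (most visible ground motion is
#'   barely above the noise floor, with a thinning fast tail); the decay
#'   scale is set by this median.
#' @param ground_static_frac fraction of ground pixels censored below the
#'   speed threshold (drawn uniform on `[0, threshold)`).
#' @param figure_static_prob probability that a figure is stationary
#'   (buildings, parked vehicles...): its pixels then draw sub-threshold
#'   speeds like static ground, and fixating it triggers no pursuit.
#' @param fg_logspeed_offset mean log10 speed difference between moving
#'   figures and above-threshold ground (valid pixels, world frame).
#'   Moving-figure log10 speeds decay exponentially *downward* from a
#'   coherent peak (a rigid object's pixels cluster at its speed, with a
#'   slow tail), truncated at the validity threshold; the peak is solved
#'   so the valid-pixel mean log10 difference equals this offset exactly.
#' @param kappa_f,kappa_g axial direction concentration for figures and
#'   ground.
#' @param kappa_jitter per-pixel von Mises jitter about each figure's
#'   coherent direction.
#' @param ground_depth length-2 `(near, far)` ground-plane distances in m
#'   (bottom row to horizon).
#' @param figure_depth_offset multiplicative nearness factor (< 1) applied
#'   to the ground distance at each figure's centroid.
#' @param sky_fraction fraction of top rows labelled sky (in `[0, 0.3]`).
#' @param speed_threshold motion validity threshold, deg/s.
#' @param buffer_px annotation-border buffer radius, pixels.
#' @return a `scene_gen_params` list.
#' @export
scene_gen_params <- function(height = 384L, width = 384L, fov_deg = 42,
                             frame_rate = 120,
                             n_figures = c(1L, 3L),
                             figure_radius_deg = c(4, 9),
                             figure_roughness = 0.3,
                             ground_speed_median = 1,
                             ground_static_frac = 0.7,
                             figure_static_prob = 0.5,
                             fg_logspeed_offset = 1.3,
                             kappa_f = 4, kappa_g = 0.8,
                             kappa_jitter = 60,
                             ground_depth = c(3, 30),
                             figure_depth_offset = 0.45,
                             sky_fraction = 0.1,
                             speed_threshold = 0.5,
                             buffer_px = 5L) {
  p <- list(height = as.integer(height), width = as.integer(width),
            fov_deg = fov_deg, frame_rate = frame_rate,
            n_figures = as.integer(range(n_figures)),
            figure_radius_deg = as.numeric(figure_radius_deg),
            figure_roughness = figure_roughness,
            ground_speed_median = ground_speed_median,
            ground_static_frac = ground_static_frac,
            figure_static_prob = figure_static_prob,
            fg_logspeed_offset = fg_logspeed_offset,
            kappa_f = kappa_f, kappa_g = kappa_g,
            kappa_jitter = kappa_jitter,
            ground_depth = as.numeric(ground_depth),
            figure_depth_offset = figure_depth_offset,
            sky_fraction = sky_fraction,
            speed_threshold = speed_threshold,
            buffer_px = as.integer(buffer_px))
  stopifnot(p$ground_speed_median > p$speed_threshold,
            p$ground_static_frac >= 0, p$ground_static_frac < 1,
            p$figure_static_prob >= 0, p$figure_static_prob <= 1,
            p$kappa_f >= 0, p$kappa_g >= 0,
            all(p$ground_depth > 0), p$figure_depth_offset > 0,
            p$figure_depth_offset < 1,
            p$sky_fraction >= 0, p$sky_fraction <= 0.3,
            p$n_figures[1] >= 1L)
  class(p) <- "scene_gen_params"
  p
}

#' Write / read generator parameters as YAML
#' @param params a [scene_gen_params()] list.
#' @param path file path.
#' @return `path` (write) or a `scene_gen_params` (read).
#' @export
write_scene_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_scene_params
#' @export
read_scene_params <- function(path) {
  do.call(scene_gen_params, yaml::read_yaml(path))
}

# Log10-speed model.  Above-threshold ground: t + Exp(scale s), i.e. an
# exponential decay of log10 speed away from the validity threshold t,
# with scale s fixed by the configured median.  Moving figures: an
# exponential decay *downward* from a coherent peak c_f, truncated at t;
# c_f is solved so that the valid-pixel mean log10 difference between the
# two distributions equals fg_logspeed_offset exactly.

logspeed_scale <- function(params) {
  (log10(params$ground_speed_median) - log10(params$speed_threshold)) /
    log(2)
}

# mean of a unit-rate exponential truncated to [0, T]
texp_mean <- function(T) 1 - T * exp(-T) / (1 - exp(-T))

figure_logspeed_peak <- function(params) {
  t <- log10(params$speed_threshold)
  s <- logspeed_scale(params)
  target <- t + s + params$fg_logspeed_offset  # required mean of fig log10
  f <- function(c) c - s * texp_mean((c - t) / s) - target
  stats::uniroot(f, c(t + 1e-9, target + s + 1), tol = 1e-12)$root
}

rground_logspeed <- function(n, params) {
  log10(params$speed_threshold) +
    stats::rexp(n, rate = 1 / logspeed_scale(params))
}

rfigure_logspeed <- function(n, params, peak = figure_logspeed_peak(params)) {
  t <- log10(params$speed_threshold)
  s <- logspeed_scale(params)
  T <- (peak - t) / s
  u <- stats::runif(n)
  e <- -log(1 - u * (1 - exp(-T)))  # Exp(1) truncated to [0, T]
  peak - s * e
}

# Rasterise one smooth radially-perturbed blob.  Returns a logical mask.
# Star-shaped by construction (radius function bounded below), hence
# 4-connected.
blob_mask <- function(h, w, center, r0_px, roughness) {
  nharm <- 4L
  a <- stats::rnorm(nharm, 0, roughness / (1 + seq_len(nharm)))
  phi <- stats::runif(nharm, 0, 2 * pi)
  rows <- seq_len(h); cols <- seq_len(w)
  dr <- matrix(rows - center[1], h, w)
  dc <- matrix(cols - center[2], h, w, byrow = TRUE)
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(-dr, dc)  # +y up
  pert <- matrix(0, h, w)
  for (k in seq_len(nharm)) {
    pert <- pert + a[k] * cos((k + 1) * theta + phi[k])
  }
  pert <- pmax(pert, -0.75)
  rho <= r0_px * (1 + pert)
}

#' Generate one synthetic scene bundle
#'
#' @param params a [scene_gen_params()] list.
#' @param seed integer RNG seed; the scene is deterministic given
#'   `(params, seed)`.
#' @return a [scene_bundle()] with speed, direction, distance, label,
#'   luminance and saliency channels.
#' @export
generate_scene <- function(params = scene_gen_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_gen_params"))
  set.seed(seed)
  h <- params$height; w <- params$width
  dpp <- params$fov_deg / max(h, w)
  meta <- scene_metadata(dpp, params$frame_rate, h, w,
                         site_tag = sprintf("synthetic-%d", seed))

  n_sky <- round(params$sky_fraction * h)
  label <- matrix(LABEL_GROUND, h, w)
  if (n_sky > 0) label[seq_len(n_sky), ] <- LABEL_SKY

  # --- place figures -------------------------------------------------------
  nf <- if (params$n_figures[1] == params$n_figures[2]) params$n_figures[1]
        else sample(params$n_figures[1]:params$n_figures[2], 1L)
  r_px_range <- params$figure_radius_deg / dpp
  placed <- 0L
  for (fid in seq_len(nf)) {
    ok <- FALSE
    for (try in seq_len(30L)) {
      r0 <- stats::runif(1, r_px_range[1], r_px_range[2])
      margin <- ceiling(r0 * 0.6)
      rlo <- n_sky + 1L + margin; rhi <- h - margin
      if (rlo >= rhi) next
      center <- c(sample(rlo:rhi, 1L), sample((1L + margin):(w - margin), 1L))
      m <- blob_mask(h, w, center, r0, params$figure_roughness)
      m[seq_len(max(n_sky, 0L)), ] <- FALSE
      if (sum(m) < 25L) next
      if (any(label[m] != LABEL_GROUND)) next  # keep figures disjoint
      label[m] <- fid
      ok <- TRUE
      break
    }
    if (ok) placed <- placed + 1L
  }
  if (placed == 0L) {
    stop("generate_scene: could not place any figure after bounded retries ",
         "(figures too large for the canvas?)")
  }

  sky <- label == LABEL_SKY
  ground <- label == LABEL_GROUND
  fig_ids <- seq_len(placed)
  fig_peak <- figure_logspeed_peak(params)

  # --- motion --------------------------------------------------------------
  speed <- matrix(NA_real_, h, w)
  direction <- matrix(NA_real_, h, w)
  n_g <- sum(ground)
  static <- stats::runif(n_g) < params$ground_static_frac
  sp_g <- numeric(n_g)
  sp_g[static] <- stats::runif(sum(static), 0, params$speed_threshold)
  sp_g[!static] <- 10^rground_logspeed(sum(!static), params)
  speed[ground] <- sp_g
  direction[ground] <- raxial(n_g, 0, params$kappa_g)
  for (fid in fig_ids) {
    fm <- label == fid
    n_f <- sum(fm)
    dir_fig <- raxial(1L, 0, params$kappa_f)
    if (stats::runif(1) < params$figure_static_prob) {
      # stationary figure: sub-threshold speeds, motion invalid
      speed[fm] <- stats::runif(n_f, 0, params$speed_threshold)
    } else {
      speed[fm] <- 10^rfigure_logspeed(n_f, params, fig_peak)
    }
    direction[fm] <- (dir_fig + rvonmises(n_f, 0, params$kappa_jitter)) %% 360
  }

  # --- distance ------------------------------------------------------------
  distance <- matrix(NA_real_, h, w)
  near <- params$ground_depth[1]; far <- params$ground_depth[2]
  horizon <- n_sky + 1L
  frac <- (matrix(seq_len(h), h, w) - horizon) / max(h - horizon, 1L)
  ramp <- far + (near - far) * pmax(frac, 0)
  distance[ground] <- ramp[ground] * exp(stats::rnorm(n_g, 0, 0.05))
  for (fid in fig_ids) {
    fm <- label == fid
    centroid_row <- round(mean(which(fm, arr.ind = TRUE)[, 1]))
    base <- ramp[centroid_row, 1] * params$figure_depth_offset
    distance[fm] <- base * exp(stats::rnorm(sum(fm), 0, 0.03))
  }

  # --- luminance and saliency ---------------------------------------------
  luminance <- matrix(0.5 + stats::rnorm(h * w, 0, 0.08), h, w)
  fig_lum <- seq(0.15, 0.9, length.out = max(placed, 1L))[sample.int(max(placed, 1L))]
  for (fid in fig_ids) {
    fm <- label == fid
    luminance[fm] <- fig_lum[fid] + stats::rnorm(sum(fm), 0, 0.08)
  }
  luminance[sky] <- 0.95 + stats::rnorm(sum(sky), 0, 0.01)
  luminance <- pmin(pmax(luminance, 0), 1)
  saliency <- stand_in_saliency(luminance)

  scene_bundle(speed, direction, distance, label, meta,
               saliency = saliency, luminance = luminance,
               speed_threshold = params$speed_threshold,
               buffer_px = params$buffer_px)
}

#' Generate an independent batch of synthetic scenes
#'
#' Child seeds are spawned deterministically from the master seed and
#' recorded in the manifest, so a dataset is reproducible from
#' `(params, seed)` alone.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param params a [scene_gen_params()] list.
#' @param seed master RNG seed.
#' @return a `scene_dataset`: list with `bundles` (list of
#'   [scene_bundle()]) and `manifest` (master seed, child seeds, params).
#' @export
generate_dataset <- function(n_scenes, params = scene_gen_params(),
                             seed = 1L) {
  if (n_scenes < 1L) stop("n_scenes must be >= 1")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, n_scenes)
  bundles <- lapply(child, function(s) generate_scene(params, s))
  structure(
    list(bundles = bundles,
         manifest = list(master_seed = as.integer(seed),
                         child_seeds = child,
                         n_scenes = as.integer(n_scenes),
                         params = unclass(params))),
    class = "scene_dataset"
  )
}

#' Write a dataset manifest as JSON
#' @param dataset a `scene_dataset`.
#' @param path file path.
#' @export
write_manifest <- function(dataset, path) {
  jsonlite::write_json(dataset$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Synthetic per-frame mean-speed time series
#'
#' Baseline plus Gaussian-bump motion events plus white noise, emulating the
#' scene-wide mean optic-flow speed from which motion epochs are picked.
#' Ground-truth event frames are returned alongside the series.
#'
#' @param duration_s series duration in seconds.
#' @param frame_rate frames per second.
#' @param event_times event (bump centre) times in seconds, within the
#'   duration.
#' @param event_amps bump amplitudes in deg/s (recycled).
#' @param noise_sd white-noise sd in deg/s.
#' @param seed RNG seed.
#' @param baseline baseline mean speed in deg/s.
#' @param event_sd_s bump standard deviation in seconds.
#' @return list with `series` (deg/s per frame), `t` (seconds),
#'   `event_frames` (1-based ground-truth peak frames).
#' @export
generate_mean_speed_series <- function(duration_s, frame_rate,
                                       event_times = numeric(0),
                                       event_amps = 1,
                                       noise_sd = 0, seed = 1L,
                                       baseline = 0.2, event_sd_s = 1) {
  if (any(event_times < 0 | event_times > duration_s)) {
    stop("event_times must lie within the duration")
  }
  if (length(event_times) > 1L) {
    gaps <- diff(sort(event_times))
    if (any(gaps < 3)) {
      warning("events closer than 3 s: epoch selection may merge them")
    }
  }
  set.seed(seed)
  n <- round(duration_s * frame_rate)
  t <- (seq_len(n) - 1) / frame_rate
  series <- rep(baseline, n)
  amps <- rep_len(event_amps, length(event_times))
  for (i in seq_along(event_times)) {
    series <- series + amps[i] * exp(-(t - event_times[i])^2 / (2 * event_sd_s^2))
  }
  if (noise_sd > 0) series <- series + stats::rnorm(n, 0, noise_sd)
  series <- pmax(series, 0)
  list(series = series, t = t,
       event_frames = round(event_times * frame_rate) + 1L)
}
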