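# Gaze simulation: fixation selection by saliency median split, smooth
# pursuit (subtracting the fixated point's motion vector from the motion
# field) and vergence (binocular disparity geometry for a fixated distance).

# ---- saliency ---------------------------------------------------------------

# Truncated-window box mean via an integral image (edges use the actual
# overlap count).
box_mean <- function(x, half) {
  h <- nrow(x); w <- ncol(x)
  S <- rbind(0, cbind(0, t(apply(apply(x, 2L, cumsum), 1L, cumsum))))
  r1 <- pmax(seq_len(h) - half, 1L); r2 <- pmin(seq_len(h) + half, h)
  c1 <- pmax(seq_len(w) - half, 1L); c2 <- pmin(seq_len(w) + half, w)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

#' Local-intensity-variance saliency map
#'
#' A deterministic bottom-up saliency stand-in: per-pixel local variance of
#' the luminance channel over a square window.  High-contrast regions
#' (texture, object boundaries) attract candidate fixations; the map is
#' invariant to adding a constant to the image.
#'
#' @param luminance numeric luminance raster.
#' @param window half-width of the square window in pixels (default 3, i.e.
#'   a 7x7 window).
#' @return nonnegative saliency raster of the same shape.
#' @export
stand_in_saliency <- function(luminance, window = 3L) {
  stopifnot(is.matrix(luminance), all(is.finite(luminance)))
  m1 <- box_mean(luminance, window)
  m2 <- box_mean(luminance^2, window)
  pmax(m2 - m1^2, 0)
}

#' Candidate fixation pixels from a saliency map
#'
#' The upper half of a median split: pixels at or above the median salience.
#' With distinct salience values this selects `ceiling(N/2)` pixels; ties at
#' the median enlarge the set (all-tied maps make every pixel a candidate).
#'
#' @param saliency finite saliency raster.
#' @return logical raster of candidates.
#' @export
fixation_candidates <- function(saliency) {
  stopifnot(is.matrix(saliency), all(is.finite(saliency)))
  n <- length(saliency)
  cut <- sort(saliency, decreasing = TRUE)[ceiling(n / 2)]
  saliency >= cut
}

# ---- gaze state -------------------------------------------------------------

#' Gaze state at a fixation pixel
#'
#' Looks up the world motion and distance at the fixation pixel.  Pursuit is
#' active only when pursuit is enabled and the fixated point's world speed
#' exceeds the motion detection threshold (the 0.5 deg/s validity
#' threshold); a fixation on sub-threshold or missing motion is treated as
#' not moving.
#'
#' @param bundle a [scene_bundle()].
#' @param fixation `(row, col)` pixel of fixation; must not be sky.
#' @param pursuit_enabled simulate smooth pursuit of the fixated point?
#' @param interocular interocular separation in metres (default 0.062).
#' @return a `gaze_state` list: `fixation`, `fixation_motion` `(vx, vy)`
#'   deg/s, `pursuit_active`, `fixation_distance` m, `interocular`.
#' @export
gaze_state <- function(bundle, fixation, pursuit_enabled = TRUE,
                       interocular = 0.062) {
  stopifnot(inherits(bundle, "scene_bundle"), length(fixation) == 2L)
  if (interocular <= 0) stop("interocular separation must be positive")
  r <- fixation[1]; c <- fixation[2]
  if (r < 1 || r > bundle$meta$height || c < 1 || c > bundle$meta$width) {
    stop("fixation outside the raster")
  }
  if (bundle$label[r, c] == LABEL_SKY) stop("fixation on a sky pixel")
  sp <- bundle$speed[r, c]
  moving <- !is.na(sp) && sp > bundle$speed_threshold
  v <- c(0, 0)
  if (moving) {
    th <- bundle$direction[r, c] * pi / 180
    v <- sp * c(cos(th), sin(th))
  }
  structure(
    list(fixation = c(r, c), fixation_motion = v,
         pursuit_active = isTRUE(pursuit_enabled) && moving,
         fixation_distance = bundle$distance[r, c],
         interocular = interocular),
    class = "gaze_state"
  )
}

# ---- pursuit ----------------------------------------------------------------

# World motion components (vx rightward, vy upward) at given pixel indices.
motion_components <- function(bundle, idx = NULL) {
  sp <- bundle$speed; dir <- bundle$direction
  if (!is.null(idx)) { sp <- sp[idx]; dir <- dir[idx] }
  th <- dir * pi / 180
  list(vx = sp * cos(th), vy = sp * sin(th))
}

#' Retinal motion under smooth pursuit
#'
#' Subtracts the fixated point's motion vector from the world motion at
#' every pixel, simulating perfect smooth pursuit; with pursuit inactive
#' (stationary eye, or a fixation below the detection threshold) the world
#' motion is returned unchanged.  Speed and direction are recomputed from
#' the subtracted components; pixels without valid world motion stay
#' missing.
#'
#' @param bundle a [scene_bundle()].
#' @param gaze a [gaze_state()].
#' @return list of rasters `speed` (deg/s) and `direction` (deg in
#'   `[0, 360)`, NA where speed is 0 or world motion missing).
#' @export
retinal_motion <- function(bundle, gaze) {
  stopifnot(inherits(gaze, "gaze_state"))
  if (!gaze$pursuit_active) {
    return(list(speed = bundle$speed, direction = bundle$direction))
  }
  mc <- motion_components(bundle)
  vx <- mc$vx - gaze$fixation_motion[1]
  vy <- mc$vy - gaze$fixation_motion[2]
  sp <- sqrt(vx^2 + vy^2)
  dir <- (atan2(vy, vx) * 180 / pi) %% 360
  dir[!is.finite(sp) | sp == 0] <- NA_real_
  list(speed = sp, direction = dir)
}

# ---- disparity geometry -----------------------------------------------------

#' World coordinates of pixels from radial distances
#'
#' Reconstructs the Cartesian coordinates `[x y z]` (metres, z forward,
#' x rightward, y upward) of scene points from their pixel positions
#' (azimuth/elevation via the raster's angular convention) and their radial
#' distances from the recording device (a laser range scanner measures
#' distance along the line of sight).
#'
#' @param row,col pixel indices (vectorised).
#' @param distance_m radial distances in metres (> 0).
#' @param meta a [scene_metadata()].
#' @return an `n x 3` matrix of `[x y z]`.
#' @export
point_coordinates <- function(row, col, distance_m, meta) {
  if (any(distance_m <= 0, na.rm = TRUE)) stop("distances must be positive")
  ang <- pixel_angles(row, col, meta)
  az <- ang$ax * pi / 180
  el <- ang$ay * pi / 180
  cbind(x = distance_m * cos(el) * sin(az),
        y = distance_m * sin(el),
        z = distance_m * cos(el) * cos(az))
}

#' Horizontal binocular disparity of scene points
#'
#' The two eyes are offset symmetrically by half the interocular separation
#' `s` along the horizontal axis, and verged on the fixated point.  For each
#' eye the horizontal angular eccentricity of a point is the difference of
#' the azimuths of the fixated point and the target point in that eye's
#' coordinates; the disparity is the difference between the two eyes'
#' eccentricities (left minus right).  Crossed disparities (points nearer
#' than fixation) are positive, uncrossed negative.
#'
#' @param P `n x 3` matrix (or length-3 vector) of point coordinates, m.
#' @param P_fix length-3 coordinates of the fixated point, m.
#' @param s interocular separation in metres (default 0.062).
#' @return horizontal disparity in degrees (length n).
#' @export
binocular_disparity <- function(P, P_fix, s = 0.062) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3L)
  stopifnot(ncol(P) == 3L, length(P_fix) == 3L, s > 0)
  if (P_fix[3] <= 0 || any(P[, 3] <= 0, na.rm = TRUE)) {
    stop("points must lie in front of the eyes (z > 0)")
  }
  eye_ecc <- function(x, z, x_fix, z_fix) {
    atan(x_fix / z_fix) - atan(x / z)
  }
  xR <- 0.5 * s - P[, 1];  xL <- -0.5 * s - P[, 1]
  xR_fix <- 0.5 * s - P_fix[1]; xL_fix <- -0.5 * s - P_fix[1]
  thR <- eye_ecc(xR, P[, 3], xR_fix, P_fix[3])
  thL <- eye_ecc(xL, P[, 3], xL_fix, P_fix[3])
  (thL - thR) * 180 / pi
}

#' Per-pixel binocular disparity map for a gaze state
#'
#' Applies [binocular_disparity()] to every pixel with a distance
#' measurement, verged on the fixated pixel's world point.
#'
#' @param bundle a [scene_bundle()].
#' @param gaze a [gaze_state()]; its fixation distance must be present.
#' @return disparity raster in degrees (NA where distance missing).
#' @export
disparity_map <- function(bundle, gaze) {
  stopifnot(inherits(gaze, "gaze_state"))
  if (is.na(gaze$fixation_distance)) {
    stop("fixation distance is missing; cannot simulate vergence")
  }
  meta <- bundle$meta
  P_fix <- point_coordinates(gaze$fixation[1], gaze$fixation[2],
                             gaze$fixation_distance, meta)[1L, ]
  out <- matrix(NA_real_, meta$height, meta$width)
  ok <- which(!is.na(bundle$distance))
  if (length(ok) == 0L) return(out)
  rc <- arrayInd(ok, dim(bundle$distance))
  P <- point_coordinates(rc[, 1], rc[, 2], bundle$distance[ok], meta)
  out[ok] <- binocular_disparity(P, P_fix, gaze$interocular)
  out
}
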