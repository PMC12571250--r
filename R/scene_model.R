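# Scene raster data model shared by every analysis stage.
#
# A scene bundle holds co-registered per-pixel rasters: world motion speed
# (deg/s) and direction (deg, 0 = rightward, 90 = upward), radial distance
# from the recording device (m), a label map (0 = sky, 1..K = figure ids,
# 255 = ground), an optional saliency map, and metadata giving the angular
# resolution.  Missing measurements are NA.

#' Label code for sky pixels
#' @export
LABEL_SKY <- 0L

#' Label code for ground pixels
#' @export
LABEL_GROUND <- 255L

#' Scene metadata
#'
#' @param deg_per_pixel angular resolution in degrees per pixel (> 0).
#' @param frame_rate acquisition frame rate in Hz (> 0).
#' @param height,width raster dimensions in pixels.
#' @param field_of_view optional numeric length-2 field of view in degrees
#'   (width, height); defaults to `dims * deg_per_pixel`.  Must agree with
#'   the dimensions and resolution to within 10%.
#' @param site_tag free-text tag describing the recording site.
#' @return a `scene_metadata` object (a named list).
#' @export
scene_metadata <- function(deg_per_pixel, frame_rate, height, width,
                           field_of_view = NULL, site_tag = "") {
  if (!is.numeric(deg_per_pixel) || deg_per_pixel <= 0) {
    stop("deg_per_pixel must be a positive number")
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be a positive number")
  }
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("raster dimensions must be positive")
  if (is.null(field_of_view)) {
    field_of_view <- c(width, height) * deg_per_pixel
  }
  expected <- c(width, height) * deg_per_pixel
  if (any(abs(field_of_view - expected) > 0.1 * expected)) {
    stop("field_of_view inconsistent with dims x deg_per_pixel (>10% off)")
  }
  structure(
    list(deg_per_pixel = deg_per_pixel, frame_rate = frame_rate,
         height = height, width = width,
         field_of_view = as.numeric(field_of_view),
         site_tag = as.character(site_tag)),
    class = "scene_metadata"
  )
}

#' Convert a pixel/frame displacement to an angular speed
#'
#' Camera displacements in pixels per frame map linearly to retinal speeds:
#' `v * deg_per_pixel * frame_rate`.
#'
#' @param v displacement in pixels/frame (>= 0); vectorised.
#' @param meta a [scene_metadata()] object.
#' @return speed in deg/s.
#' @examples
#' m <- scene_metadata(0.04, 120, 1024, 1024)
#' pxframe_to_degs(0.14, m)  # 0.672 deg/s
#' @export
pxframe_to_degs <- function(v, meta) {
  stopifnot(inherits(meta, "scene_metadata"))
  if (any(v < 0, na.rm = TRUE)) stop("pixel/frame displacement must be >= 0")
  v * meta$deg_per_pixel * meta$frame_rate
}

#' Angular resolution from a field of view
#'
#' @param fov_deg field of view extent in degrees (> 0).
#' @param n_pixels number of pixels spanning it (> 0).
#' @return resolution in deg/pixel.
#' @export
fov_to_degperpixel <- function(fov_deg, n_pixels) {
  if (any(fov_deg <= 0)) stop("fov_deg must be positive")
  if (any(n_pixels <= 0)) stop("n_pixels must be positive")
  fov_deg / n_pixels
}

#' Exclusion buffer around annotation borders
#'
#' Marks every pixel within `buffer_px` (Chebyshev distance, i.e. a square
#' structuring element) of a differently-labelled pixel.  These pixels are
#' excluded from both figure and ground statistics so that imperfect
#' annotation borders cannot cross-contaminate the two regions.
#'
#' @param label_map integer label raster.
#' @param buffer_px buffer radius in pixels (default 5).
#' @return logical raster, TRUE where excluded.
#' @export
boundary_buffer_mask <- function(label_map, buffer_px = 5L) {
  stopifnot(is.matrix(label_map))
  buffer_px <- as.integer(buffer_px)
  if (buffer_px < 0L) stop("buffer_px must be >= 0")
  h <- nrow(label_map); w <- ncol(label_map)
  out <- matrix(FALSE, h, w)
  if (buffer_px == 0L) return(out)
  for (dr in -buffer_px:buffer_px) {
    for (dc in -buffer_px:buffer_px) {
      if (dr == 0L && dc == 0L) next
      r1 <- max(1L, 1L - dr):min(h, h - dr)
      c1 <- max(1L, 1L - dc):min(w, w - dc)
      differs <- label_map[r1, c1, drop = FALSE] !=
        label_map[r1 + dr, c1 + dc, drop = FALSE]
      out[r1, c1] <- out[r1, c1, drop = FALSE] | differs
    }
  }
  out
}

#' Above-threshold motion validity mask
#'
#' Motion estimates at or below the noise floor are treated as missing.
#' A pixel is valid when its speed strictly exceeds `threshold`, is not NA,
#' and (when a label map is supplied) is not sky.
#'
#' @param speed_map speed raster in deg/s.
#' @param threshold validity threshold in deg/s (default 0.5).
#' @param label_map optional label raster; sky pixels are forced invalid.
#' @return logical raster.
#' @export
speed_threshold_mask <- function(speed_map, threshold = 0.5, label_map = NULL) {
  stopifnot(is.matrix(speed_map))
  if (threshold < 0) stop("threshold must be >= 0")
  ok <- !is.na(speed_map) & speed_map > threshold
  if (!is.null(label_map)) ok <- ok & (label_map != LABEL_SKY)
  ok
}

#' Construct a scene bundle
#'
#' @param speed,direction,distance numeric rasters (deg/s, deg, m); NA for
#'   missing.  Directions are wrapped into `[0, 360)`.
#' @param label integer label raster (0 sky, 1..K figure ids, 255 ground).
#' @param meta a [scene_metadata()] object.
#' @param saliency optional nonnegative saliency raster.
#' @param luminance optional luminance raster (used to derive saliency).
#' @param speed_threshold motion validity threshold in deg/s.
#' @param buffer_px annotation-border buffer radius in pixels.
#' @param check if TRUE require at least one figure id and some ground.
#' @return a `scene_bundle` object.
#' @export
scene_bundle <- function(speed, direction, distance, label, meta,
                         saliency = NULL, luminance = NULL,
                         speed_threshold = 0.5, buffer_px = 5L,
                         check = TRUE) {
  stopifnot(inherits(meta, "scene_metadata"))
  dims <- c(meta$height, meta$width)
  rasters <- list(speed = speed, direction = direction, distance = distance,
                  label = label, saliency = saliency, luminance = luminance)
  for (nm in names(rasters)) {
    r <- rasters[[nm]]
    if (is.null(r)) next
    if (!is.matrix(r) || !all(dim(r) == dims)) {
      stop(sprintf("raster '%s' does not match metadata dims %dx%d",
                   nm, dims[1], dims[2]))
    }
  }
  label <- matrix(as.integer(label), dims[1], dims[2])
  known <- label %in% c(LABEL_SKY, LABEL_GROUND) | (label >= 1L & label <= 250L)
  if (!all(known)) stop("label map contains unknown label codes")
  sky <- label == LABEL_SKY
  speed[sky] <- NA_real_
  distance[sky] <- NA_real_
  if (any(speed < 0, na.rm = TRUE)) stop("speeds must be nonnegative")
  if (any(distance <= 0, na.rm = TRUE)) stop("distances must be positive")
  direction <- direction %% 360
  valid <- speed_threshold_mask(speed, speed_threshold, label)
  direction[!valid] <- NA_real_
  if (check) {
    if (!any(label == LABEL_GROUND)) stop("bundle has no ground pixels")
    if (!any(label >= 1L & label <= 250L)) stop("bundle has no figure pixels")
  }
  structure(
    list(speed = speed, direction = direction, distance = distance,
         label = label, saliency = saliency, luminance = luminance,
         buffer_mask = boundary_buffer_mask(label, buffer_px),
         valid_motion = valid,
         speed_threshold = speed_threshold, buffer_px = as.integer(buffer_px),
         meta = meta),
    class = "scene_bundle"
  )
}

#' @export
print.scene_bundle <- function(x, ...) {
  m <- x$meta
  figs <- sort(unique(x$label[x$label >= 1L & x$label <= 250L]))
  cat(sprintf("<scene_bundle> %dx%d px (%.3g deg/px), %d figure id(s)\n",
              m$height, m$width, m$deg_per_pixel, length(figs)))
  cat(sprintf("  valid motion: %.1f%%  sky: %.1f%%  buffer: %.1f%%\n",
              100 * mean(x$valid_motion), 100 * mean(x$label == LABEL_SKY),
              100 * mean(x$buffer_mask)))
  invisible(x)
}

# ---- I/O --------------------------------------------------------------------
# Floating rasters go to 32-bit-sampled single-channel TIFF scaled to [0,1]
# with the value range stored in the JSON sidecar (precision: raster range
# times 2^-32); a companion mask TIFF encodes per-pixel validity so NA
# round-trips.  Labels are an 8-bit PNG.

mask_path <- function(path) sub("\\.tif$", ".mask.tif", path)

write_float_tiff <- function(x, path) {
  ok <- is.finite(x)
  if (!any(ok)) {
    vmin <- 0; vmax <- 1
  } else {
    vmin <- min(x[ok]); vmax <- max(x[ok])
  }
  scale <- if (vmax > vmin) vmax - vmin else 1
  plane <- (x - vmin) / scale
  plane[!ok] <- 0
  tiff::writeTIFF(plane, path, bits.per.sample = 32L,
                  compression = "deflate")
  if (!all(ok)) {
    tiff::writeTIFF((!ok) * 1, mask_path(path), bits.per.sample = 8L,
                    compression = "deflate")
  }
  list(vmin = vmin, vmax = vmax)
}

read_float_tiff <- function(path, rng) {
  plane <- tiff::readTIFF(path)
  stopifnot(is.matrix(plane))
  scale <- if (rng$vmax > rng$vmin) rng$vmax - rng$vmin else 1
  x <- plane * scale + rng$vmin
  if (file.exists(mask_path(path))) {
    x[tiff::readTIFF(mask_path(path)) > 0.5] <- NA_real_
  }
  x
}

#' Write a scene bundle to a directory
#'
#' Writes `speed.tif`, `direction.tif`, `distance.tif` (and `saliency.tif`,
#' `luminance.tif` when present), `label.png` and `meta.json` under `path`.
#'
#' @param bundle a [scene_bundle()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "scene_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  channels <- c("speed", "direction", "distance", "saliency", "luminance")
  ranges <- list()
  for (ch in channels) {
    if (is.null(bundle[[ch]])) next
    ranges[[ch]] <- write_float_tiff(bundle[[ch]],
                                     file.path(path, paste0(ch, ".tif")))
  }
  png::writePNG(bundle$label / 255, file.path(path, "label.png"))
  meta <- bundle$meta
  side <- list(
    deg_per_pixel = meta$deg_per_pixel, frame_rate = meta$frame_rate,
    height = meta$height, width = meta$width,
    field_of_view = meta$field_of_view, site_tag = meta$site_tag,
    speed_threshold = bundle$speed_threshold, buffer_px = bundle$buffer_px,
    ranges = ranges
  )
  jsonlite::write_json(side, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene bundle from a directory
#'
#' @param path directory previously written by [write_bundle()].
#' @return a [scene_bundle()].
#' @export
read_bundle <- function(path) {
  mj <- file.path(path, "meta.json")
  if (!file.exists(mj)) stop("missing meta.json under ", path)
  side <- jsonlite::read_json(mj, simplifyVector = TRUE)
  meta <- scene_metadata(side$deg_per_pixel, side$frame_rate,
                         side$height, side$width, side$field_of_view,
                         side$site_tag)
  get_ch <- function(ch, required) {
    f <- file.path(path, paste0(ch, ".tif"))
    if (!file.exists(f)) {
      if (required) stop("missing channel '", ch, "' under ", path)
      return(NULL)
    }
    read_float_tiff(f, as.list(side$ranges[[ch]]))
  }
  speed <- get_ch("speed", TRUE)
  direction <- get_ch("direction", TRUE)
  distance <- get_ch("distance", TRUE)
  saliency <- get_ch("saliency", FALSE)
  luminance <- get_ch("luminance", FALSE)
  lab_raw <- png::readPNG(file.path(path, "label.png"))
  if (length(dim(lab_raw)) == 3L) lab_raw <- lab_raw[, , 1L]
  label <- matrix(as.integer(round(lab_raw * 255)), meta$height, meta$width)
  scene_bundle(speed, direction, distance, label, meta,
               saliency = saliency, luminance = luminance,
               speed_threshold = side$speed_threshold,
               buffer_px = side$buffer_px)
}

#' Angular position of pixels relative to the raster centre
#'
#' Returns azimuth/elevation offsets in degrees with +x rightward and
#' +y upward (consistent with the motion direction convention).
#'
#' @param row,col pixel indices (1-based); vectorised.
#' @param meta a [scene_metadata()].
#' @return list with components `ax`, `ay` (deg).
#' @export
pixel_angles <- function(row, col, meta) {
  cr <- (meta$height + 1) / 2
  cc <- (meta$width + 1) / 2
  list(ax = (col - cc) * meta$deg_per_pixel,
       ay = (cr - row) * meta$deg_per_pixel)
}
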