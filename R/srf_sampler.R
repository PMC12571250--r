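# Simulated receptive field (sRF) sampling: place circular apertures of
# 2.5/5/10/15 deg diameter at random scene positions, attach a fixation at
# matching eccentricity from the saliency candidates, and keep only samples
# with enough figure, enough ground, and enough valid measurements.

srf_radius_px <- function(diameter_deg, meta) {
  diameter_deg / 2 / meta$deg_per_pixel
}

# Linear-index offsets of the circular aperture (pixel centres strictly
# inside the circle), relative to a centre pixel, for a raster with h rows.
disk_offsets <- function(radius_px, h) {
  r <- ceiling(radius_px)
  dr <- rep(-r:r, times = 2L * r + 1L)
  dc <- rep(-r:r, each = 2L * r + 1L)
  keep <- dr^2 + dc^2 < radius_px^2
  list(dr = dr[keep], dc = dc[keep], lin = dc[keep] * h + dr[keep])
}

#' Propose a random sRF centre
#'
#' Uniform over all pixel centres for which the full circular aperture lies
#' inside the raster.
#'
#' @param bundle a [scene_bundle()].
#' @param diameter_deg aperture diameter in degrees.
#' @return `(row, col)` centre.
#' @export
propose_srf <- function(bundle, diameter_deg) {
  meta <- bundle$meta
  r_px <- srf_radius_px(diameter_deg, meta)
  rlo <- ceiling(1 + r_px); rhi <- floor(meta$height - r_px)
  clo <- ceiling(1 + r_px); chi <- floor(meta$width - r_px)
  if (rlo > rhi || clo > chi) {
    stop("aperture of ", diameter_deg, " deg does not fit in the raster")
  }
  c(sample(rlo:rhi, 1L), sample(clo:chi, 1L))
}

#' Assign a fixation at matching eccentricity
#'
#' Picks a uniform random candidate pixel whose distance from the sRF
#' centre lies in the annulus `diameter * [1 - tol, 1 + tol]` (receptive
#' field sizes of MT neurons roughly match their eccentricities, so the
#' fixation must sit about one diameter away from the aperture centre).
#' Sky pixels are never eligible.  An empty annulus is a normal rejection.
#'
#' @param bundle a [scene_bundle()].
#' @param center sRF centre `(row, col)`.
#' @param diameter_deg aperture diameter (= target eccentricity) in deg.
#' @param candidates logical candidate raster
#'   (see [fixation_candidates()]).
#' @param tol relative annulus tolerance (default 0.1).
#' @return `(row, col)` fixation, or NULL when the annulus holds no
#'   candidate.
#' @export
assign_fixation <- function(bundle, center, diameter_deg, candidates,
                            tol = 0.1) {
  meta <- bundle$meta
  ecc_px <- diameter_deg / meta$deg_per_pixel
  ok <- which(candidates & bundle$label != LABEL_SKY)
  if (length(ok) == 0L) return(NULL)
  rc <- arrayInd(ok, dim(candidates))
  d <- sqrt((rc[, 1] - center[1])^2 + (rc[, 2] - center[2])^2)
  in_ann <- d >= (1 - tol) * ecc_px & d <= (1 + tol) * ecc_px
  if (!any(in_ann)) return(NULL)
  pick <- which(in_ann)
  pick <- pick[sample.int(length(pick), 1L)]
  c(rc[pick, 1], rc[pick, 2])
}

#' Validate an sRF placement
#'
#' Applies the acceptance rules in a fixed order: at most 50% invalid
#' pixels (sky, missing distance, or motion at/below threshold), then at
#' least 25% figure and 25% ground among the aperture pixels outside the
#' annotation-border buffer.  The figure and ground pixel sets returned
#' exclude buffer and sky pixels.
#'
#' @param bundle a [scene_bundle()].
#' @param center sRF centre `(row, col)`.
#' @param diameter_deg aperture diameter in degrees.
#' @return list with `accept`, `reason` (`"ok"`, `"invalid_fraction"`,
#'   `"figure_fraction"` or `"ground_fraction"`), the three fractions, and
#'   linear pixel index vectors `figure_idx`, `ground_idx`.
#' @export
validate_srf <- function(bundle, center, diameter_deg) {
  meta <- bundle$meta
  h <- meta$height
  off <- disk_offsets(srf_radius_px(diameter_deg, meta), h)
  idx <- (center[2] - 1L) * h + center[1] + off$lin
  lab <- bundle$label[idx]
  invalid <- !bundle$valid_motion[idx] | is.na(bundle$distance[idx])
  nb <- !bundle$buffer_mask[idx]
  is_fig <- lab >= 1L & lab <= 250L
  is_gnd <- lab == LABEL_GROUND
  fr <- list(invalid = mean(invalid),
             figure = sum(is_fig & nb) / max(sum(nb), 1L),
             ground = sum(is_gnd & nb) / max(sum(nb), 1L))
  reason <- if (fr$invalid > 0.5) "invalid_fraction"
    else if (fr$figure < 0.25) "figure_fraction"
    else if (fr$ground < 0.25) "ground_fraction"
    else "ok"
  list(accept = reason == "ok", reason = reason,
       invalid_fraction = fr$invalid, figure_fraction = fr$figure,
       ground_fraction = fr$ground,
       figure_idx = idx[is_fig & nb], ground_idx = idx[is_gnd & nb])
}

#' Build a set of accepted sRF samples over a dataset
#'
#' Rejection-samples sRF placements (random scene, random centre, validity
#' rules, eccentricity-matched fixation) until `n_per_size` samples are
#' accepted for every diameter.  Provenance (scene, rejection reasons) is
#' recorded.  No cap is placed on the number of distinct figure regions in
#' an sRF.
#'
#' @param dataset a `scene_dataset` (see [generate_dataset()]).
#' @param n_per_size accepted samples per diameter (default 200).
#' @param sizes aperture diameters in degrees.
#' @param seed RNG seed for the whole sampling pass.
#' @param pursuit_enabled simulate smooth pursuit at the fixations?
#' @param tol fixation annulus tolerance (default 0.1).
#' @param min_accept_rate abort (with diagnostics) if the acceptance rate
#'   for a size falls below this floor.
#' @return an `srf_set`: list with `samples` (list of sRF records: scene
#'   id, centre, diameter, eccentricity in deg, [gaze_state()], figure and
#'   ground pixel indices, fractions), `table` (one row per sample),
#'   `reject_counts`, and `attempts`.
#' @export
build_srf_set <- function(dataset, n_per_size = 200L,
                          sizes = c(2.5, 5, 10, 15), seed = 1L,
                          pursuit_enabled = TRUE, tol = 0.1,
                          min_accept_rate = 1e-3) {
  stopifnot(inherits(dataset, "scene_dataset"))
  set.seed(seed)
  bundles <- dataset$bundles
  # per-scene precomputations: candidate fixation coordinates and the
  # rasters the validity rules consult
  pre <- lapply(bundles, function(b) {
    if (is.null(b$saliency)) stop("bundle lacks a saliency map")
    cand_idx <- which(fixation_candidates(b$saliency) &
                        b$label != LABEL_SKY)
    rc <- arrayInd(cand_idx, dim(b$label))
    list(cand_row = rc[, 1], cand_col = rc[, 2],
         is_fig = b$label >= 1L & b$label <= 250L,
         invalid = !b$valid_motion | is.na(b$distance),
         nb = !b$buffer_mask)
  })
  samples <- list()
  rejects <- c(invalid_fraction = 0L, figure_fraction = 0L,
               ground_fraction = 0L, no_fixation = 0L)
  attempts <- 0L
  for (diam in sizes) {
    got <- 0L
    size_attempts <- 0L
    max_attempts <- ceiling(n_per_size / min_accept_rate)
    off_cache <- lapply(bundles, function(b)
      disk_offsets(srf_radius_px(diam, b$meta), b$meta$height))
    while (got < n_per_size) {
      size_attempts <- size_attempts + 1L
      if (size_attempts > max_attempts) {
        stop(sprintf(
          "acceptance rate below %.1g for %.3g deg sRFs after %d attempts (rejects: %s)",
          min_accept_rate, diam, size_attempts - 1L,
          paste(names(rejects), rejects, sep = "=", collapse = ", ")))
      }
      si <- sample.int(length(bundles), 1L)
      b <- bundles[[si]]; pp <- pre[[si]]
      center <- propose_srf(b, diam)
      idx <- (center[2] - 1L) * b$meta$height + center[1] +
        off_cache[[si]]$lin
      is_fig <- pp$is_fig[idx]; nb <- pp$nb[idx]
      is_gnd <- b$label[idx] == LABEL_GROUND
      inv_frac <- mean(pp$invalid[idx])
      nnb <- max(sum(nb), 1L)
      fig_frac <- sum(is_fig & nb) / nnb
      gnd_frac <- sum(is_gnd & nb) / nnb
      reason <- if (inv_frac > 0.5) "invalid_fraction"
        else if (fig_frac < 0.25) "figure_fraction"
        else if (gnd_frac < 0.25) "ground_fraction"
        else "ok"
      if (reason != "ok") {
        rejects[reason] <- rejects[reason] + 1L
        next
      }
      val <- list(figure_idx = idx[is_fig & nb], ground_idx = idx[is_gnd & nb],
                  invalid_fraction = inv_frac, figure_fraction = fig_frac,
                  ground_fraction = gnd_frac)
      ecc_px <- diam / b$meta$deg_per_pixel
      d2 <- (pp$cand_row - center[1])^2 + (pp$cand_col - center[2])^2
      in_ann <- d2 >= ((1 - tol) * ecc_px)^2 & d2 <= ((1 + tol) * ecc_px)^2
      if (!any(in_ann)) {
        rejects["no_fixation"] <- rejects["no_fixation"] + 1L
        next
      }
      pick <- which(in_ann)
      pick <- pick[sample.int(length(pick), 1L)]
      fix <- c(pp$cand_row[pick], pp$cand_col[pick])
      gz <- gaze_state(b, fix, pursuit_enabled = pursuit_enabled)
      got <- got + 1L
      samples[[length(samples) + 1L]] <- list(
        scene_id = si, center = center, diameter = diam,
        eccentricity = sqrt(sum((fix - center)^2)) * b$meta$deg_per_pixel,
        gaze = gz,
        figure_idx = val$figure_idx, ground_idx = val$ground_idx,
        figure_fraction = val$figure_fraction,
        ground_fraction = val$ground_fraction,
        invalid_fraction = val$invalid_fraction)
    }
    attempts <- attempts + size_attempts
  }
  tab <- do.call(rbind, lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    data.frame(srf_id = i, scene_id = s$scene_id,
               center_row = s$center[1], center_col = s$center[2],
               diameter = s$diameter, eccentricity = s$eccentricity,
               fix_row = s$gaze$fixation[1], fix_col = s$gaze$fixation[2],
               pursuit_active = s$gaze$pursuit_active,
               fixation_distance = s$gaze$fixation_distance,
               figure_fraction = s$figure_fraction,
               ground_fraction = s$ground_fraction,
               invalid_fraction = s$invalid_fraction,
               fix_on_figure = {
                 lab <- dataset$bundles[[s$scene_id]]$label[
                   s$gaze$fixation[1], s$gaze$fixation[2]]
                 lab >= 1L && lab <= 250L
               })
  }))
  structure(list(samples = samples, table = tab,
                 reject_counts = rejects, attempts = attempts,
                 pursuit_enabled = pursuit_enabled),
            class = "srf_set")
}

#' @export
print.srf_set <- function(x, ...) {
  cat(sprintf("<srf_set> %d samples (%d attempts, pursuit %s)\n",
              length(x$samples), x$attempts,
              if (x$pursuit_enabled) "on" else "off"))
  print(table(x$table$diameter))
  invisible(x)
}
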