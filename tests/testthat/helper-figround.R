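# Shared fixtures, built in code.

# Small-canvas generator parameters for fast tests (same angular resolution
# as the defaults, smaller field of view).
test_params <- function(...) {
  scene_gen_params(height = 192L, width = 192L, fov_deg = 21,
                   figure_radius_deg = c(3, 5), ...)
}

# A deterministic toy bundle with uniform motion and a square figure.
# Distances are constant (frontoparallel) unless a distance matrix is given.
make_toy_bundle <- function(h = 40L, w = 40L, speed = 10, direction = 0,
                            distance = 10, deg_per_pixel = 0.25,
                            fig_rows = 11:20, fig_cols = 11:20,
                            sky_rows = integer(0), buffer_px = 0L) {
  lab <- matrix(figround::LABEL_GROUND, h, w)
  lab[fig_rows, fig_cols] <- 1L
  if (length(sky_rows)) lab[sky_rows, ] <- figround::LABEL_SKY
  sp <- matrix(speed, h, w)
  dir <- matrix(direction, h, w)
  dst <- if (is.matrix(distance)) distance else matrix(distance, h, w)
  meta <- scene_metadata(deg_per_pixel, 120, h, w)
  scene_bundle(sp, dir, dst, lab, meta,
               saliency = matrix(1, h, w), buffer_px = buffer_px)
}

# Brute-force per-pixel oracle for the annotation-border buffer.
brute_buffer <- function(label, b) {
  h <- nrow(label); w <- ncol(label)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    for (dr in -b:b) for (dc in -b:b) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
          label[rr, cc] != label[r, c]) {
        out[r, c] <- TRUE
      }
    }
  }
  out
}
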