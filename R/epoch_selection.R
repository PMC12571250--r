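# Motion-epoch selection from a per-frame mean-speed time series: smooth the
# series with a wide Gaussian window, take the two highest well-separated
# local maxima as motion peaks, and mark motion onset/offset as the frames
# whose raw mean speed is closest to half the peak speed in the 2.5 s
# windows before/after each peak.

#' Gaussian smoothing of a mean-speed series
#'
#' Convolution with a Gaussian kernel (truncated at 4 sigma), edge-truncated
#' and renormalised so the effective kernel always integrates to one.
#'
#' @param series numeric per-frame series; must be longer than
#'   `6 * sigma_frames`.
#' @param sigma_frames kernel standard deviation in frames (default 120).
#' @return smoothed series of the same length.
#' @export
smooth_series <- function(series, sigma_frames = 120) {
  n <- length(series)
  if (n <= 6 * sigma_frames) {
    stop("series too short for sigma_frames = ", sigma_frames)
  }
  half <- ceiling(4 * sigma_frames)
  k <- stats::dnorm(-half:half, sd = sigma_frames)
  pad <- function(x) c(rep(0, half), x, rep(0, half))
  num <- stats::filter(pad(series), k, sides = 2)
  den <- stats::filter(pad(rep(1, n)), k, sides = 2)
  as.numeric(num[half + seq_len(n)] / den[half + seq_len(n)])
}

# Local maxima of a series: strictly greater than both neighbours; plateaus
# contribute their centre frame.  Endpoints are not maxima.
local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i > 1L && r$values[i] > r$values[i - 1L]
    right_ok <- i < k && r$values[i] > r$values[i + 1L]
    if (left_ok && right_ok) {
      out <- c(out, floor((starts[i] + ends[i]) / 2))
    }
  }
  out
}

#' Select two motion epochs from a mean-speed series
#'
#' The two highest local maxima of the smoothed series at a minimum
#' separation of 3 s become the motion peaks.  For each, the onset is the
#' frame in the 2.5 s window before the peak whose raw mean speed is
#' closest to 50% of the raw peak speed; the offset is found the same way
#' in the 2.5 s window after.  Ties break toward the frame nearest the
#' peak.
#'
#' @param smoothed smoothed series (see [smooth_series()]).
#' @param raw raw series of the same length.
#' @param frame_rate frames per second.
#' @param min_sep_s minimum peak separation in seconds (default 3).
#' @param window_s onset/offset search window in seconds (default 2.5).
#' @return a data.frame with one row per epoch (ordered by frame):
#'   `peak_frame`, `onset_frame`, `offset_frame`, `peak_speed`.
#' @export
select_epochs <- function(smoothed, raw, frame_rate,
                          min_sep_s = 3, window_s = 2.5) {
  stopifnot(length(smoothed) == length(raw))
  n <- length(raw)
  cand <- local_maxima(smoothed)
  if (length(cand) < 2L) stop("fewer than two local maxima in the series")
  cand <- cand[order(smoothed[cand], decreasing = TRUE)]
  min_sep <- min_sep_s * frame_rate
  picked <- cand[1L]
  for (f in cand[-1L]) {
    if (all(abs(f - picked) >= min_sep)) {
      picked <- c(picked, f)
      break
    }
  }
  if (length(picked) < 2L) {
    stop("no second local maximum at >= ", min_sep_s, " s separation")
  }
  win <- round(window_s * frame_rate)
  half_match <- function(peak, side) {
    frames <- if (side == "before") {
      max(1L, peak - win):(peak - 1L)
    } else {
      (peak + 1L):min(n, peak + win)
    }
    if (length(frames) == 0L) stop("no frames in the ", side, " window")
    err <- abs(raw[frames] - 0.5 * raw[peak])
    # ties toward the frame nearest the peak
    best <- which(err == min(err))
    frames[best][which.min(abs(frames[best] - peak))]
  }
  res <- lapply(sort(picked), function(p) {
    data.frame(peak_frame = p,
               onset_frame = half_match(p, "before"),
               offset_frame = half_match(p, "after"),
               peak_speed = raw[p])
  })
  do.call(rbind, res)
}
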