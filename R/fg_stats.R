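# Figure-ground statistics: per-sRF region summaries (mean log10 retinal
# speed, circular variance of retinal direction, mean disparity), the
# associated hypothesis tests and effect sizes, global per-class frequency
# distributions, and figure/ground probability-ratio curves with bootstrap
# confidence intervals.

# ---- per-sRF feature extraction ---------------------------------------------

# Retinal speed (deg/s), retinal direction (deg) and disparity (deg) for the
# figure and ground pixel sets of one sRF.  Motion values come from pixels
# with valid world motion only; with pursuit active the fixation vector is
# subtracted from the world motion components.  Disparity values come from
# pixels with distance measurements, verged on the fixated point.
srf_region_features <- function(srf, bundle, floor_speed = 0.01) {
  gaze <- srf$gaze
  meta <- bundle$meta
  P_fix <- if (!is.na(gaze$fixation_distance)) {
    point_coordinates(gaze$fixation[1], gaze$fixation[2],
                      gaze$fixation_distance, meta)[1L, ]
  } else NULL
  one_region <- function(idx) {
    vm <- bundle$valid_motion[idx]
    midx <- idx[vm]
    mc <- motion_components(bundle, midx)
    vx <- mc$vx; vy <- mc$vy
    if (gaze$pursuit_active) {
      vx <- vx - gaze$fixation_motion[1]
      vy <- vy - gaze$fixation_motion[2]
    }
    sp <- sqrt(vx^2 + vy^2)
    dir <- (atan2(vy, vx) * 180 / pi) %% 360
    dir[sp == 0] <- NA_real_
    disp <- numeric(0)
    didx <- idx[!is.na(bundle$distance[idx])]
    if (!is.null(P_fix) && length(didx) > 0L) {
      rc <- arrayInd(didx, c(meta$height, meta$width))
      P <- point_coordinates(rc[, 1], rc[, 2], bundle$distance[didx], meta)
      disp <- binocular_disparity(P, P_fix, gaze$interocular)
    }
    list(speed = pmax(sp, floor_speed), direction = dir, disparity = disp)
  }
  list(figure = one_region(srf$figure_idx),
       ground = one_region(srf$ground_idx))
}

#' Per-sRF figure and ground region summary
#'
#' Computes, for one sRF, the mean log10 retinal speed, the circular
#' variance of retinal directions and the mean binocular disparity in the
#' figure region and in the ground region.  Retinal speeds below
#' `floor_speed` deg/s are floored before taking logs (perfect pursuit can
#' null figure motion exactly).  A region with no valid pixels yields NA
#' for that feature.
#'
#' @param srf one sample from an `srf_set`.
#' @param bundle the [scene_bundle()] the sample came from.
#' @param floor_speed log-flooring threshold in deg/s (default 0.01).
#' @return one-row data.frame with `s_f`, `s_g`, `v_f`, `v_g`, `d_f`,
#'   `d_g`, valid counts `n_f`, `n_g`, and the sample's diameter and
#'   eccentricity.
#' @export
region_summary <- function(srf, bundle, floor_speed = 0.01) {
  summary_from_features(srf_region_features(srf, bundle, floor_speed), srf)
}

#' Extract per-pixel features for every sRF in a set
#'
#' Computes retinal speed, retinal direction and binocular disparity for
#' the figure and ground pixel sets of each sample once, so that summaries
#' and ratio curves can share the result.
#'
#' @param srf_set an `srf_set` (see [build_srf_set()]).
#' @param dataset the `scene_dataset` it was sampled from.
#' @param floor_speed log-flooring threshold in deg/s.
#' @return list (one element per sRF) of `figure`/`ground` feature lists.
#' @export
srf_features <- function(srf_set, dataset, floor_speed = 0.01) {
  stopifnot(inherits(srf_set, "srf_set"), inherits(dataset, "scene_dataset"))
  lapply(srf_set$samples, function(s) {
    srf_region_features(s, dataset$bundles[[s$scene_id]], floor_speed)
  })
}

summary_from_features <- function(ft, srf) {
  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  cv_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else circular_variance(x)
  }
  data.frame(
    s_f = mean_or_na(log10(ft$figure$speed)),
    s_g = mean_or_na(log10(ft$ground$speed)),
    v_f = cv_or_na(ft$figure$direction),
    v_g = cv_or_na(ft$ground$direction),
    d_f = mean_or_na(ft$figure$disparity),
    d_g = mean_or_na(ft$ground$disparity),
    n_f = length(ft$figure$speed), n_g = length(ft$ground$speed),
    diameter = srf$diameter, eccentricity = srf$eccentricity
  )
}

#' Summarise every sRF in a set
#'
#' @param srf_set an `srf_set` (see [build_srf_set()]).
#' @param dataset the `scene_dataset` it was sampled from.
#' @param floor_speed log-flooring threshold in deg/s.
#' @param features optional precomputed [srf_features()] list.
#' @return data.frame with one row per sRF: the [region_summary()] columns
#'   plus the figure-ground differences `delta_s`, `delta_v`, `delta_d`.
#' @export
summarize_srf_set <- function(srf_set, dataset, floor_speed = 0.01,
                              features = NULL) {
  stopifnot(inherits(srf_set, "srf_set"), inherits(dataset, "scene_dataset"))
  if (is.null(features)) {
    features <- srf_features(srf_set, dataset, floor_speed)
  }
  rows <- lapply(seq_along(srf_set$samples), function(i) {
    r <- summary_from_features(features[[i]], srf_set$samples[[i]])
    r$srf_id <- i
    r
  })
  out <- do.call(rbind, rows)
  out$delta_s <- out$s_f - out$s_g
  out$delta_v <- out$v_f - out$v_g
  out$delta_d <- out$d_f - out$d_g
  out
}

# ---- hypothesis tests -------------------------------------------------------

#' One-sample t-test against zero with Cohen's D
#'
#' @param values numeric vector (n >= 2, nonzero variance; NAs dropped).
#' @return list with `statistic`, `df`, `p_value`, `effect_size`
#'   (Cohen's D = mean/sd), `ci` (95% CI of the mean), `n`.
#' @export
one_sample_t <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0) stop("zero variance")
  tt <- stats::t.test(values, mu = 0)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       effect_size = mean(values) / stats::sd(values),
       ci = as.numeric(tt$conf.int), n = length(values))
}

#' One-way fixed-effects ANOVA with eta squared
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor); >= 2 groups with
#'   n >= 2 each.
#' @return list with `statistic` (F), `df` (between, within), `p_value`,
#'   `effect_size` (eta^2 = SS_between / SS_total), and the fitted `aov`.
#' @export
anova_eta <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    stop("need >= 2 groups with n >= 2 each")
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  ss <- tab[["Sum Sq"]]
  list(statistic = tab[["F value"]][1L],
       df = tab[["Df"]],
       p_value = tab[["Pr(>F)"]][1L],
       effect_size = ss[1L] / sum(ss),
       fit = fit)
}

#' Tukey HSD pairwise comparisons with Cohen's D
#'
#' All pairwise group comparisons with studentized-range p values and
#' confidence intervals; Cohen's D per pair uses the pooled sd of the two
#' groups.
#'
#' @inheritParams anova_eta
#' @param level confidence level (default 0.95).
#' @return data.frame with `pair`, `mean_diff`, `ci_lo`, `ci_hi`,
#'   `p_value`, `cohens_d`.
#' @export
tukey_pairs <- function(values, groups, level = 0.95) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  fit <- stats::aov(values ~ groups)
  hsd <- stats::TukeyHSD(fit, conf.level = level)$groups
  pairs <- rownames(hsd)
  d <- vapply(pairs, function(p) {
    gs <- strsplit(p, "-", fixed = TRUE)[[1L]]
    x1 <- values[groups == gs[1L]]; x2 <- values[groups == gs[2L]]
    sp <- sqrt(((length(x1) - 1) * stats::var(x1) +
                  (length(x2) - 1) * stats::var(x2)) /
                 (length(x1) + length(x2) - 2))
    (mean(x1) - mean(x2)) / sp
  }, numeric(1L))
  data.frame(pair = pairs, mean_diff = hsd[, "diff"],
             ci_lo = hsd[, "lwr"], ci_hi = hsd[, "upr"],
             p_value = hsd[, "p adj"], cohens_d = unname(d),
             row.names = NULL)
}

#' Wilcoxon rank-sum test with effect size r
#'
#' Two-sided rank-sum test via the tie-corrected normal approximation of
#' the Mann-Whitney U statistic; the effect size is r = |z| / sqrt(N).
#'
#' @param x,y numeric samples (NAs dropped).
#' @return list with `statistic` (U), `z`, `p_value`, `effect_size` (r),
#'   `n`.
#' @export
ranksum_r <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- as.numeric(length(x)); n2 <- as.numeric(length(y))
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty")
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- as.numeric(table(c(x, y)))
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) stop("all values tied; rank-sum test undefined")
  z <- (U - n1 * n2 / 2) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = U, z = z, p_value = min(p, 1),
       effect_size = abs(z) / sqrt(N), n = N)
}

#' Exact binomial confidence interval for a proportion
#'
#' Clopper-Pearson (beta-quantile) interval by default; Wilson and Wald
#' intervals are available for robustness checks.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @param method one of "clopper-pearson", "wilson", "wald".
#' @return length-2 numeric `(lo, hi)` on the proportion scale.
#' @export
binomial_ci <- function(successes, n, level = 0.95,
                        method = c("clopper-pearson", "wilson", "wald")) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive")
  if (successes < 0 || successes > n) stop("successes must be in 0..n")
  a <- 1 - level
  p <- successes / n
  switch(method,
    "clopper-pearson" = {
      lo <- if (successes == 0) 0 else
        stats::qbeta(a / 2, successes, n - successes + 1)
      hi <- if (successes == n) 1 else
        stats::qbeta(1 - a / 2, successes + 1, n - successes)
      c(lo, hi)
    },
    "wilson" = {
      z <- stats::qnorm(1 - a / 2)
      den <- 1 + z^2 / n
      ctr <- (p + z^2 / (2 * n)) / den
      hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
      c(ctr - hw, ctr + hw)
    },
    "wald" = {
      z <- stats::qnorm(1 - a / 2)
      hw <- z * sqrt(p * (1 - p) / n)
      c(max(0, p - hw), min(1, p + hw))
    }
  )
}

# ---- global distributions ---------------------------------------------------

#' Global per-class feature distributions over a dataset
#'
#' Pools world-frame (pre-gaze) speed, direction and distance over all
#' non-excluded pixels (outside the annotation buffer, non-sky; motion
#' restricted to above-threshold pixels), overall and split into figure and
#' ground classes.
#'
#' @param dataset a `scene_dataset`.
#' @param n_bins histogram bin count (default 50).
#' @param return_values also return the pooled raw values per class?
#' @return list with per-feature (`speed`, `direction`, `distance`)
#'   elements: `medians` (named all/figure/ground), `counts` (pixel
#'   counts), and a binned frequency `table` (data.frame of bin edges and
#'   per-class frequencies).  Speed bins are on log10 speed.
#' @export
global_distributions <- function(dataset, n_bins = 50L,
                                 return_values = FALSE) {
  stopifnot(inherits(dataset, "scene_dataset"))
  pull <- function(b) {
    keep <- !b$buffer_mask & b$label != LABEL_SKY
    vm <- b$valid_motion & keep
    cls <- ifelse(b$label >= 1L & b$label <= 250L, "figure", "ground")
    list(speed = data.frame(v = b$speed[vm], cls = cls[vm]),
         direction = data.frame(v = b$direction[vm], cls = cls[vm]),
         distance = {
           dm <- keep & !is.na(b$distance)
           data.frame(v = b$distance[dm], cls = cls[dm])
         })
  }
  pooled <- lapply(dataset$bundles, pull)
  out <- list()
  for (feat in c("speed", "direction", "distance")) {
    df <- do.call(rbind, lapply(pooled, `[[`, feat))
    vals <- list(all = df$v,
                 figure = df$v[df$cls == "figure"],
                 ground = df$v[df$cls == "ground"])
    x <- if (feat == "speed") log10(df$v) else df$v
    breaks <- if (feat == "direction") seq(0, 360, length.out = n_bins + 1L)
      else seq(min(x), max(x), length.out = n_bins + 1L)
    freq <- function(sel) {
      h <- graphics::hist(x[sel], breaks = breaks, plot = FALSE)
      h$counts / max(sum(h$counts), 1L)
    }
    tab <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                      all = freq(rep(TRUE, nrow(df))),
                      figure = freq(df$cls == "figure"),
                      ground = freq(df$cls == "ground"))
    out[[feat]] <- list(
      medians = vapply(vals, stats::median, numeric(1L)),
      counts = vapply(vals, length, numeric(1L)),
      table = tab)
    if (return_values) out[[feat]]$values <- vals
  }
  out
}

# ---- normalisation for ratio curves -----------------------------------------

#' Normalise speeds within an sRF to the unit interval
#'
#' Drops values outside the 1st..99th percentile (robustness to outliers)
#' and min-max rescales the survivors to `[0, 1]`.  Degenerate inputs
#' (all survivors equal) map to 0.5 with a warning.
#'
#' @param speeds numeric speeds (>= 3 values).
#' @return list with `values` (rescaled survivors) and `keep` (logical
#'   index of survivors into the input).
#' @export
normalized_speed_values <- function(speeds) {
  speeds_ok <- speeds[!is.na(speeds)]
  if (length(speeds_ok) < 3L) stop("need at least 3 valid speeds")
  q <- stats::quantile(speeds_ok, c(0.01, 0.99), names = FALSE)
  keep <- !is.na(speeds) & speeds >= q[1] & speeds <= q[2]
  v <- speeds[keep]
  if (max(v) == min(v)) {
    warning("degenerate speed range; all values mapped to 0.5")
    return(list(values = rep(0.5, length(v)), keep = keep))
  }
  list(values = (v - min(v)) / (max(v) - min(v)), keep = keep)
}

#' Align directions so the dominant direction is 0 deg
#'
#' Finds the modal bin of a 50-bin circular histogram (ties break toward
#' the lower bin edge) and rotates all directions by minus the modal bin
#' centre, wrapping to `[-180, 180)`.
#'
#' @param directions directions in degrees (NAs dropped).
#' @param n_bins circular histogram bin count (default 50).
#' @return list with `values` (aligned directions) and `mode` (the modal
#'   direction in degrees that was rotated to zero).
#' @export
aligned_directions <- function(directions, n_bins = 50L) {
  directions <- directions[!is.na(directions)] %% 360
  if (length(directions) == 0L) stop("need at least 1 direction")
  width <- 360 / n_bins
  bin <- pmin(floor(directions / width), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  mode_bin <- which.max(counts)  # which.max takes the first (lower edge) tie
  mode_dir <- (mode_bin - 1L + 0.5) * width
  list(values = ((directions - mode_dir + 180) %% 360) - 180,
       mode = mode_dir)
}

# ---- probability-ratio curves -----------------------------------------------

# Per-sRF relative-frequency histogram rows for a list of value vectors.
freq_rows <- function(value_list, breaks) {
  nb <- length(breaks) - 1L
  t(vapply(value_list, function(v) {
    v <- v[!is.na(v) & v >= breaks[1L] & v <= breaks[nb + 1L]]
    if (length(v) == 0L) return(rep(NA_real_, nb))
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  }, numeric(nb)))
}

ratio_from_freqs <- function(fig_rows, gnd_rows, binwidth) {
  fig_f <- colMeans(fig_rows, na.rm = TRUE)
  gnd_f <- colMeans(gnd_rows, na.rm = TRUE)
  fig_d <- fig_f / sum(fig_f) / binwidth
  gnd_d <- gnd_f / sum(gnd_f) / binwidth
  ratio <- ifelse(gnd_d > 0, fig_d / gnd_d, NA_real_)
  list(figure_density = fig_d, ground_density = gnd_d, ratio = ratio)
}

#' Figure/ground probability-ratio curve over an sRF set
#'
#' For each sRF, histograms a per-pixel feature separately for the figure
#' and ground regions in 50 linearly-spaced bins; relative frequencies are
#' averaged across sRFs, converted to probability densities, and the
#' per-bin figure/ground density ratio is computed with a percentile
#' bootstrap CI (resampling sRFs, the resampling unit).
#'
#' Features: `"rel_speed"` - retinal speeds normalised within each sRF to
#' `[0, 1]` ([normalized_speed_values()] applied to figure and ground
#' pixels jointly); `"rel_direction"` - retinal directions aligned so each
#' sRF's dominant direction is 0 deg; `"disparity"` - binocular disparity
#' in degrees (already fixation-relative, no normalisation), binned over
#' the pooled 1st..99th percentile range.
#'
#' @param srf_set an `srf_set`.
#' @param dataset the `scene_dataset` it was sampled from.
#' @param feature one of `"rel_speed"`, `"rel_direction"`, `"disparity"`.
#' @param n_bins bin count (default 50).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param floor_speed log-flooring threshold passed to feature extraction.
#' @param features optional precomputed [srf_features()] list.
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`,
#'   `figure_density`, `ground_density`, `ratio`, `ci_lo`, `ci_hi`.
#' @export
ratio_curve <- function(srf_set, dataset,
                        feature = c("rel_speed", "rel_direction", "disparity"),
                        n_bins = 50L, n_boot = 1000L, seed = 1L,
                        floor_speed = 0.01, features = NULL) {
  feature <- match.arg(feature)
  stopifnot(inherits(srf_set, "srf_set"))
  if (is.null(features)) {
    features <- srf_features(srf_set, dataset, floor_speed)
  }
  per_srf <- lapply(features, function(ft) {
    nf <- length(ft$figure$speed); ng <- length(ft$ground$speed)
    if (feature == "rel_speed") {
      if (nf < 1L || ng < 1L || nf + ng < 3L) return(NULL)
      nz <- normalized_speed_values(c(ft$figure$speed, ft$ground$speed))
      src <- rep(c("f", "g"), c(nf, ng))[nz$keep]
      list(fig = nz$values[src == "f"], gnd = nz$values[src == "g"])
    } else if (feature == "rel_direction") {
      df <- ft$figure$direction[!is.na(ft$figure$direction)]
      dg <- ft$ground$direction[!is.na(ft$ground$direction)]
      if (length(df) < 1L || length(dg) < 1L) return(NULL)
      al <- aligned_directions(c(df, dg))
      src <- rep(c("f", "g"), c(length(df), length(dg)))
      list(fig = al$values[src == "f"], gnd = al$values[src == "g"])
    } else {
      if (length(ft$figure$disparity) < 1L ||
          length(ft$ground$disparity) < 1L) return(NULL)
      list(fig = ft$figure$disparity, gnd = ft$ground$disparity)
    }
  })
  per_srf <- Filter(Negate(is.null), per_srf)
  if (length(per_srf) < 10L) stop("need >= 10 sRFs with both regions defined")
  breaks <- switch(feature,
    rel_speed = seq(0, 1, length.out = n_bins + 1L),
    rel_direction = seq(-180, 180, length.out = n_bins + 1L),
    disparity = {
      pooled <- unlist(lapply(per_srf, function(p) c(p$fig, p$gnd)))
      rng <- stats::quantile(pooled, c(0.01, 0.99), names = FALSE)
      seq(rng[1], rng[2], length.out = n_bins + 1L)
    })
  binwidth <- diff(breaks)[1L]
  fig_rows <- freq_rows(lapply(per_srf, `[[`, "fig"), breaks)
  gnd_rows <- freq_rows(lapply(per_srf, `[[`, "gnd"), breaks)
  pt <- ratio_from_freqs(fig_rows, gnd_rows, binwidth)
  set.seed(seed)
  n <- nrow(fig_rows)
  boot <- matrix(NA_real_, n_boot, n_bins)
  for (b in seq_len(n_boot)) {
    ii <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- ratio_from_freqs(fig_rows[ii, , drop = FALSE],
                                  gnd_rows[ii, , drop = FALSE],
                                  binwidth)$ratio
  }
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  data.frame(bin_lo = breaks[-(n_bins + 1L)], bin_hi = breaks[-1L],
             bin_mid = (breaks[-(n_bins + 1L)] + breaks[-1L]) / 2,
             figure_density = pt$figure_density,
             ground_density = pt$ground_density,
             ratio = pt$ratio, ci_lo = ci[1L, ], ci_hi = ci[2L, ])
}

#' Figure-ground proportions with binomial confidence intervals
#'
#' Fraction of sRFs in which the figure region is faster, more coherent
#' (lower circular variance) and nearer (more positive disparity) than the
#' ground region, with 95% Clopper-Pearson intervals.
#'
#' @param summaries output of [summarize_srf_set()].
#' @return data.frame with one row per feature: `feature`, `successes`,
#'   `n`, `proportion`, `ci_lo`, `ci_hi`.
#' @export
fg_proportions <- function(summaries) {
  one <- function(feature, x, better_positive) {
    x <- x[!is.na(x)]
    succ <- if (better_positive) sum(x > 0) else sum(x < 0)
    ci <- binomial_ci(succ, length(x))
    data.frame(feature = feature, successes = succ, n = length(x),
               proportion = succ / length(x), ci_lo = ci[1], ci_hi = ci[2])
  }
  rbind(one("figure_faster", summaries$delta_s, TRUE),
        one("figure_more_coherent", summaries$delta_v, FALSE),
        one("figure_nearer", summaries$delta_d, TRUE))
}
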