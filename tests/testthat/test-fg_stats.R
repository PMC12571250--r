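test_that("circular variance matches analytic cases and vector summation", {
  expect_equal(circular_variance(rep(37, 12)), 0, tolerance = 1e-12)
  expect_equal(circular_variance(c(0, 90, 180, 270)), 1, tolerance = 1e-12)
  expect_equal(circular_variance(c(0, 90)), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
  # random sample vs direct vector-sum oracle
  set.seed(30)
  th <- runif(200, 0, 360)
  S <- sum(sin(th * pi / 180)); C <- sum(cos(th * pi / 180))
  expect_equal(circular_variance(th), 1 - sqrt(S^2 + C^2) / 200,
               tolerance = 1e-12)
  expect_error(circular_variance(numeric(0)), "no directions")
})

test_that("region summaries match a brute-force pixelwise recomputation", {
  # uniform region: speed 10 deg/s, direction 0 -> s = 1, v = 0
  b <- make_toy_bundle(h = 41, w = 41, speed = 10, direction = 0,
                       fig_rows = 10:20, fig_cols = 10:20)
  srf <- list(scene_id = 1L, center = c(15, 15), diameter = 5,
              eccentricity = 5,
              gaze = gaze_state(b, c(35, 35), pursuit_enabled = FALSE),
              figure_idx = which(b$label == 1L),
              ground_idx = which(b$label == LABEL_GROUND))
  rs <- region_summary(srf, b)
  expect_equal(rs$s_f, 1)
  expect_equal(rs$v_f, 0)

  # two-pixel region with speeds {1, 100}: mean log10 speed = 1
  b2 <- b
  b2$speed[10, 10] <- 1; b2$speed[10, 11] <- 100
  srf2 <- srf
  srf2$figure_idx <- c(which(b$label == 1L)[1:2])
  b2$speed[srf2$figure_idx] <- c(1, 100)
  rs2 <- region_summary(srf2, b2)
  expect_equal(rs2$s_f, 1)

  # random region vs oracle
  set.seed(31)
  bb <- generate_scene(test_params(), seed = 55)
  cand <- fixation_candidates(bb$saliency)
  fx <- which(cand & bb$label != LABEL_SKY)[100]
  fxrc <- as.vector(arrayInd(fx, dim(bb$label)))
  gz <- gaze_state(bb, fxrc, pursuit_enabled = TRUE)
  fig_idx <- which(bb$label == 1L & !bb$buffer_mask)[1:200]
  gnd_idx <- which(bb$label == LABEL_GROUND & !bb$buffer_mask)[1:300]
  srf3 <- list(scene_id = 1L, center = c(96, 96), diameter = 5,
               eccentricity = 5, gaze = gz,
               figure_idx = fig_idx, ground_idx = gnd_idx)
  rs3 <- region_summary(srf3, bb)
  # oracle: per-pixel recomputation of every summary
  oracle_region <- function(idx) {
    vsp <- c(); vdir <- c(); vd <- c()
    meta <- bb$meta
    Pf <- point_coordinates(fxrc[1], fxrc[2], bb$distance[fx], meta)[1, ]
    for (i in idx) {
      rc <- arrayInd(i, dim(bb$label))
      if (bb$valid_motion[i]) {
        th <- bb$direction[i] * pi / 180
        v <- bb$speed[i] * c(cos(th), sin(th))
        if (gz$pursuit_active) v <- v - gz$fixation_motion
        sp <- max(sqrt(sum(v^2)), 0.01)
        vsp <- c(vsp, log10(sp))
        if (sqrt(sum(v^2)) > 0) {
          vdir <- c(vdir, (atan2(v[2], v[1]) * 180 / pi) %% 360)
        }
      }
      if (!is.na(bb$distance[i])) {
        P <- point_coordinates(rc[1], rc[2], bb$distance[i], meta)[1, ]
        vd <- c(vd, binocular_disparity(P, Pf))
      }
    }
    list(s = mean(vsp), v = circular_variance(vdir), d = mean(vd))
  }
  of <- oracle_region(fig_idx); og <- oracle_region(gnd_idx)
  expect_equal(rs3$s_f, of$s, tolerance = 1e-12)
  expect_equal(rs3$v_f, of$v, tolerance = 1e-12)
  expect_equal(rs3$d_f, of$d, tolerance = 1e-12)
  expect_equal(rs3$s_g, og$s, tolerance = 1e-12)
  expect_equal(rs3$d_g, og$d, tolerance = 1e-12)
})

test_that("one-sample t matches the textbook computation", {
  r <- one_sample_t(c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 4.2426406871, tolerance = 1e-9)
  expect_equal(r$p_value, 0.0132355996, tolerance = 1e-8)
  expect_equal(r$effect_size, 1.8973665961, tolerance = 1e-9)
  expect_equal(r$df, 4)

  sym <- c(-2, -1, 0, 1, 2)
  r0 <- one_sample_t(sym)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect_size, 0)

  # scale invariance of t, p and D
  x <- c(0.3, 1.2, -0.5, 2.2, 0.9)
  ra <- one_sample_t(x); rb <- one_sample_t(7 * x)
  expect_equal(ra$statistic, rb$statistic)
  expect_equal(ra$p_value, rb$p_value)
  expect_equal(ra$effect_size, rb$effect_size)

  expect_error(one_sample_t(rep(3, 5)), "variance")
})

test_that("ANOVA and eta squared match brute-force sums of squares", {
  # identical group distributions: F = 0
  v <- rep(c(1, 2, 3), 4)
  g <- rep(c("a", "b"), each = 6)
  r <- anova_eta(v, g)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$effect_size, 0, tolerance = 1e-12)

  # all variance between groups
  r2 <- anova_eta(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_equal(r2$effect_size, 1)

  # 4 x 5 toy table vs explicit sums of squares
  set.seed(32)
  vals <- rnorm(20, rep(c(0, 1, 3, 0.5), each = 5))
  grp <- rep(letters[1:4], each = 5)
  r3 <- anova_eta(vals, grp)
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(x) sum((x - mean(x))^2)))
  expect_equal(r3$effect_size, ssb / (ssb + ssw), tolerance = 1e-12)
  expect_equal(r3$statistic, (ssb / 3) / (ssw / 16), tolerance = 1e-12)
  expect_equal(r3$p_value, pf((ssb / 3) / (ssw / 16), 3, 16,
                              lower.tail = FALSE), tolerance = 1e-12)

  expect_error(anova_eta(1:5, rep("a", 5)), "2 groups")
})

test_that("Tukey pairs reduce to the two-sample t-test for two groups", {
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  tp <- tukey_pairs(v, g)
  expect_true(all(abs(tp$mean_diff) < 1e-12))
  expect_true(all(tp$p_value > 0.99))

  set.seed(33)
  x <- rnorm(12); y <- rnorm(12, 0.8)
  tp2 <- tukey_pairs(c(x, y), rep(c("a", "b"), each = 12))
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(tp2$p_value, tt$p.value, tolerance = 1e-9)
  expect_equal(tp2$mean_diff, mean(y) - mean(x), tolerance = 1e-12)

  # CI excludes 0 iff p < 0.05, over random 4-group datasets
  for (k in 1:5) {
    vals <- rnorm(40, rep(runif(4, 0, k / 3), each = 10))
    grp <- rep(letters[1:4], each = 10)
    tpk <- tukey_pairs(vals, grp)
    excl <- tpk$ci_lo > 0 | tpk$ci_hi < 0
    expect_equal(excl, tpk$p_value < 0.05)
  }
})

test_that("rank-sum effect sizes follow |z|/sqrt(N)", {
  x <- c(1, 2, 3, 4, 5, 6)
  r <- ranksum_r(x, x)
  expect_gt(r$p_value, 0.95)
  expect_lt(r$effect_size, 0.05)

  # fully separated samples: U attains its extreme, minimal attainable p
  r2 <- ranksum_r(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r2$statistic, 0)  # exhaustive enumeration: all y above x
  set.seed(34)
  ps <- replicate(20, {
    a <- rnorm(8); bshift <- rnorm(8, runif(1, -2, 2))
    rr <- ranksum_r(a, bshift)
    expect_true(rr$effect_size >= 0 && rr$effect_size <= 1)
    # p agrees with the base-R normal approximation without correction
    w <- suppressWarnings(wilcox.test(a, bshift, exact = FALSE,
                                      correct = FALSE))
    expect_equal(rr$p_value, w$p.value, tolerance = 1e-9)
    rr$p_value
  })
  expect_true(all(ps >= 0 & ps <= 1))
  expect_error(ranksum_r(c(1, 1), c(1, 1)), "tied")
})

test_that("Rayleigh test behaves at the concentration extremes", {
  expect_lt(rayleigh_test(rep(90, 50))$p_value, 1e-10)
  grid <- seq(0, 356.4, by = 3.6)  # exact uniform grid on the circle
  rg <- rayleigh_test(grid)
  expect_lt(rg$rbar, 1e-10)
  expect_gt(rg$p_value, 0.9)
  # power: von Mises kappa = 2, n = 100 rejects essentially always
  set.seed(35)
  rej <- replicate(100, {
    rayleigh_test(rvonmises(100, 45, 2))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.99)
  expect_error(rayleigh_test(c(1, 2)), "at least 5")
})

test_that("Kuiper test is rotation invariant and matches a CDF scan", {
  set.seed(36)
  a <- runif(40, 0, 360)
  k0 <- kuiper_two(a, a)
  expect_gt(k0$p_value, 0.95)

  b <- rvonmises(35, 120, 1.5)
  k1 <- kuiper_two(a, b)
  for (phi in c(37.3, 180, 275)) {
    k2 <- kuiper_two((a + phi) %% 360, (b + phi) %% 360)
    expect_equal(k2$statistic, k1$statistic, tolerance = 1e-12)
    expect_equal(k2$p_value, k1$p_value, tolerance = 1e-12)
  }

  # brute-force CDF-difference scan over a dense angle grid
  scan_V <- function(x, y) {
    th <- seq(0, 360, by = 0.01)
    Fx <- ecdf(x)(th); Fy <- ecdf(y)(th)
    max(Fx - Fy) + max(Fy - Fx)
  }
  x <- c(10, 40, 95, 200, 310, 355)
  y <- c(5, 50, 120, 180, 250, 260, 300)
  expect_equal(kuiper_two(x, y)$statistic, scan_V(x, y), tolerance = 1e-9)
})

test_that("binomial confidence intervals hit the printed benchmark", {
  for (m in c("clopper-pearson", "wilson", "wald")) {
    ci <- binomial_ci(544, 800, method = m)
    expect_equal(round(100 * ci), c(65, 71))
  }
  expect_equal(binomial_ci(0, 100)[1], 0)
  ci50 <- binomial_ci(50, 100)
  expect_equal(ci50[1] - 0.5, 0.5 - ci50[2], tolerance = 1e-9)
  expect_error(binomial_ci(5, 0), "positive")
})

test_that("global distributions recover the configured structure", {
  p <- test_params()
  ds <- generate_dataset(6, p, seed = 61)
  g <- global_distributions(ds)
  # histogram masses are relative frequencies summing to one
  for (feat in names(g)) {
    expect_equal(sum(g[[feat]]$table$all), 1, tolerance = 1e-9)
    expect_equal(sum(g[[feat]]$table$figure), 1, tolerance = 1e-9)
  }
  # the above-threshold ground speed median is the configured one by
  # construction; the figure median follows from the textbook
  # truncated-exponential quantile with the peak solved independently
  expect_lt(abs(g$speed$medians["ground"] / p$ground_speed_median - 1), 0.1)
  t0 <- log10(0.5)
  s0 <- (log10(p$ground_speed_median) - t0) / log(2)
  mexp <- function(T) 1 - T * exp(-T) / (1 - exp(-T))
  cf <- uniroot(function(c) {
    c - s0 * mexp((c - t0) / s0) - (t0 + s0 + p$fg_logspeed_offset)
  }, c(t0 + 1e-9, t0 + 2 * s0 + p$fg_logspeed_offset + 2))$root
  Tq <- (cf - t0) / s0
  fig_med <- 10^(cf - s0 * -log(1 - 0.5 * (1 - exp(-Tq))))
  expect_lt(abs(g$speed$medians["figure"] / fig_med - 1), 0.15)
  # figures configured nearer than ground
  expect_lt(g$distance$medians["figure"], g$distance$medians["ground"])

  # a scene with no figures contributes an empty figure class
  lab <- matrix(LABEL_GROUND, 96, 96)
  meta <- scene_metadata(21 / 96, 120, 96, 96)
  b1 <- scene_bundle(matrix(2, 96, 96), matrix(0, 96, 96),
                     matrix(10, 96, 96), lab, meta, check = FALSE)
  ds1 <- structure(list(bundles = list(b1), manifest = list()),
                   class = "scene_dataset")
  g1 <- global_distributions(ds1)
  expect_equal(unname(g1$speed$counts["figure"]), 0)
})

test_that("speed normalisation drops outliers then rescales", {
  v <- seq(1, 100)
  nz <- normalized_speed_values(v)
  expect_equal(min(nz$values), 0)
  expect_equal(max(nz$values), 1)

  # one extreme outlier is excluded by the quantile rule before rescaling
  v2 <- c(seq(1, 99), 1e6)
  nz2 <- normalized_speed_values(v2)
  expect_false(nz2$keep[100])
  q <- quantile(v2, c(0.01, 0.99), names = FALSE)
  expect_equal(nz2$keep, v2 >= q[1] & v2 <= q[2])

  expect_warning(nzc <- normalized_speed_values(rep(5, 10)), "degenerate")
  expect_true(all(nzc$values == 0.5))
})

test_that("direction alignment puts the modal lobe at zero", {
  al <- aligned_directions(rep(90, 20))
  expect_true(all(abs(al$values) < 3.6 + 1e-9))
  expect_equal(al$mode, 90, tolerance = 3.6)

  # bimodal 30/210 with 60/40 mass: the 60% lobe is rotated to 0
  set.seed(37)
  d <- c(rep(30, 60), rep(210, 40)) + rnorm(100, 0, 1)
  al2 <- aligned_directions(d)
  expect_lt(abs(al2$mode - 30), 7.2)
  expect_gt(mean(abs(al2$values) < 15), 0.55)

  # equivariance: pre-rotating by a whole number of bins changes nothing
  d0 <- (runif(200, 0, 360))
  a0 <- aligned_directions(d0)
  a1 <- aligned_directions((d0 + 5 * 7.2) %% 360)
  expect_equal(sort(a1$values), sort(a0$values), tolerance = 1e-9)
})

test_that("ratio curves are flat under the null and tilted under shifts", {
  # null: figure and ground drawn from one speed distribution, supplied
  # through the precomputed-features interface
  set.seed(71)
  null_features <- replicate(80, list(
    figure = list(speed = rlnorm(300, 1, 0.6), direction = numeric(0),
                  disparity = numeric(0)),
    ground = list(speed = rlnorm(400, 1, 0.6), direction = numeric(0),
                  disparity = numeric(0))), simplify = FALSE)
  dummy_set <- structure(list(samples = vector("list", 80)),
                         class = "srf_set")
  rc0 <- ratio_curve(dummy_set, NULL, "rel_speed", n_boot = 400, seed = 73,
                     features = null_features)
  covered <- rc0$ci_lo <= 1 & rc0$ci_hi >= 1
  expect_gte(mean(covered, na.rm = TRUE), 0.9)
  # point ratio inside its own bootstrap interval
  ok <- !is.na(rc0$ratio)
  expect_true(all(rc0$ratio[ok] >= rc0$ci_lo[ok] - 1e-9))
  expect_true(all(rc0$ratio[ok] <= rc0$ci_hi[ok] + 1e-9))

  # constructed shift: faster figures tilt the ratio upward
  p1 <- test_params()
  ds1 <- generate_dataset(8, p1, seed = 74)
  ss1 <- build_srf_set(ds1, n_per_size = 40, sizes = c(2.5, 5), seed = 75,
                       pursuit_enabled = FALSE)
  ft1 <- srf_features(ss1, ds1)
  rc1 <- ratio_curve(ss1, ds1, "rel_speed", n_boot = 200, seed = 76,
                     features = ft1)
  rho <- cor(seq_len(nrow(rc1)), rc1$ratio, method = "spearman",
             use = "complete.obs")
  expect_gt(rho, 0)

  # figures nearer: elevated ratio at crossed (positive) disparities
  rcd <- ratio_curve(ss1, ds1, "disparity", n_boot = 200, seed = 77,
                     features = ft1)
  pos <- rcd$bin_mid > 0 & !is.na(rcd$ratio)
  neg <- rcd$bin_mid < 0 & !is.na(rcd$ratio)
  expect_gt(mean(rcd$ratio[pos] > 1), 0.5)
  expect_gt(mean(rcd$ratio[neg] < 1), 0.5)
})

test_that("proportion bookkeeping equals direct counting", {
  p <- test_params()
  ds <- generate_dataset(5, p, seed = 81)
  ss <- build_srf_set(ds, n_per_size = 30, sizes = c(2.5, 5), seed = 82)
  sm <- summarize_srf_set(ss, ds)
  pr <- fg_proportions(sm)
  expect_equal(pr$successes[pr$feature == "figure_faster"],
               sum(sm$delta_s > 0, na.rm = TRUE))
  expect_equal(pr$successes[pr$feature == "figure_more_coherent"],
               sum(sm$delta_v < 0, na.rm = TRUE))
  expect_equal(pr$successes[pr$feature == "figure_nearer"],
               sum(sm$delta_d > 0, na.rm = TRUE))
  expect_true(all(pr$ci_lo <= pr$proportion & pr$proportion <= pr$ci_hi))
})
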