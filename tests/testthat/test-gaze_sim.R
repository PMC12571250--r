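test_that("stand-in saliency is a windowed variance", {
  u <- matrix(0.4, 20, 20)
  s <- stand_in_saliency(u)
  expect_lt(max(s), 1e-12)  # constant image: zero variance everywhere
  # invariant to adding a constant
  set.seed(8)
  img <- matrix(runif(400), 20, 20)
  expect_equal(stand_in_saliency(img), stand_in_saliency(img + 5),
               tolerance = 1e-9)
  # bright blob on a dark field: salience maximal around the blob boundary;
  # checked against a direct windowed-variance oracle
  img2 <- matrix(0, 30, 30); img2[13:18, 13:18] <- 1
  s2 <- stand_in_saliency(img2, window = 2)
  oracle <- matrix(0, 30, 30)
  for (r in 1:30) for (c in 1:30) {
    rr <- max(1, r - 2):min(30, r + 2)
    cc <- max(1, c - 2):min(30, c + 2)
    v <- img2[rr, cc]
    oracle[r, c] <- mean(v^2) - mean(v)^2
  }
  expect_equal(s2, oracle, tolerance = 1e-12)
  expect_true(which.max(s2) %in% which(oracle == max(oracle)))
  # the maximum sits on the boundary region, not deep inside the blob
  expect_lt(s2[15, 15], max(s2))
})

test_that("fixation candidates are the upper half of a median split", {
  set.seed(9)
  s <- matrix(runif(81), 9, 9)  # distinct values
  cand <- fixation_candidates(s)
  expect_equal(sum(cand), ceiling(81 / 2))
  # equals brute-force sort-and-cut
  cut <- sort(as.vector(s), decreasing = TRUE)[ceiling(81 / 2)]
  expect_equal(cand, s >= cut)
  # all-tied map: everything is a candidate
  expect_true(all(fixation_candidates(matrix(1, 5, 5))))
})

test_that("pursuit subtracts the fixation vector; slow fixations do not move", {
  b <- make_toy_bundle(speed = 3, direction = 0)
  # fixation on a slow pixel (< 0.5 deg/s): identity
  b_slow <- make_toy_bundle(speed = 0.3, direction = 0)
  gz <- gaze_state(b_slow, c(5, 5))
  expect_false(gz$pursuit_active)
  rm0 <- retinal_motion(b_slow, gz)
  expect_identical(rm0$speed, b_slow$speed)

  # fixation tracking a uniformly-moving scene: zero retinal speed
  gz2 <- gaze_state(b, c(15, 15))
  expect_true(gz2$pursuit_active)
  rm2 <- retinal_motion(b, gz2)
  expect_true(all(rm2$speed == 0))

  # v = (3, 0), v_fix = (1, 0) -> retinal (2, 0), direction 0
  b3 <- make_toy_bundle(speed = 3, direction = 0)
  b3$speed[7, 7] <- 1
  gz3 <- gaze_state(b3, c(7, 7))
  rm3 <- retinal_motion(b3, gz3)
  expect_equal(rm3$speed[20, 20], 2)
  expect_equal(rm3$direction[20, 20], 0)

  # pursuit disabled is the identity regardless of fixation motion
  gz4 <- gaze_state(b, c(15, 15), pursuit_enabled = FALSE)
  expect_identical(retinal_motion(b, gz4)$speed, b$speed)

  expect_error(gaze_state(make_toy_bundle(sky_rows = 1:3), c(1, 5)), "sky")
})

test_that("world coordinates follow spherical geometry", {
  meta <- scene_metadata(0.5, 120, 41, 41)
  # central pixel at distance r -> [0, 0, r]
  expect_equal(as.vector(point_coordinates(21, 21, 7, meta)), c(0, 0, 7))
  # +5 deg horizontal (10 pixels right), r = 10
  P <- point_coordinates(21, 31, 10, meta)
  expect_equal(unname(P[1, "x"]), 10 * sin(5 * pi / 180), tolerance = 1e-12)
  expect_equal(unname(P[1, "z"]), 10 * cos(5 * pi / 180), tolerance = 1e-12)
  expect_equal(unname(P[1, "y"]), 0)
  # symmetric pixels mirror in x with equal z
  Pl <- point_coordinates(21, 11, 10, meta)
  expect_equal(Pl[1, "x"], -P[1, "x"])
  expect_equal(Pl[1, "z"], P[1, "z"])
  expect_error(point_coordinates(21, 21, -1, meta), "positive")
})

test_that("binocular disparity matches the closed-form vergence difference", {
  s <- 0.062
  # fixated point has zero disparity
  expect_equal(binocular_disparity(c(0.3, 0.1, 5), c(0.3, 0.1, 5), s), 0)
  # on-axis fixation 10 m, on-axis point 5 m: closed-form vergence-angle
  # difference, crossed sign positive
  d <- binocular_disparity(c(0, 0, 5), c(0, 0, 10), s)
  expect_equal(d, 2 * (atan(s / 2 / 5) - atan(s / 2 / 10)) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(d, 0.355225867658, tolerance = 1e-9)
  expect_gt(d, 0)
  # point farther than fixation: uncrossed, negative
  expect_lt(binocular_disparity(c(0, 0, 20), c(0, 0, 10), s), 0)
  expect_error(binocular_disparity(c(0, 0, -1), c(0, 0, 10), s), "z > 0")
})

test_that("relative disparity is invariant to the fixated point", {
  set.seed(10)
  for (rep in 1:100) {
    P1 <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, 2, 40))
    P2 <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, 2, 40))
    rel <- NULL
    for (f in 1:10) {
      Pf <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, 2, 40))
      r <- binocular_disparity(P1, Pf) - binocular_disparity(P2, Pf)
      if (is.null(rel)) rel <- r
      expect_equal(r, rel, tolerance = 1e-9)
    }
  }
})

test_that("disparity decreases monotonically with distance along a ray", {
  set.seed(11)
  for (rep in 1:50) {
    Pf <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, 3, 30))
    u <- c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3), 1)
    dists <- sort(runif(8, 1, 50))
    d <- vapply(dists, function(r) {
      binocular_disparity(u / sqrt(sum(u^2)) * r, Pf)
    }, numeric(1))
    expect_true(all(diff(d) < 0))
  }
})

test_that("disparity maps respect the near/far sign convention", {
  # frontoparallel constant distance, on-axis fixation: centre pixel d = 0
  b <- make_toy_bundle(h = 41, w = 41, distance = 10,
                       fig_rows = 5:10, fig_cols = 5:10)
  gz <- gaze_state(b, c(21, 21))
  dm <- disparity_map(b, gz)
  expect_equal(dm[21, 21], 0, tolerance = 1e-12)

  # two-depth scene: nearer plane uniformly more positive at matched
  # eccentricities (mirror pixels left/right of fixation)
  dst <- matrix(10, 41, 41); dst[, 1:20] <- 4
  b2 <- make_toy_bundle(h = 41, w = 41, distance = dst,
                        fig_rows = 5:10, fig_cols = 5:10)
  gz2 <- gaze_state(b2, c(21, 21))
  dm2 <- disparity_map(b2, gz2)
  for (off in 1:15) {
    expect_gt(dm2[21, 21 - off], dm2[21, 21 + off])
  }

  # relative disparity between two pixels identical across random fixations
  set.seed(12)
  dstr <- matrix(runif(41 * 41, 3, 30), 41, 41)
  b3 <- make_toy_bundle(h = 41, w = 41, distance = dstr,
                        fig_rows = 5:10, fig_cols = 5:10)
  rel <- NULL
  for (k in 1:10) {
    fx <- c(sample(41, 1), sample(41, 1))
    dmk <- disparity_map(b3, gaze_state(b3, fx))
    r <- dmk[30, 30] - dmk[10, 35]
    if (is.null(rel)) rel <- r
    expect_equal(r, rel, tolerance = 1e-9)
  }
})
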