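# Circular statistics: circular variance, Rayleigh and two-sample Kuiper
# tests, and a von Mises sampler.  All angles are in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular variance of a set of directions
#'
#' One minus the mean resultant length of the direction unit vectors:
#' 0 for perfectly coherent directions, 1 for fully dispersed ones.
#' Used as the (inverse) motion-coherence measure.
#'
#' @param directions directions in degrees (NAs dropped).
#' @return circular variance in `[0, 1]`.
#' @export
circular_variance <- function(directions) {
  directions <- directions[!is.na(directions)]
  if (length(directions) == 0L) stop("circular_variance: no directions")
  th <- deg2rad(directions)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  # numerical guard: rbar can exceed 1 by eps for a single angle
  1 - min(1, rbar)
}

#' Circular mean direction (degrees in [0, 360))
#' @param directions directions in degrees (NAs dropped).
#' @export
circular_mean <- function(directions) {
  directions <- directions[!is.na(directions)]
  if (length(directions) == 0L) stop("circular_mean: no directions")
  th <- deg2rad(directions)
  rad2deg(atan2(mean(sin(th)), mean(cos(th)))) %% 360
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a direction distribution differs from uniform.  The test
#' statistic is z = n * Rbar^2 and the p value uses the standard
#' small-sample-corrected series approximation.
#'
#' @param directions directions in degrees (n >= 5 after NA removal).
#' @return list with `statistic` (z), `rbar`, `n`, `p_value`.
#' @export
rayleigh_test <- function(directions) {
  directions <- directions[!is.na(directions)]
  n <- length(directions)
  if (n < 5L) stop("rayleigh_test: need at least 5 directions")
  th <- deg2rad(directions)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(statistic = z, rbar = rbar, n = n, p_value = p)
}

#' Two-sample Kuiper test for circular distributions
#'
#' Rotation-invariant comparison of two circular samples.  The statistic is
#' V = D+ + D-, the sum of the maximal positive and negative deviations
#' between the two empirical CDFs evaluated over all sample angles; the p
#' value uses Stephens' asymptotic series with the usual effective-n
#' correction.
#'
#' @param a,b direction samples in degrees (each n >= 5 after NA removal).
#' @return list with `statistic` (V), `n_a`, `n_b`, `p_value`.
#' @export
kuiper_two <- function(a, b) {
  a <- sort(a[!is.na(a)] %% 360)
  b <- sort(b[!is.na(b)] %% 360)
  na <- length(a); nb <- length(b)
  if (na < 5L || nb < 5L) stop("kuiper_two: need at least 5 directions each")
  pts <- sort(unique(c(a, b)))
  Fa <- findInterval(pts, a) / na
  Fb <- findInterval(pts, b) / nb
  diffs <- Fa - Fb
  V <- max(diffs) - min(diffs)
  ne <- na * nb / (na + nb)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  if (lam < 0.4) {
    # the asymptotic series diverges for tiny lambda; p is 1 to 7 digits
    p <- 1
  } else {
    j <- 1:100
    p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
    p <- min(max(p, 0), 1)
  }
  list(statistic = V, n_a = na, n_b = nb, p_value = p)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler.  `kappa = 0` falls back to the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return directions in degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu_r <- deg2rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  bb <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + bb^2) / (2 * bb)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(1.3 * m)  # batch with headroom for rejections
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    fa <- f[acc]
    th <- acos(fa) * sign(u3[acc] - 0.5)
    out <- c(out, mu_r + th)
  }
  rad2deg(out[seq_len(n)]) %% 360
}

#' Sample from a two-lobe axial von Mises mixture
#'
#' Equal-weight mixture of von Mises components at `mu` and `mu + 180` deg,
#' emulating the horizontal (left/right) bias of natural object motion.
#'
#' @param n number of draws.
#' @param mu first lobe direction in degrees (default 0 = rightward).
#' @param kappa concentration of each lobe.
#' @return directions in degrees in `[0, 360)`.
#' @export
raxial <- function(n, mu = 0, kappa = 1) {
  flip <- stats::runif(n) < 0.5
  base <- rvonmises(n, mu, kappa)
  (base + 180 * flip) %% 360
}
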