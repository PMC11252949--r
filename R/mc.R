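# Monte Carlo random-walk validation oracle for the closed-form models.

#' Monte Carlo random-walk diffusion signal
#'
#' Simulates fixed-step random walks of `n_walkers` spins in a chosen
#' geometry over the scheme's diffusion time, accumulates the narrow-pulse
#' spin phase \eqn{\phi = q\,\Delta u} (with \eqn{q = \sqrt{b/t_d}} and
#' \eqn{\Delta u} the net displacement along the gradient), and estimates the
#' attenuation as \eqn{\langle\cos\phi\rangle} with its Monte Carlo standard
#' error. Boundaries are impermeable and reflecting (radial mirroring, valid
#' for steps much smaller than the radius). Sticks and cylinders are powder
#' averaged by drawing an independent uniform orientation per walker.
#'
#' This is a validation oracle for [stick_powder_signal()],
#' [sphere_gpd_signal()] and [cylinder_powder_signal()], not a fitting
#' backend: it is unbiased but slow, whereas the closed forms are instant.
#'
#' @param geometry One of `"free"`, `"sphere"`, `"stick"`, `"cylinder"`.
#' @param b Diffusion weighting(s), ms/µm²; all b share one set of walks,
#'   so estimates at different b are correlated.
#' @param D Intrinsic diffusivity, µm²/ms.
#' @param r Radius, µm (required for sphere and cylinder).
#' @param scheme An [acq_scheme()]; only `t_d` is used (narrow-pulse phase).
#' @param n_walkers Number of spins (>= 1e4 recommended for quantitative
#'   comparisons).
#' @param n_steps Number of time steps; step duration is `t_d / n_steps`.
#'   A warning is issued if the step length exceeds r/10 in a bounded
#'   geometry.
#' @param seed Integer seed; results are reproducible given the seed and do
#'   not disturb the caller's RNG state.
#' @return A tibble with columns `b`, `signal`, `se`, `n_walkers`, `n_steps`.
#' @examples
#' sch <- acq_scheme(c(1, 5))
#' mc_random_walk_signal("free", b = c(1, 5), D = 0.5, scheme = sch,
#'                       n_walkers = 2000, n_steps = 200, seed = 1)
#' @export
mc_random_walk_signal <- function(geometry = c("free", "sphere", "stick",
                                               "cylinder"),
                                  b, D, r = NULL, scheme,
                                  n_walkers = 1e5, n_steps = 2000,
                                  seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(scheme, "acq_scheme"))
  check_b(b)
  check_positive_scalar(D, "D")
  if (geometry %in% c("sphere", "cylinder")) {
    if (is.null(r)) stop("`r` is required for bounded geometries.",
                         call. = FALSE)
    check_positive_scalar(r, "r")
  }
  n_walkers <- as.integer(n_walkers)
  n_steps <- as.integer(n_steps)
  stopifnot(n_walkers >= 1, n_steps >= 1)
  dt <- scheme$t_d / n_steps

  du <- withr::with_seed(seed, switch(geometry,
    free = mc_walk_free(D, scheme$t_d, n_walkers, n_steps),
    stick = mc_walk_stick(D, scheme$t_d, n_walkers, n_steps),
    sphere = mc_walk_sphere(D, dt, r, n_walkers, n_steps),
    cylinder = mc_walk_cylinder(D, dt, r, n_walkers, n_steps)
  ))

  q <- sqrt(b / scheme$t_d)
  est <- vapply(q, function(qi) {
    ph <- cos(qi * du)
    c(mean(ph), stats::sd(ph) / sqrt(n_walkers))
  }, numeric(2))
  tibble::tibble(b = b, signal = est[1, ], se = est[2, ],
                 n_walkers = n_walkers, n_steps = n_steps)
}

# free 3D walk: net displacement along the gradient axis
mc_walk_free <- function(D, t_d, n_walkers, n_steps) {
  ell <- sqrt(6 * D * (t_d / n_steps))
  z <- numeric(n_walkers)
  for (k in seq_len(n_steps)) {
    z <- z + ell * runif_cos(n_walkers)
  }
  z
}

# stick: 1D fixed-step walk along the segment axis, projected on the
# gradient through a per-walker isotropic orientation (powder average)
mc_walk_stick <- function(D, t_d, n_walkers, n_steps) {
  ell <- sqrt(2 * D * (t_d / n_steps))
  s <- numeric(n_walkers)
  for (k in seq_len(n_steps)) {
    s <- s + ell * sign(stats::runif(n_walkers) - 0.5)
  }
  s * runif_cos(n_walkers)
}

# sphere: 3D fixed-length steps with radial mirror reflection at |p| = r
mc_walk_sphere <- function(D, dt, r, n_walkers, n_steps) {
  ell <- sqrt(6 * D * dt)
  warn_step(ell, r)
  # uniform initial positions in the ball
  p <- random_directions(n_walkers) * (r * stats::runif(n_walkers)^(1 / 3))
  z0 <- p[, 3]
  for (k in seq_len(n_steps)) {
    p <- p + ell * random_directions(n_walkers)
    rad <- sqrt(rowSums(p^2))
    out <- rad > r
    if (any(out)) {
      p[out, ] <- p[out, ] * (fold_radius(rad[out], r) / rad[out])
    }
  }
  p[, 3] - z0
}

# mirror a radius back into [0, r] (repeatedly, so even steps larger than
# the diameter stay inside; accuracy still requires small steps)
fold_radius <- function(rad, r) {
  t <- rad %% (2 * r)
  ifelse(t <= r, t, 2 * r - t)
}

# cylinder: reflecting 2D disk walk (radial part) + free 1D axial walk,
# combined per walker through a random orientation and disk azimuth
mc_walk_cylinder <- function(D, dt, r, n_walkers, n_steps) {
  ell2 <- sqrt(4 * D * dt)
  ell1 <- sqrt(2 * D * dt)
  warn_step(ell2, r)
  th0 <- 2 * pi * stats::runif(n_walkers)
  rad0 <- r * sqrt(stats::runif(n_walkers))
  p <- cbind(rad0 * cos(th0), rad0 * sin(th0))
  p0 <- p
  s <- numeric(n_walkers)
  for (k in seq_len(n_steps)) {
    ang <- 2 * pi * stats::runif(n_walkers)
    p <- p + ell2 * cbind(cos(ang), sin(ang))
    rad <- sqrt(rowSums(p^2))
    out <- rad > r
    if (any(out)) {
      p[out, ] <- p[out, ] * (fold_radius(rad[out], r) / rad[out])
    }
    s <- s + ell1 * sign(stats::runif(n_walkers) - 0.5)
  }
  dperp <- p - p0
  cth <- runif_cos(n_walkers)              # cos of axis-to-gradient angle
  sth <- sqrt(1 - cth^2)
  psi <- 2 * pi * stats::runif(n_walkers)  # azimuth of gradient in the disk
  cth * s + sth * (dperp[, 1] * cos(psi) + dperp[, 2] * sin(psi))
}

runif_cos <- function(n) stats::runif(n, -1, 1)

random_directions <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

warn_step <- function(ell, r) {
  if (ell > r / 10) {
    warning(sprintf(
      "MC step length %.3g um exceeds r/10 = %.3g um; increase n_steps for accurate reflection",
      ell, r / 10), call. = FALSE)
  }
}
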