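# Independent oracle: exact narrow-pulse signal for diffusion in a
# reflecting sphere, by eigenmode expansion of the diffusion propagator
# (Neumann modes j_n(alpha r/a) Y_nm; overlap integrals with the plane wave
# by adaptive quadrature). Independent of both the package's GPD series and
# its Monte Carlo walker.

sph_bessel_j <- function(n, x) {
  x <- pmax(x, 1e-12)
  sqrt(pi / (2 * x)) * besselJ(x, n + 0.5)
}

exact_sphere_signal <- function(b, r, D, t_d, nmax = 14, kmax = 14) {
  vapply(b, function(bi) {
    if (bi == 0) return(1)
    q <- sqrt(bi / t_d)
    qa <- q * r
    tot <- 0
    for (n in 0:nmax) {
      dj <- function(x) {
        h <- 1e-6
        (sph_bessel_j(n, x + h) - sph_bessel_j(n, x - h)) / (2 * h)
      }
      xs <- seq(max(0.05, n * 0.3), 150, by = 0.01)
      fx <- dj(xs)
      idx <- which(diff(sign(fx)) != 0)
      roots <- vapply(idx, function(i) {
        stats::uniroot(dj, c(xs[i], xs[i + 1]), tol = 1e-12)$root
      }, numeric(1))
      roots <- utils::head(roots[abs(sph_bessel_j(n, roots)) > 1e-12],
                           kmax)
      if (n == 0) roots <- c(0, roots)  # uniform equilibrium mode
      for (al in roots) {
        ovl <- stats::integrate(function(u) {
          sph_bessel_j(n, al * u) * sph_bessel_j(n, qa * u) * u^2
        }, 0, 1, rel.tol = 1e-11)$value
        nrm <- stats::integrate(function(u) {
          sph_bessel_j(n, al * u)^2 * u^2
        }, 0, 1, rel.tol = 1e-11)$value
        tot <- tot + (2 * n + 1) * exp(-al^2 * D * t_d / r^2) *
          ovl^2 / (nrm * (1 / 3))
      }
    }
    tot
  }, numeric(1))
}
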