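# Closed-form signal models: limits, oracles, invariants.

test_that("stick powder average matches the quadrature oracle to 1e-8", {
  expect_equal(stick_powder_signal(0, 0.40), 1.0)
  # frozen oracle value: integrate(exp(-20*0.52*x^2), 0, 1)
  expect_equal(stick_powder_signal(20, 0.52), 0.274805902662,
               tolerance = 1e-10)
  # first-order expansion at small bD
  expect_equal(stick_powder_signal(1, 0.01), 1 - 0.01 / 3,
               tolerance = 1e-4)
  withr::with_seed(42, {
    b <- runif(100, 0, 25)
    D <- runif(100, 0.05, 1.5)
    for (i in seq_len(100)) {
      expect_equal(stick_powder_signal(b[i], D[i]),
                   stick_quadrature_oracle(b[i], D[i]),
                   tolerance = 1e-8)
    }
  })
})

test_that("sphere GPD signal obeys its physical limits", {
  sch <- paper_scheme
  expect_equal(sphere_gpd_signal(sch, 0, 3.1, 0.4), 1.0)
  # negligible displacement: fully restricted small sphere
  for (b in c(0.02, 5, 20)) {
    expect_gte(sphere_gpd_signal(sch, b, 0.01, 0.4), 0.999)
  }
  # frozen-diffusion limit D -> 0 recovers free-diffusion slope -b*D
  # (up to the O(sqrt(D)) surface boundary-layer term, hence tiny D)
  expect_equal(sphere_gpd_signal(sch, 10, 3.1, 1e-6), exp(-10 * 1e-6),
               tolerance = 1e-7)
  # monotone decreasing in b
  s <- sphere_gpd_signal(sch, seq(0, 25, length.out = 80), 3.1, 0.4)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
})

test_that("finite-pulse GPD converges to the narrow-pulse limit", {
  b <- c(1, 5, 20)
  narrow <- sphere_gpd_signal(paper_scheme, b, 3.1, 0.4)
  delta <- 0.001
  fin <- acq_scheme(paper_b_grid, t_d = 53.2, delta = delta,
                    Delta = 53.2 + delta / 3,
                    pulse_model = "finite_pulse")
  expect_equal(sphere_gpd_signal(fin, b, 3.1, 0.4), narrow,
               tolerance = 1e-4)
  # a realistic finite pulse attenuates less than the narrow-pulse limit
  fin2 <- acq_scheme(paper_b_grid, t_d = 53.2, delta = 15,
                     Delta = 53.2 + 5, pulse_model = "finite_pulse")
  expect_true(all(sphere_gpd_signal(fin2, b, 3.1, 0.4) >= narrow))
})

test_that("cylinder powder signal reduces to the stick as r -> 0", {
  sch <- paper_scheme
  for (b in c(0.5, 5, 10, 20)) {
    expect_equal(cylinder_powder_signal(sch, b, 0.01, 0.4),
                 stick_powder_signal(b, 0.4), tolerance = 1e-3)
  }
  expect_equal(cylinder_powder_signal(sch, 0, 1, 0.4), 1.0)
  s <- cylinder_powder_signal(sch, seq(0, 25, length.out = 80), 1, 0.4)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
})

test_that("sticks-and-spheres mixture is exactly linear in f_sphere", {
  sch <- paper_scheme
  b <- paper_b_grid
  stick <- sticks_spheres_signal(sch, b, 0.4, 3.1, 0)
  sph <- sticks_spheres_signal(sch, b, 0.4, 3.1, 1)
  expect_identical(stick, stick_powder_signal(b, 0.4))
  expect_identical(sph, sphere_gpd_signal(sch, b, 3.1, 0.4))
  for (f in c(0.25, 0.5, 0.8)) {
    expect_equal(sticks_spheres_signal(sch, b, 0.4, 3.1, f),
                 f * sph + (1 - f) * stick, tolerance = 1e-15)
  }
})

test_that("all model signals stay in (0, 1], equal 1 at b = 0, decrease in b", {
  sch <- paper_scheme
  bb <- seq(0, 25, length.out = 60)
  models <- list(
    stick = function(b) stick_powder_signal(b, 0.52),
    sphere = function(b) sphere_gpd_signal(sch, b, 4, 0.6),
    cylinder = function(b) cylinder_powder_signal(sch, b, 2, 0.6),
    mix = function(b) sticks_spheres_signal(sch, b, 0.4, 3.1, 0.5),
    free = function(b) free_signal(b, 1))
  for (nm in names(models)) {
    s <- models[[nm]](bb)
    expect_equal(s[1], 1, tolerance = 1e-12)
    expect_true(all(s > 0 & s <= 1), label = nm)
    expect_true(all(diff(s) <= 0), label = nm)
  }
})

test_that("stick attenuation decreases in D as well as in b", {
  Ds <- seq(0.1, 1.5, length.out = 20)
  s <- vapply(Ds, function(D) stick_powder_signal(5, D), numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("invalid model arguments are rejected", {
  sch <- paper_scheme
  expect_error(stick_powder_signal(-1, 0.4), "nonnegative")
  expect_error(stick_powder_signal(1, -0.4), "positive")
  expect_error(sphere_gpd_signal(sch, 1, -3, 0.4), "positive")
  expect_error(sphere_gpd_signal(sch, 1, 3, 0), "positive")
  expect_error(sticks_spheres_signal(sch, 1, 0.4, 3.1, 1.2), "\\[0, 1\\]")
  expect_error(acq_scheme(c(1, 1, 2)), "strictly increasing")
  expect_error(acq_scheme(c(0, 1, 2)), "strictly positive")
  expect_error(acq_scheme(1:5, t_d = 53.2, delta = 10, Delta = 40,
                          pulse_model = "finite_pulse"), "inconsistent")
})
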