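# Step (i): pooling and sticks-and-spheres fitting.

test_that("pooling averages normalised attenuations and propagates SD", {
  b <- paper_b_grid
  two <- dplyr::bind_rows(
    make_curve(b, rep(0.8, length(b)), metabolite = "NAA"),
    make_curve(b, rep(0.6, length(b)), metabolite = "Ins"))
  pooled <- pool_intracellular(two)
  expect_equal(unique(pooled$metabolite), "pooled")
  expect_equal(pooled$signal, rep(0.7, length(b)))
  expect_equal(pooled$sd, rep(stats::sd(c(0.8, 0.6)), length(b)))

  same <- dplyr::bind_rows(
    make_curve(b, exp(-0.3 * b) + 0.5, metabolite = "NAA"),
    make_curve(b, exp(-0.3 * b) + 0.5, metabolite = "Ins"))
  pooled2 <- pool_intracellular(same)
  expect_equal(pooled2$signal, sort(exp(-0.3 * b) + 0.5,
                                    decreasing = TRUE))
  expect_equal(pooled2$sd, rep(0, length(b)))
})

test_that("pooling refuses mismatched b grids and missing metabolites", {
  b <- paper_b_grid
  mism <- dplyr::bind_rows(
    make_curve(b, exp(-0.1 * b), metabolite = "NAA"),
    make_curve(b + 0.5, exp(-0.1 * b), metabolite = "Ins"))
  expect_error(pool_intracellular(mism), "different b grids")
  expect_error(
    pool_intracellular(make_curve(b, exp(-0.1 * b), metabolite = "NAA")),
    "Ins")
})

test_that("pooling two noisy realisations beats either input (variance reduction)", {
  b <- paper_b_grid
  sch <- paper_scheme
  truth <- sticks_spheres_signal(sch, b, 0.4, 3.1, 0.5)
  rmses <- withr::with_seed(11, {
    t(vapply(seq_len(100), function(i) {
      naa <- truth * (1 + 0.02 * rnorm(length(b)))
      ins <- truth * (1 + 0.02 * rnorm(length(b)))
      pooled <- (naa + ins) / 2
      rmse <- function(x) sqrt(mean((x - truth)^2))
      c(pooled = rmse(pooled), naa = rmse(naa), ins = rmse(ins))
    }, numeric(3)))
  })
  # pooling halves the error variance: clearly better on average, and
  # usually better than even the luckier of the two inputs
  expect_lt(mean(rmses[, "pooled"]), mean(rmses[, "naa"]))
  expect_lt(mean(rmses[, "pooled"]), mean(rmses[, "ins"]))
  wins <- rmses[, "pooled"] < pmin(rmses[, "naa"], rmses[, "ins"])
  expect_gte(mean(wins), 0.6)
})

test_that("noiseless sticks-and-spheres data are recovered within 1%", {
  fit <- fit_microstructure(truth_pooled_curve(), paper_scheme)
  expect_equal(coef(fit)[["D_intra"]], 0.40, tolerance = 0.01)
  expect_equal(coef(fit)[["r_soma"]], 3.1, tolerance = 0.01)
  expect_equal(coef(fit)[["f_sphere"]], 0.5, tolerance = 0.01)
  expect_false(any(fit$at_bound))
  # optimizer sanity: optimum cost no worse than at the generating truth
  expect_lte(fit$cost, 1e-10)
})

test_that("fitting with f_sphere fixed and the cylinder variant works", {
  d <- truth_pooled_curve()
  fit_fix <- fit_microstructure(d, paper_scheme, f_sphere = 0.5)
  expect_equal(coef(fit_fix)[["D_intra"]], 0.40, tolerance = 0.01)
  expect_equal(coef(fit_fix)[["f_sphere"]], 0.5)
  expect_setequal(fit_fix$free, c("D_intra", "r_soma"))

  cylcurve <- make_curve(
    paper_b_grid,
    cylinder_powder_signal(paper_scheme, paper_b_grid, 2, 0.45))
  fit_cyl <- fit_microstructure(cylcurve, paper_scheme,
                                model = "cylinders")
  expect_equal(coef(fit_cyl)[["D_intra"]], 0.45, tolerance = 0.01)
  expect_equal(coef(fit_cyl)[["r_soma"]], 2, tolerance = 0.02)
})

test_that("refitting the fitted forward curve is idempotent", {
  fit <- fit_microstructure(truth_pooled_curve(), paper_scheme)
  refit <- fit_microstructure(
    make_curve(paper_b_grid,
               sticks_spheres_signal(paper_scheme, paper_b_grid,
                                     coef(fit)[["D_intra"]],
                                     coef(fit)[["r_soma"]],
                                     coef(fit)[["f_sphere"]])),
    paper_scheme)
  expect_equal(coef(refit), coef(fit), tolerance = 1e-6)
})

test_that("underdetermined fits and bad inputs error", {
  short <- make_curve(c(0.02, 20), c(1, 0.5))
  expect_error(fit_microstructure(short, acq_scheme(c(0.02, 20))),
               "4 distinct b")
  multi <- dplyr::bind_rows(truth_pooled_curve(),
                            make_curve(paper_b_grid,
                                       exp(-0.1 * paper_b_grid),
                                       id = "m2"))
  expect_error(fit_microstructure(multi, paper_scheme), "single")
})

test_that("parameter recovery stays unbiased over noisy synthetic curves", {
  sch <- paper_scheme
  b <- paper_b_grid
  truth <- sticks_spheres_signal(sch, b, 0.4, 3.1, 0.5)
  # pipeline fits operate on pooled NAA+Ins curves: two noisy metabolite
  # realisations (relative SD 0.02 each) averaged, then renormalised
  ests <- withr::with_seed(21, {
    t(vapply(seq_len(100), function(i) {
      s <- pmax((truth * (1 + 0.02 * rnorm(length(b))) +
                   truth * (1 + 0.02 * rnorm(length(b)))) / 2, 1e-4)
      fit <- suppressWarnings(
        fit_microstructure(make_curve(b, s / s[1]), sch))
      coef(fit)[c("D_intra", "r_soma")]
    }, numeric(2)))
  })
  expect_lt(abs(stats::median(ests[, 1]) - 0.40), 0.02)
  expect_lt(abs(stats::median(ests[, 2]) - 3.1), 0.4)
})

test_that("bootstrap intervals cover the truth on well-behaved data", {
  b <- paper_b_grid
  truth <- sticks_spheres_signal(paper_scheme, b, 0.4, 3.1, 0.5)
  s <- withr::with_seed(5, pmax(truth * (1 + 0.01 * rnorm(length(b))),
                                1e-4))
  fit <- suppressWarnings(
    fit_microstructure(make_curve(b, s / s[1]), paper_scheme,
                       n_boot = 60, seed = 2))
  td <- tidy(fit)
  expect_true(all(c("std.error", "conf.low", "conf.high") %in% names(td)))
  row <- td[td$term == "D_intra", ]
  expect_lt(row$conf.low, 0.45)
  expect_gt(row$conf.high, 0.35)
})
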