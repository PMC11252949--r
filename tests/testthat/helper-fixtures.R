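# Shared fixtures and independent oracles used across the test files.

paper_b_grid <- dmrslac::default_b_grid()
paper_scheme <- dmrslac::acq_scheme(paper_b_grid)

# independent quadrature oracle for the powder-averaged stick
stick_quadrature_oracle <- function(b, D) {
  vapply(b, function(bi) {
    if (bi == 0) return(1)
    stats::integrate(function(x) exp(-bi * D * x^2), 0, 1,
                     rel.tol = 1e-12)$value
  }, numeric(1))
}

# build a single-curve tibble from a signal vector
make_curve <- function(b, s, id = "m1", group = "control",
                       metabolite = "pooled", sd = NULL) {
  d <- tibble::tibble(subject_id = id, group = group,
                      metabolite = metabolite, b = b, signal = s)
  if (!is.null(sd)) d$sd <- sd
  d
}

# noiseless sticks-and-spheres curve at the reference truth
truth_micro <- c(D_intra = 0.40, r_soma = 3.1, f_sphere = 0.5)

truth_pooled_curve <- function(scheme = paper_scheme, b = paper_b_grid) {
  make_curve(b, dmrslac::sticks_spheres_signal(
    scheme, b, truth_micro[["D_intra"]], truth_micro[["r_soma"]],
    truth_micro[["f_sphere"]]))
}

# noiseless two-pool lactate curve from given compartment parameters
truth_lactate_curve <- function(f_extra = 0.36, D_extra = 1.3,
                                lambda = 1.3, scheme = paper_scheme,
                                b = paper_b_grid) {
  s_i <- dmrslac::predict_intracellular_lactate(truth_micro, scheme,
                                                b_grid = b,
                                                lambda = lambda)
  make_curve(b, f_extra * exp(-b * D_extra) +
                  (1 - f_extra) * s_i$signal,
             metabolite = "Lac")
}
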