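# Step (i): pool intracellular metabolites and fit the sticks-and-spheres
# model for D_intra, r_soma and (optionally) f_sphere.

#' Pool intracellular metabolite attenuation curves
#'
#' Averages the normalised attenuations of purely intracellular metabolites
#' (by default NAA and myo-inositol) at each b, per subject. Because both
#' metabolites probe the same intracellular geometry, their average is a
#' lower-noise estimate of the intracellular attenuation; the across-input
#' SD at each b is propagated into the `sd` column.
#'
#' @param data Curve table (see [validate_curves()]) containing at least one
#'   curve per metabolite in `metabolites` for each subject. All curves of a
#'   subject must share an identical b grid; no interpolation is performed.
#' @param metabolites Metabolite labels to pool (default `c("NAA", "Ins")`).
#' @return A tibble of pooled curves, one per subject, with
#'   `metabolite = "pooled"` and `sd` the across-metabolite SD at each b.
#' @examples
#' cfg <- cohort_config(n_per_group = 2)
#' curves <- generate_cohort(cfg)
#' pool_intracellular(curves)
#' @export
pool_intracellular <- function(data, metabolites = c("NAA", "Ins")) {
  validate_curves(data)
  sub <- dplyr::filter(data, .data$metabolite %in% metabolites)
  present <- unique(sub$metabolite)
  if (!all(metabolites %in% present)) {
    stop("missing intracellular metabolite(s): ",
         paste(setdiff(metabolites, present), collapse = ", "),
         call. = FALSE)
  }
  sub |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::group_modify(function(d, key) {
      grids <- split(d$b, d$metabolite)
      grids <- lapply(grids, sort)
      ref <- grids[[1]]
      same <- vapply(grids, function(g) {
        length(g) == length(ref) && all(abs(g - ref) < 1e-9)
      }, logical(1))
      if (!all(same)) {
        stop(sprintf(
          "subject '%s': metabolites measured on different b grids; cannot pool without interpolation",
          key$subject_id), call. = FALSE)
      }
      d |>
        dplyr::group_by(.data$b) |>
        dplyr::summarise(
          sd = stats::sd(.data$signal),
          signal = mean(.data$signal),
          .groups = "drop")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(metabolite = "pooled") |>
    dplyr::relocate(dplyr::all_of(curve_cols))
}

#' Fit the sticks-and-spheres model to an intracellular attenuation curve
#'
#' Step (i) of the pipeline: bounded weighted least squares of
#' [sticks_spheres_signal()] to a single pooled intracellular curve,
#' estimating the intracellular diffusivity `D_intra` (µm²/ms), the soma
#' radius `r_soma` (µm) and, unless fixed, the sphere signal fraction
#' `f_sphere`. Optimisation is a deterministic grid multi-start
#' (Levenberg-Marquardt from the best grid points); parameters landing on a
#' bound are flagged.
#'
#' @param data A single curve (one subject x metabolite), normalised to 1 at
#'   the lowest b, with at least 4 distinct b values spanning a decade.
#' @param scheme An [acq_scheme()] describing the acquisition timing.
#' @param f_sphere `NULL` (default) to fit the sphere fraction freely, or a
#'   fixed value in \[0, 1\].
#' @param model `"sticks_spheres"` (default) or `"cylinders"`, the
#'   robustness variant in which the whole intracellular signal arises from
#'   finite-radius cylinders (then `r_soma` is the cylinder radius and
#'   `f_sphere` is irrelevant).
#' @param weights `"auto"` (inverse-variance when a usable `sd` column is
#'   present, else uniform), `"uniform"`, or `"inverse_variance"`.
#' @param bounds Named list overriding the default box
#'   `D_intra` in \[0.01, 1.5\], `r_soma` in \[0.1, 15\], `f_sphere` in \[0, 1\].
#' @param n_grid Start-grid points per free parameter (default 3).
#' @param n_boot Residual-bootstrap draws for confidence half-widths
#'   (0 = skip; pipeline default 200).
#' @param seed Seed for the bootstrap only; the fit itself is deterministic.
#' @return A `micro_fit` object; see [tidy.micro_fit()], [glance.micro_fit()]
#'   and [autoplot.micro_fit()].
#' @examples
#' sch <- acq_scheme(default_b_grid())
#' b <- default_b_grid()
#' s <- sticks_spheres_signal(sch, b, 0.4, 3.1, 0.5)
#' d <- tibble::tibble(subject_id = "m1", group = "control",
#'                     metabolite = "pooled", b = b, signal = s)
#' fit <- fit_microstructure(d, sch)
#' coef(fit)
#' @export
fit_microstructure <- function(data, scheme,
                               f_sphere = NULL,
                               model = c("sticks_spheres", "cylinders"),
                               weights = "auto",
                               bounds = NULL,
                               n_grid = 3,
                               n_boot = 0,
                               seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(scheme, "acq_scheme"))
  d <- single_curve(data, "pooled intracellular curve")
  check_fit_grid(d$b)
  w <- sqrt(fit_weights(d, weights))
  if (!is.null(f_sphere)) check_fraction(f_sphere, "f_sphere")

  box <- list(D_intra = c(0.01, 1.5), r_soma = c(0.1, 15),
              f_sphere = c(0, 1))
  box[names(bounds)] <- bounds

  fwd <- micro_forward(model, scheme, f_sphere)
  free <- fwd$free
  lower <- vapply(box[free], `[`, numeric(1), 1)
  upper <- vapply(box[free], `[`, numeric(1), 2)

  fit_once <- function(y) {
    multistart_ls(function(p) w * (fwd$fn(p, d$b) - y),
                  lower, upper, n_grid = n_grid, par_names = free)$par
  }
  res <- multistart_ls(function(p) w * (fwd$fn(p, d$b) - d$signal),
                       lower, upper, n_grid = n_grid, par_names = free)
  fitted <- fwd$fn(res$par, d$b)
  ci <- bootstrap_ci(fit_once, fitted, d$signal - fitted, n_boot, seed)

  par_full <- fwd$full_par(res$par)
  structure(
    list(par = par_full, free = free, cost = res$cost,
         at_bound = res$at_bound, ci = ci, model = model,
         fixed_f_sphere = f_sphere, data = d, fitted = fitted,
         scheme = scheme, n_starts = res$n_starts),
    class = "micro_fit")
}

# forward-model closure for each microstructure variant; `free` lists the
# fitted parameter names, full_par() reassembles the complete parameter set
micro_forward <- function(model, scheme, f_sphere) {
  if (model == "cylinders") {
    list(
      free = c("D_intra", "r_soma"),
      fn = function(p, b) cylinder_powder_signal(scheme, b, p[["r_soma"]],
                                                 p[["D_intra"]]),
      full_par = function(p) c(p, f_sphere = NA_real_)
    )
  } else if (is.null(f_sphere)) {
    list(
      free = c("D_intra", "r_soma", "f_sphere"),
      fn = function(p, b) sticks_spheres_signal(scheme, b, p[["D_intra"]],
                                                p[["r_soma"]],
                                                p[["f_sphere"]]),
      full_par = function(p) p
    )
  } else {
    list(
      free = c("D_intra", "r_soma"),
      fn = function(p, b) sticks_spheres_signal(scheme, b, p[["D_intra"]],
                                                p[["r_soma"]], f_sphere),
      full_par = function(p) c(p, f_sphere = f_sphere)
    )
  }
}

check_fit_grid <- function(b) {
  bu <- unique(b)
  if (length(bu) < 4) {
    stop("model fitting needs >= 4 distinct b values; got ", length(bu),
         call. = FALSE)
  }
  if (max(bu) / max(min(bu), 1e-12) < 10) {
    warning("b values span less than a decade; restricted-diffusion parameters may be poorly determined",
            call. = FALSE)
  }
  invisible(b)
}

#' @export
print.micro_fit <- function(x, ...) {
  cat("<micro_fit> sticks-and-spheres intracellular fit\n")
  cat(sprintf("  model: %s%s\n", x$model,
              if (!is.null(x$fixed_f_sphere))
                sprintf(" (f_sphere fixed at %.2f)", x$fixed_f_sphere)
              else ""))
  p <- x$par
  cat(sprintf("  D_intra = %.3f um^2/ms, r_soma = %.2f um, f_sphere = %s\n",
              p[["D_intra"]], p[["r_soma"]],
              ifelse(is.na(p[["f_sphere"]]), "-",
                     sprintf("%.2f", p[["f_sphere"]]))))
  cat(sprintf("  cost = %.4g over %d points\n", x$cost, nrow(x$data)))
  invisible(x)
}

#' @export
coef.micro_fit <- function(object, ...) object$par

#' Tidy a microstructure fit
#'
#' @param x A `micro_fit` from [fit_microstructure()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and when
#'   a bootstrap was run, `std.error`, `conf.low`, `conf.high`; `at_bound`
#'   flags estimates pinned at the box boundary.
#' @export
tidy.micro_fit <- function(x, ...) {
  terms <- x$free
  out <- tibble::tibble(
    term = terms,
    estimate = as.numeric(x$par[terms]),
    at_bound = as.logical(x$at_bound[terms]))
  if (!is.null(x$ci)) {
    out$std.error <- as.numeric(x$ci$sd[terms])
    out$conf.low <- out$estimate - as.numeric(x$ci$half_width[terms])
    out$conf.high <- out$estimate + as.numeric(x$ci$half_width[terms])
  }
  out
}

#' Glance at a microstructure fit
#'
#' @inheritParams tidy.micro_fit
#' @return A one-row tibble with the residual cost, observation count,
#'   model variant and multi-start count.
#' @export
glance.micro_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, n_obs = nrow(x$data), model = x$model,
                 n_starts = x$n_starts,
                 any_at_bound = any(x$at_bound))
}
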