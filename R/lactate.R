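# Steps (ii)-(iii): predict intracellular lactate attenuation from the
# fitted microstructure, then fit the two-pool intra/extracellular model.

#' Predict intracellular lactate attenuation
#'
#' Step (ii) of the pipeline: evaluates the intracellular model with the
#' geometry fitted on NAA + Ins, but with the intrinsic diffusivity scaled
#' by `lambda`, the ratio of lactate's free diffusivity to that of the
#' larger intracellular metabolites (default 1.3: lactate is a smaller
#' molecule and diffuses roughly 30% faster). Geometry (`r_soma`,
#' `f_sphere`, or the cylinder radius) is unchanged.
#'
#' @param micro A `micro_fit` from [fit_microstructure()], or a named vector
#'   or list with `D_intra`, `r_soma`, `f_sphere`.
#' @param scheme An [acq_scheme()].
#' @param b_grid b values at which to evaluate (defaults to the scheme's).
#' @param lambda Lactate diffusivity scaling, in \[1, 2\].
#' @param model `"sticks_spheres"` or `"cylinders"`; defaults to the
#'   variant stored in `micro` when it is a `micro_fit`.
#' @return A tibble curve (`metabolite = "Lac_intra"`) normalised to 1 at
#'   b = 0 by construction.
#' @examples
#' sch <- acq_scheme(default_b_grid())
#' predict_intracellular_lactate(
#'   c(D_intra = 0.4, r_soma = 3.1, f_sphere = 0.5), sch)
#' @export
predict_intracellular_lactate <- function(micro, scheme, b_grid = NULL,
                                          lambda = 1.3, model = NULL) {
  stopifnot(inherits(scheme, "acq_scheme"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 1 ||
        lambda > 2) {
    stop("`lambda` must be a single value in [1, 2] (lactate diffuses at least as fast as larger metabolites).",
         call. = FALSE)
  }
  if (inherits(micro, "micro_fit")) {
    if (is.null(model)) model <- micro$model
    p <- micro$par
  } else {
    p <- unlist(micro)
    if (is.null(model)) model <- "sticks_spheres"
  }
  needed <- if (model == "cylinders") c("D_intra", "r_soma") else
    c("D_intra", "r_soma", "f_sphere")
  if (!all(needed %in% names(p)) || any(!is.finite(p[needed]))) {
    stop("`micro` must provide finite ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(b_grid)) b_grid <- scheme$b_values
  d_lac <- lambda * p[["D_intra"]]
  s <- if (model == "cylinders") {
    cylinder_powder_signal(scheme, b_grid, p[["r_soma"]], d_lac)
  } else {
    sticks_spheres_signal(scheme, b_grid, d_lac, p[["r_soma"]],
                          p[["f_sphere"]])
  }
  tibble::tibble(subject_id = "model", group = "model",
                 metabolite = "Lac_intra", b = b_grid, signal = s)
}

#' Fit the two-pool lactate model
#'
#' Step (iii): weighted least squares of the two-pool forward model
#' \deqn{S(b) = f_{extra}\, e^{-b D_{extra}} + (1 - f_{extra})\, S_{intra}^{Lac}(b)}
#' to a measured lactate attenuation curve, with the intracellular component
#' \eqn{S_{intra}^{Lac}} fixed from step (ii). Extracellular diffusion is
#' taken as Gaussian (monoexponential); `f_extra` is constrained to \[0, 1\]
#' and `D_extra` to \[0.2, 3\] µm²/ms (bracketing free-water-scale
#' diffusivities).
#'
#' @param data A single lactate curve (columns `b`, `signal`, optional
#'   `sd`), normalised to 1 at the lowest b.
#' @param s_intra_lac The predicted intracellular lactate curve from
#'   [predict_intracellular_lactate()], on exactly the same b grid.
#' @param weights,n_grid,n_boot,seed As in [fit_microstructure()].
#' @param bounds Named list overriding the default `f_extra` \[0, 1\] /
#'   `D_extra` \[0.2, 3\] box.
#' @return A `two_pool_fit` object with elements `par` (`f_extra`,
#'   `D_extra`), `cost`, `at_bound`, optional bootstrap `ci`; has
#'   [tidy.two_pool_fit()] and [autoplot.two_pool_fit()] methods.
#' @examples
#' sch <- acq_scheme(default_b_grid())
#' s_i <- predict_intracellular_lactate(
#'   c(D_intra = 0.4, r_soma = 3.1, f_sphere = 0.5), sch)
#' lac <- s_i
#' lac$signal <- 0.36 * exp(-lac$b * 1.3) + 0.64 * s_i$signal
#' lac$metabolite <- "Lac"
#' fit_two_pool(lac, s_i)
#' @export
fit_two_pool <- function(data, s_intra_lac, weights = "auto",
                         bounds = NULL, n_grid = 3, n_boot = 0, seed = 1L) {
  d <- single_curve(data, "lactate curve")
  check_fit_grid(d$b)
  si <- dplyr::arrange(s_intra_lac, .data$b)
  if (nrow(si) != nrow(d) || any(abs(si$b - d$b) > 1e-8)) {
    stop("`s_intra_lac` must be evaluated on exactly the lactate curve's b grid (no interpolation).",
         call. = FALSE)
  }
  w <- sqrt(fit_weights(d, weights))
  box <- list(f_extra = c(0, 1), D_extra = c(0.2, 3))
  box[names(bounds)] <- bounds
  lower <- vapply(box, `[`, numeric(1), 1)
  upper <- vapply(box, `[`, numeric(1), 2)
  s_i <- si$signal

  fwd <- function(p, b) {
    p[["f_extra"]] * exp(-b * p[["D_extra"]]) + (1 - p[["f_extra"]]) * s_i
  }
  fit_once <- function(y) {
    multistart_ls(function(p) w * (fwd(p, d$b) - y), lower, upper,
                  n_grid = n_grid, par_names = names(box))$par
  }
  res <- multistart_ls(function(p) w * (fwd(p, d$b) - d$signal),
                       lower, upper, n_grid = n_grid,
                       par_names = names(box))
  fitted <- fwd(res$par, d$b)
  ci <- bootstrap_ci(fit_once, fitted, d$signal - fitted, n_boot, seed)
  structure(
    list(par = res$par, cost = res$cost, at_bound = res$at_bound, ci = ci,
         data = d, s_intra_lac = si, fitted = fitted,
         n_starts = res$n_starts),
    class = "two_pool_fit")
}

#' @export
print.two_pool_fit <- function(x, ...) {
  cat("<two_pool_fit> intra/extracellular lactate fit\n")
  cat(sprintf("  f_extra = %.3f, D_extra = %.3f um^2/ms, cost = %.4g\n",
              x$par[["f_extra"]], x$par[["D_extra"]], x$cost))
  invisible(x)
}

#' @export
coef.two_pool_fit <- function(object, ...) object$par

#' Tidy a two-pool lactate fit
#'
#' @param x A `two_pool_fit` from [fit_two_pool()].
#' @param ... Unused.
#' @return One row per parameter (`f_extra`, `D_extra`) with bootstrap
#'   intervals when available.
#' @export
tidy.two_pool_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = names(x$par),
    estimate = as.numeric(x$par),
    at_bound = as.logical(x$at_bound))
  if (!is.null(x$ci)) {
    out$std.error <- as.numeric(x$ci$sd)
    out$conf.low <- out$estimate - as.numeric(x$ci$half_width)
    out$conf.high <- out$estimate + as.numeric(x$ci$half_width)
  }
  out
}

#' Glance at a two-pool lactate fit
#'
#' @inheritParams tidy.two_pool_fit
#' @return One-row tibble with cost, n_obs and bound flags.
#' @export
glance.two_pool_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, n_obs = nrow(x$data),
                 n_starts = x$n_starts, any_at_bound = any(x$at_bound))
}

#' Phenomenological biexponential fit
#'
#' The historical comparator for intra/extracellular partitioning: fits
#' \eqn{f\,e^{-b D_{fast}} + (1-f)\,e^{-b D_{slow}}} with the ordering
#' constraint \eqn{D_{fast} \ge D_{slow}}. Unlike the two-pool model it
#' carries no biophysical prior on the slow (intracellular) component, which
#' is why it misattributes signal when the intracellular pool is both
#' restricted and faster-diffusing, as lactate's is.
#'
#' @param data A single curve with at least 5 b values.
#' @param weights,n_grid As in [fit_microstructure()].
#' @return A `biexp_fit` object with `par` (`f_fast`, `D_fast`, `D_slow`),
#'   `cost`, and `degenerate` flag (TRUE when the two rates coincide or the
#'   fraction sits on a bound, i.e. the data are effectively
#'   monoexponential).
#' @examples
#' b <- default_b_grid()
#' d <- tibble::tibble(subject_id = "s", group = "g", metabolite = "Lac",
#'                     b = b, signal = 0.3 * exp(-b) + 0.7 * exp(-0.1 * b))
#' biexponential_fit(d)
#' @export
biexponential_fit <- function(data, weights = "auto", n_grid = 4) {
  d <- single_curve(data, "curve")
  if (length(unique(d$b)) < 5) {
    stop("biexponential fitting needs >= 5 distinct b values.",
         call. = FALSE)
  }
  w <- sqrt(fit_weights(d, weights))
  # parametrised as (f_fast, D_slow, dD = D_fast - D_slow >= 0) so the
  # ordering constraint is built into the box
  lower <- c(f_fast = 0, D_slow = 1e-4, dD = 0)
  upper <- c(f_fast = 1, D_slow = 3, dD = 10)
  fwd <- function(p, b) {
    p[["f_fast"]] * exp(-b * (p[["D_slow"]] + p[["dD"]])) +
      (1 - p[["f_fast"]]) * exp(-b * p[["D_slow"]])
  }
  res <- suppressWarnings(
    multistart_ls(function(p) w * (fwd(p, d$b) - d$signal), lower, upper,
                  n_grid = n_grid, n_local = 8, par_names = names(lower)))
  par <- c(f_fast = res$par[["f_fast"]],
           D_fast = res$par[["D_slow"]] + res$par[["dD"]],
           D_slow = res$par[["D_slow"]])
  degenerate <- res$par[["dD"]] < 1e-3 ||
    par[["f_fast"]] < 1e-3 || par[["f_fast"]] > 1 - 1e-3
  structure(
    list(par = par, cost = res$cost, degenerate = degenerate, data = d,
         fitted = fwd(res$par, d$b)),
    class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("<biexp_fit> phenomenological biexponential\n")
  cat(sprintf("  f_fast = %.3f, D_fast = %.3f, D_slow = %.3f, cost = %.4g%s\n",
              x$par[["f_fast"]], x$par[["D_fast"]], x$par[["D_slow"]],
              x$cost, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
coef.biexp_fit <- function(object, ...) object$par

#' Tidy a biexponential fit
#'
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @return One row per parameter with a `degenerate` flag.
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = as.numeric(x$par),
                 degenerate = x$degenerate)
}
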