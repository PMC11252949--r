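#' Diffusion acquisition scheme
#'
#' Describes the timing of the diffusion-weighting experiment that produced a
#' set of attenuation curves. Units are fixed package-wide: b-values in
#' ms/µm², diffusivities in µm²/ms, lengths in µm and times in ms, so that
#' `b * D` is dimensionless.
#'
#' @param b_values Numeric vector of diffusion weightings (ms/µm²). Must be
#'   strictly positive and strictly increasing; at least 4 distinct values
#'   are required for any model fit.
#' @param t_d Effective diffusion time in ms (default 53.2, the value used
#'   for the in vivo cohort this package models).
#' @param delta Gradient pulse duration in ms; only used (and then required)
#'   when `pulse_model = "finite_pulse"`.
#' @param Delta Gradient pulse separation in ms; only used (and then
#'   required) when `pulse_model = "finite_pulse"`. Must satisfy
#'   `Delta >= delta > 0` and be consistent with `t_d = Delta - delta/3`.
#' @param pulse_model `"narrow_pulse"` (default) or `"finite_pulse"`.
#'   The narrow-pulse limit is fully determined by `t_d` alone; the finite
#'   pulse variant evaluates the full Gaussian-phase-distribution bracket.
#'
#' @return An object of class `acq_scheme`.
#' @examples
#' sch <- acq_scheme(c(0.02, 1, 3, 10, 20))
#' sch
#' @export
acq_scheme <- function(b_values,
                       t_d = 53.2,
                       delta = NULL,
                       Delta = NULL,
                       pulse_model = c("narrow_pulse", "finite_pulse")) {
  pulse_model <- match.arg(pulse_model)
  stopifnot(is.numeric(b_values), length(b_values) >= 1)
  if (any(b_values <= 0)) {
    stop("`b_values` must be strictly positive; include the lowest ",
         "weighting (e.g. 0.02) rather than 0.", call. = FALSE)
  }
  if (is.unsorted(b_values, strictly = TRUE)) {
    stop("`b_values` must be strictly increasing with no duplicates.",
         call. = FALSE)
  }
  if (!is.numeric(t_d) || length(t_d) != 1 || t_d <= 0) {
    stop("`t_d` must be a single positive diffusion time in ms.",
         call. = FALSE)
  }
  if (pulse_model == "finite_pulse") {
    if (is.null(delta) || is.null(Delta)) {
      stop("finite_pulse scheme requires both `delta` and `Delta` (ms).",
           call. = FALSE)
    }
    if (delta <= 0 || Delta < delta) {
      stop("finite_pulse scheme requires Delta >= delta > 0.", call. = FALSE)
    }
    t_eff <- Delta - delta / 3
    if (abs(t_eff - t_d) > 1e-6 * max(1, t_d)) {
      stop(sprintf(
        "`t_d` (%.4g ms) is inconsistent with Delta - delta/3 = %.4g ms.",
        t_d, t_eff), call. = FALSE)
    }
  }
  structure(
    list(b_values = as.numeric(b_values), t_d = as.numeric(t_d),
         delta = delta, Delta = Delta, pulse_model = pulse_model),
    class = "acq_scheme"
  )
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("<acq_scheme>\n")
  cat(sprintf("  b: %s ms/um^2 (%d values)\n",
              paste(signif(utils::head(x$b_values, 6), 3), collapse = ", "),
              length(x$b_values)))
  cat(sprintf("  t_d: %.4g ms, pulse model: %s\n", x$t_d, x$pulse_model))
  if (x$pulse_model == "finite_pulse") {
    cat(sprintf("  delta: %.4g ms, Delta: %.4g ms\n", x$delta, x$Delta))
  }
  invisible(x)
}

#' Default b-value grid
#'
#' The b-grid used throughout the package's simulations: 10 weightings
#' spanning 0.02 to 20 ms/µm², denser at low b where attenuation changes
#' fastest.
#'
#' @return Numeric vector of b-values (ms/µm²).
#' @export
default_b_grid <- function() {
  c(0.02, 1, 2.5, 4, 6, 8.5, 11, 14, 17, 20)
}

# shared argument checks -----------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number.", name),
         call. = FALSE)
  }
  invisible(x)
}

check_b <- function(b) {
  if (!is.numeric(b) || any(!is.finite(b)) || any(b < 0)) {
    stop("`b` must be numeric, finite and nonnegative (ms/um^2).",
         call. = FALSE)
  }
  invisible(b)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1].", name), call. = FALSE)
  }
  invisible(x)
}
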