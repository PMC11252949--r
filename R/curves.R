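# Attenuation-curve tables: validation and normalisation.
#
# Curves live in long tibbles with columns subject_id, group, metabolite,
# b, signal and optionally sd. One curve = one (subject_id, metabolite)
# combination.

curve_cols <- c("subject_id", "group", "metabolite", "b", "signal")

#' Validate an attenuation-curve table
#'
#' Checks the long-format contract used throughout the package: required
#' columns, positive finite signals, no duplicated (subject, metabolite, b)
#' rows, and (optionally) unit normalisation at the lowest b of every curve.
#'
#' @param data A data frame with columns `subject_id`, `group`, `metabolite`,
#'   `b`, `signal` and optionally `sd`.
#' @param normalized If `TRUE`, additionally require signal = 1 at the lowest
#'   b of each curve (tolerance 1e-6).
#' @return The validated data, invisibly as a tibble.
#' @export
validate_curves <- function(data, normalized = FALSE) {
  missing_cols <- setdiff(curve_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("attenuation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(data$b) || !is.numeric(data$signal)) {
    stop("columns `b` and `signal` must be numeric.", call. = FALSE)
  }
  bad <- which(!is.finite(data$signal) | data$signal <= 0 |
                 !is.finite(data$b) | data$b < 0)
  if (length(bad) > 0) {
    stop("non-finite, nonpositive signal or invalid b at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if ("sd" %in% names(data)) {
    bad_sd <- which(!is.na(data$sd) & data$sd < 0)
    if (length(bad_sd) > 0) {
      stop("negative sd at row(s): ",
           paste(utils::head(bad_sd, 5), collapse = ", "), call. = FALSE)
    }
  }
  dup <- duplicated(data[c("subject_id", "metabolite", "b")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf(
      "duplicated (subject_id, metabolite, b) row: subject '%s', metabolite '%s', b = %g (row %d)",
      data$subject_id[i], data$metabolite[i], data$b[i], i), call. = FALSE)
  }
  if (normalized) {
    chk <- data |>
      dplyr::group_by(.data$subject_id, .data$metabolite) |>
      dplyr::summarise(
        s0 = .data$signal[which.min(.data$b)], .groups = "drop")
    off <- chk[abs(chk$s0 - 1) > 1e-6, ]
    if (nrow(off) > 0) {
      stop(sprintf(
        "curve (%s, %s) is not normalised: signal at lowest b is %.6g",
        off$subject_id[1], off$metabolite[1], off$s0[1]), call. = FALSE)
    }
  }
  invisible(tibble::as_tibble(data))
}

#' Normalise attenuation curves to unity at the lowest b
#'
#' Divides each (subject, metabolite) curve by its signal at the lowest
#' measured b, the convention under which all model fitting operates. The
#' `sd` column, when present, is scaled by the same factor.
#'
#' @param data Curve table (see [validate_curves()]).
#' @return A tibble with normalised `signal` (and `sd`).
#' @export
normalize_curves <- function(data) {
  validate_curves(data)
  data |>
    dplyr::group_by(.data$subject_id, .data$metabolite) |>
    dplyr::group_modify(function(d, key) {
      s0 <- d$signal[which.min(d$b)]
      d$signal <- d$signal / s0
      if ("sd" %in% names(d)) d$sd <- d$sd / s0
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::all_of(curve_cols))
}

# expects exactly one curve; returns it sorted by b
single_curve <- function(data, what = "curve") {
  validate_curves(data)
  ids <- unique(data[c("subject_id", "metabolite")])
  if (nrow(ids) != 1) {
    stop(sprintf(
      "expected a single %s (one subject_id x metabolite), got %d; fit per subject or pool first",
      what, nrow(ids)), call. = FALSE)
  }
  dplyr::arrange(data, .data$b)
}

# least-squares weights from an sd column: inverse variance when all sds are
# present and positive, otherwise uniform (degenerate sds would blow up)
fit_weights <- function(data, weights = c("auto", "uniform",
                                          "inverse_variance")) {
  weights <- match.arg(weights)
  n <- nrow(data)
  has_sd <- "sd" %in% names(data) && all(is.finite(data$sd)) &&
    all(data$sd > 0)
  if (weights == "inverse_variance" && !has_sd) {
    stop("inverse-variance weights requested but `sd` is absent, zero or non-finite.",
         call. = FALSE)
  }
  if (weights == "uniform" || (weights == "auto" && !has_sd)) {
    return(rep(1, n))
  }
  w <- 1 / data$sd^2
  w / mean(w)
}
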