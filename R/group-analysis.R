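# Cohort-level statistics: unpaired two-group comparisons and simple
# percent-change arithmetic.

#' Unpaired two-group t test
#'
#' Two-sided unpaired Student's t test computed from first principles
#' (group means, pooled variance, t statistic, p from the t-distribution
#' CDF). Equal variances are assumed by default; `var_equal = FALSE` gives
#' the Welch variant with Satterthwaite degrees of freedom.
#'
#' When both groups have zero variance the test is degenerate: the result
#' carries `degenerate = TRUE` with p = 1 for identical means and p = 0
#' (infinite t, sign of the mean difference) otherwise.
#'
#' @param values_a,values_b Per-animal values, at least 2 per group.
#' @param var_equal Pool the variance (classical Student) or not (Welch).
#' @param labels Length-2 character, group labels for the output.
#' @param quantity Label for what was compared (e.g. `"f_extra"`).
#' @return A one-row tibble: `quantity`, `group_a`, `group_b`, `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`, `t_stat`, `df`, `p_value`,
#'   `method`, `degenerate`.
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE,
                           labels = c("a", "b"), quantity = "value") {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values.", call. = FALSE)
  }
  na <- length(values_a); nb <- length(values_b)
  ma <- mean(values_a); mb <- mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    degenerate <- TRUE
    if (ma == mb) {
      t_stat <- 0; p <- 1; df <- na + nb - 2
    } else {
      t_stat <- sign(ma - mb) * Inf; p <- 0; df <- na + nb - 2
    }
    warning("zero variance in both groups; t test is degenerate",
            call. = FALSE)
  } else if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(t_stat), df)
  } else {
    sa2 <- va / na; sb2 <- vb / nb
    t_stat <- (ma - mb) / sqrt(sa2 + sb2)
    df <- (sa2 + sb2)^2 / (sa2^2 / (na - 1) + sb2^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  tibble::tibble(
    quantity = quantity, group_a = labels[1], group_b = labels[2],
    mean_a = ma, mean_b = mb, sd_a = sqrt(va), sd_b = sqrt(vb),
    n_a = na, n_b = nb, t_stat = t_stat, df = df, p_value = p,
    method = if (var_equal) "student" else "welch",
    degenerate = degenerate)
}

#' Per-b-value group comparison of attenuations
#'
#' Runs [compare_groups()] on the per-animal normalised attenuations of one
#' metabolite at every b, the test behind significance stars on group
#' attenuation plots. No multiple-testing correction is applied; each b is
#' reported marginally.
#'
#' @param data Curve table with exactly two groups.
#' @param metabolite Metabolite to test.
#' @param var_equal As in [compare_groups()].
#' @return A tibble with one row per b value.
#' @export
compare_attenuation_by_b <- function(data, metabolite = "Lac",
                                     var_equal = TRUE) {
  validate_curves(data)
  d <- dplyr::filter(data, .data$metabolite == !!metabolite)
  gs <- unique(d$group)
  if (length(gs) != 2) {
    stop("need exactly two groups, got: ", paste(gs, collapse = ", "),
         call. = FALSE)
  }
  d |>
    dplyr::group_by(.data$b) |>
    dplyr::group_modify(function(dd, key) {
      compare_groups(dd$signal[dd$group == gs[1]],
                     dd$signal[dd$group == gs[2]],
                     var_equal = var_equal, labels = gs,
                     quantity = paste0("S(", signif(key$b, 3), ")"))
    }) |>
    dplyr::ungroup()
}

#' Percent decrease of a quantity relative to a reference
#'
#' `100 * (reference - test) / reference`; an increase comes out negative.
#'
#' @param reference Reference (e.g. control) value; must be nonzero.
#' @param test Test (e.g. disease-group) value.
#' @return Percent decrease.
#' @examples
#' percent_decrease(36, 23) # ~ one third
#' @export
percent_decrease <- function(reference, test) {
  if (any(reference == 0)) {
    stop("`reference` must be nonzero.", call. = FALSE)
  }
  100 * (reference - test) / reference
}
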