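# Three-step pipeline: pool -> microstructure fit -> intracellular lactate
# prediction -> two-pool fit -> group statistics.

#' Run the full lactate compartmentation pipeline
#'
#' Executes the three modeling steps in order on a cohort of attenuation
#' curves: (i) pool NAA + Ins per animal and fit the sticks-and-spheres
#' microstructure; (ii) predict each animal's intracellular lactate
#' attenuation after scaling the fitted diffusivity by `lambda`; (iii) fit
#' the two-pool model to each animal's lactate curve. When the cohort
#' contains exactly two groups, per-animal `f_extra` and `D_extra`
#' estimates are compared with an unpaired t test.
#'
#' @param data Curve table containing `NAA`, `Ins` and `Lac` curves for at
#'   least one subject (see [validate_curves()]); signals should already be
#'   normalised (as [read_attenuation_table()] and [generate_cohort()]
#'   produce).
#' @param scheme An [acq_scheme()]; defaults to the union of b values found
#'   in the data at t_d = 53.2 ms.
#' @param lambda Lactate free-diffusivity scaling (default 1.3).
#' @param micro_level `"subject"` (default) fits the microstructure per
#'   animal; `"group"` fits one microstructure per group on the
#'   across-animal mean pooled curve and shares it within the group.
#' @param f_sphere,model,weights,bounds As in [fit_microstructure()].
#' @param n_boot Bootstrap draws for per-fit confidence intervals
#'   (default 200; set 0 to skip, e.g. in large simulation loops).
#' @param var_equal Equal-variance t test (default) or Welch.
#' @param seed Seed for bootstrap resampling (the fits themselves are
#'   deterministic).
#' @return A `pipeline_result` with elements `micro` (per-subject tibble),
#'   `two_pool` (per-subject tibble), `summary` (per-group mean ± SD of
#'   every parameter), `comparison` (t tests on `f_extra` and `D_extra`, or
#'   `NULL` with one group), `s_intra_lac` (per-subject predicted
#'   intracellular lactate curves) and `meta` (lambda, seed, config hash,
#'   package version).
#' @examples
#' curves <- generate_cohort(cohort_config(n_per_group = 2, seed = 3))
#' res <- run_pipeline(curves, n_boot = 0)
#' res$summary
#' @export
run_pipeline <- function(data, scheme = NULL, lambda = 1.3,
                         micro_level = c("subject", "group"),
                         f_sphere = NULL,
                         model = c("sticks_spheres", "cylinders"),
                         weights = "auto", bounds = NULL,
                         n_boot = 200, var_equal = TRUE, seed = 1L) {
  micro_level <- match.arg(micro_level)
  model <- match.arg(model)
  validate_curves(data)
  mets <- unique(data$metabolite)
  needed <- c("NAA", "Ins", "Lac")
  missing_mets <- setdiff(needed, mets)
  if (length(missing_mets) > 0) {
    stage <- if (identical(missing_mets, "Lac")) {
      "iii (fit two-pool)"
    } else {
      "i (pool intracellular)"
    }
    stop("pipeline stage ", stage, ": cohort is missing metabolite(s): ",
         paste(missing_mets, collapse = ", "), call. = FALSE)
  }
  if (is.null(scheme)) {
    scheme <- acq_scheme(sort(unique(data$b)))
  }

  # stage i: pooling + microstructure
  pooled <- pipeline_stage("i (pool intracellular)", NULL,
                           pool_intracellular(data))
  micro_fits <- if (micro_level == "subject") {
    fits <- pooled |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_split() |>
      purrr::map(function(d) {
        pipeline_stage("i (fit microstructure)", d$subject_id[1],
                       fit_microstructure(
                         d, scheme, f_sphere = f_sphere, model = model,
                         weights = weights, bounds = bounds,
                         n_boot = n_boot, seed = seed))
      })
    names(fits) <- vapply(fits, function(f) f$data$subject_id[1],
                          character(1))
    fits
  } else {
    # one fit per group on the across-animal mean pooled curve
    by_group <- pooled |>
      dplyr::group_by(.data$group, .data$b) |>
      dplyr::summarise(sd = stats::sd(.data$signal),
                       signal = mean(.data$signal), .groups = "drop") |>
      dplyr::mutate(subject_id = paste0("group:", .data$group),
                    metabolite = "pooled")
    fits <- by_group |>
      dplyr::group_by(.data$group) |>
      dplyr::group_split() |>
      purrr::map(function(d) {
        pipeline_stage("i (fit microstructure)", d$group[1],
                       fit_microstructure(
                         d, scheme, f_sphere = f_sphere, model = model,
                         weights = weights, bounds = bounds,
                         n_boot = n_boot, seed = seed))
      })
    names(fits) <- vapply(fits, function(f) f$data$group[1], character(1))
    fits
  }

  subj_tbl <- dplyr::distinct(data, .data$subject_id, .data$group)
  micro_tbl <- purrr::imap_dfr(micro_fits, function(f, nm) {
    tibble::tibble(unit = nm, !!!as.list(f$par), cost = f$cost,
                   any_at_bound = any(f$at_bound))
  })

  # stages ii + iii per subject
  two_pool <- list()
  s_intra_all <- list()
  for (si in seq_len(nrow(subj_tbl))) {
    id <- subj_tbl$subject_id[si]
    grp <- subj_tbl$group[si]
    mf <- if (micro_level == "subject") micro_fits[[id]] else
      micro_fits[[grp]]
    lac <- dplyr::filter(data, .data$subject_id == id,
                         .data$metabolite == "Lac")
    s_i <- pipeline_stage("ii (predict intracellular lactate)", id,
                          predict_intracellular_lactate(
                            mf, scheme, b_grid = sort(lac$b),
                            lambda = lambda))
    tp <- pipeline_stage("iii (fit two-pool)", id,
                         fit_two_pool(lac, s_i, weights = weights,
                                      n_boot = n_boot, seed = seed))
    s_i$subject_id <- id
    s_i$group <- grp
    s_intra_all[[id]] <- s_i
    two_pool[[id]] <- tibble::tibble(
      subject_id = id, group = grp, !!!as.list(tp$par), cost = tp$cost,
      any_at_bound = any(tp$at_bound))
  }
  two_pool <- dplyr::bind_rows(two_pool)

  # per-group summaries and group comparison
  micro_long <- if (micro_level == "subject") {
    dplyr::left_join(micro_tbl, subj_tbl,
                     by = c(unit = "subject_id")) |>
      dplyr::rename(subject_id = "unit")
  } else {
    dplyr::rename(micro_tbl, group = "unit")
  }
  summary_tbl <- dplyr::bind_rows(
    summarise_params(micro_long,
                     intersect(c("D_intra", "r_soma", "f_sphere"),
                               names(micro_long))),
    summarise_params(two_pool, c("f_extra", "D_extra")))

  comparison <- NULL
  gs <- unique(subj_tbl$group)
  if (length(gs) == 2 && all(table(subj_tbl$group) >= 2)) {
    comparison <- dplyr::bind_rows(lapply(c("f_extra", "D_extra"),
      function(q) {
        compare_groups(two_pool[[q]][two_pool$group == gs[1]],
                       two_pool[[q]][two_pool$group == gs[2]],
                       var_equal = var_equal, labels = gs, quantity = q)
      }))
  }

  cfg <- list(lambda = lambda, micro_level = micro_level,
              f_sphere = f_sphere, model = model, weights = weights,
              bounds = bounds, n_boot = n_boot, var_equal = var_equal,
              seed = seed, b_values = scheme$b_values, t_d = scheme$t_d)
  structure(
    list(micro = micro_long, two_pool = two_pool, summary = summary_tbl,
         comparison = comparison,
         s_intra_lac = dplyr::bind_rows(s_intra_all),
         micro_fits = micro_fits,
         meta = list(
           lambda = lambda, seed = seed, config = cfg,
           config_hash = rlang::hash(cfg),
           package_version = as.character(utils::packageVersion("dmrslac")),
           units = list(b = "ms/um^2", D = "um^2/ms", r = "um",
                        t = "ms"))),
    class = "pipeline_result")
}

pipeline_stage <- function(stage, unit, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage %s failed%s: %s", stage,
                 if (is.null(unit)) "" else paste0(" for '", unit, "'"),
                 conditionMessage(e)), call. = FALSE)
  })
}

summarise_params <- function(tbl, params) {
  tbl |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter") |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d subject(s), lambda = %.2f, config %s\n",
              nrow(x$two_pool), x$meta$lambda, x$meta$config_hash))
  print(x$summary)
  if (!is.null(x$comparison)) {
    cat("group comparison:\n")
    print(dplyr::select(x$comparison, "quantity", "mean_a", "mean_b",
                        "t_stat", "p_value"))
  }
  invisible(x)
}

#' Tidy a pipeline result
#'
#' @param x A `pipeline_result` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-group parameter summary (mean, SD, n per parameter).
#' @export
tidy.pipeline_result <- function(x, ...) x$summary

#' Glance at a pipeline result
#'
#' @inheritParams tidy.pipeline_result
#' @return One-row tibble: subject count, lambda, f_extra p-value (NA with
#'   a single group), config hash.
#' @export
glance.pipeline_result <- function(x, ...) {
  p <- if (is.null(x$comparison)) NA_real_ else
    x$comparison$p_value[x$comparison$quantity == "f_extra"]
  tibble::tibble(n_subjects = nrow(x$two_pool), lambda = x$meta$lambda,
                 p_f_extra = p, config_hash = x$meta$config_hash)
}

#' Serialise a pipeline result to JSON
#'
#' Writes tables, metadata and units as deterministic JSON: the same data,
#' config and seed produce byte-identical output (no timestamps).
#'
#' @param x A `pipeline_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_result <- function(x, path) {
  stopifnot(inherits(x, "pipeline_result"))
  out <- list(
    micro = x$micro, two_pool = x$two_pool, summary = x$summary,
    comparison = x$comparison, meta = x$meta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
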