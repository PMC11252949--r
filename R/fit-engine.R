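# Shared bounded weighted-least-squares engine with grid multi-start.
#
# All model fits in the package go through multistart_ls(): a fixed start
# grid over the parameter box is scored by residual cost, the best
# `n_local` grid points seed bounded Levenberg-Marquardt refinements
# (minpack.lm::nls.lm), and the lowest-cost solution is returned. The
# procedure is deterministic: no randomness enters the optimisation.

multistart_ls <- function(resid_fn, lower, upper, n_grid = 3, n_local = 5,
                          par_names = names(lower)) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  k <- length(lower)
  axes <- lapply(seq_len(k), function(i) {
    seq(lower[i], upper[i], length.out = n_grid + 2)[2:(n_grid + 1)]
  })
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- par_names
  cost <- apply(grid, 1, function(p) sum(resid_fn(p)^2))
  ord <- order(cost)
  starts <- grid[ord[seq_len(min(n_local, nrow(grid)))], , drop = FALSE]

  fits <- apply(starts, 1, function(p0) {
    tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("model fit failed: no multi-start refinement converged; start-grid costs: ",
         paste(signif(sort(cost)[1:min(5, length(cost))], 4), collapse = ", "),
         call. = FALSE)
  }
  dev <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(dev)]]
  par <- stats::setNames(as.numeric(best$par), par_names)
  span <- upper - lower
  at_bound <- (par - lower < 1e-6 * span) | (upper - par < 1e-6 * span)
  if (any(at_bound)) {
    warning("fitted parameter(s) at bound: ",
            paste(par_names[at_bound], collapse = ", "), call. = FALSE)
  }
  list(par = par, cost = min(dev), at_bound = stats::setNames(at_bound,
                                                              par_names),
       n_starts = nrow(starts), info = best$info)
}

# Residual bootstrap confidence half-widths: refit on fitted + resampled
# residuals, seeded for reproducibility; returns per-parameter half-widths
# (1.96 * bootstrap SD) plus the draws' SDs.
bootstrap_ci <- function(fit_once, fitted, residuals, n_boot, seed) {
  if (n_boot <= 0) return(NULL)
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(i) {
      y_star <- fitted + sample(residuals, replace = TRUE)
      # resampled signals must stay positive to remain a valid attenuation
      y_star <- pmax(y_star, 1e-6)
      tryCatch(fit_once(y_star), error = function(e) NULL)
    })
  })
  draws <- do.call(rbind, Filter(Negate(is.null), draws))
  if (is.null(draws) || nrow(draws) < max(10, n_boot / 4)) {
    warning("residual bootstrap mostly failed; no CIs reported",
            call. = FALSE)
    return(NULL)
  }
  sds <- apply(draws, 2, stats::sd)
  list(half_width = 1.96 * sds, sd = sds, n_ok = nrow(draws))
}
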