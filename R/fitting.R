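#' Fit the input nonlinearity to calibration points
#'
#' Multi-start nonlinear least squares of
#' `f(dI) = f0 + f1/(1 + exp(-r (dI - dI0)))` to (intensity difference, drive
#' strength) pairs. With only five points for four parameters the problem is
#' near-interpolating, so `starts` Latin-hypercube initial guesses within the
#' bounds are refined with L-BFGS-B and the best solution is kept;
#' the procedure is deterministic given `seed`.
#'
#' @param points data.frame with columns `delta_I` and `f`; at least 4
#'   distinct `delta_I` values.
#' @param starts number of optimisation starts.
#' @param seed RNG seed for the start design.
#' @param lower,upper parameter bounds, order `(f0, f1, r, delta_I0)`.
#' @return A [nonlinearity_params()] object with the fitted constants and the
#'   input table; attributes `sse` (residual sum of squares), `converged`,
#'   and `n_starts_converged`.
#' @export
fit_sigmoid <- function(points, starts = 32, seed = 1,
                        lower = c(f0 = 0, f1 = 0, r = 0.05, delta_I0 = 0),
                        upper = c(f0 = 5, f1 = 5, r = 10, delta_I0 = 8)) {
  stopifnot(is.data.frame(points), all(c("delta_I", "f") %in% names(points)))
  x <- points$delta_I; y <- points$f
  if (length(unique(x)) < 4) {
    stop("need at least 4 points with distinct delta_I (4 free parameters)")
  }
  sse <- function(p) {
    pred <- p[1] + p[2] * stats::plogis(p[3] * (x - p[4]))
    sum((pred - y)^2)
  }
  set.seed(seed)
  design <- lhs::randomLHS(starts, 4)
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(starts)) {
    p0 <- lower + design[i, ] * (upper - lower)
    fit <- tryCatch(
      stats::optim(p0, sse, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")
  p <- unname(best$par)
  out <- nonlinearity_params(f0 = p[1], f1 = p[2], r = p[3],
                             delta_I0 = p[4],
                             table = points[order(points$delta_I), ])
  attr(out, "sse") <- best$value
  attr(out, "converged") <- best$convergence == 0
  attr(out, "n_starts_converged") <- n_conv
  out
}

#' Mean-duration curve of the model over intensity differences
#'
#' Thin wrapper over [levelt_curve()] returning just the per-condition mean
#' dominance durations; used both to build synthetic fitting targets and to
#' evaluate candidates inside [fit_model_durations()]. Identical arguments
#' (including `seed`) give identical output.
#'
#' @inheritParams levelt_curve
#' @return data.frame with columns `delta_I`, `mean_SIM`, `mean_AM`.
#' @export
model_duration_curve <- function(delta_I_values, profile, reps = 2,
                                 t_max = 300, seed = 1, dt = 5e-5) {
  lc <- levelt_curve(delta_I_values, nl = profile$nonlinearity, reps = reps,
                     t_max = t_max, seed = seed, profile = profile, dt = dt)
  lc[c("delta_I", "mean_SIM", "mean_AM")]
}

.fit_bounds <- function() {
  list(sigma = c(0.05, 1.5), tau_n = c(0.01, 2), tau_alpha = c(1, 10))
}

.apply_free <- function(profile, free_names, values) {
  for (i in seq_along(free_names)) {
    nm <- free_names[i]; v <- values[i]
    if (nm == "sigma") profile$noise$sigma <- v
    else if (nm == "tau_n") profile$noise$tau_n <- v
    else if (nm == "tau_alpha") profile$first_stage$tau_alpha <- v
    else if (startsWith(nm, "f@")) {
      dI <- as.numeric(sub("^f@", "", nm))
      tab <- profile$nonlinearity$table
      j <- match(dI, tab$delta_I)
      if (is.na(j)) stop("no calibration point at delta_I = ", dI)
      tab$f[j] <- v
      profile$nonlinearity$table <- tab
    } else stop("unknown free parameter: ", nm)
  }
  profile
}

#' Fit model parameters to target duration curves by evolutionary search
#'
#' A small real-coded genetic algorithm (tournament selection of size 3,
#' uniform crossover, Gaussian mutation at 10% of each parameter range,
#' elitism of one) minimising the sum of squared differences between the
#' model's mean-duration curve and a target curve. Free parameters are any of
#' `"sigma"`, `"tau_n"`, `"tau_alpha"`, or individual calibration points
#' `"f@<delta_I>"`. Candidate curves are computed with
#' [model_duration_curve()] using fixed internal seeds, so the loss of the
#' generating parameter set is exactly zero when the same `curve_seed`,
#' `reps` and `t_max` are used. Conditions where a candidate produces no
#' phase of a percept incur a fixed penalty per missing entry.
#'
#' @param target data.frame with columns `delta_I`, `mean_SIM`, `mean_AM`
#'   (at least 2 conditions).
#' @param free character vector of free parameter names.
#' @param budget total number of loss evaluations, `>=` population size.
#' @param seed seed for the evolutionary search.
#' @param profile base profile; free parameters override its entries.
#' @param bounds named list of `c(lower, upper)` per free parameter
#'   (defaults provided for the named scalars; `f@*` defaults to `c(1, 5)`).
#' @param pop_size population size.
#' @param reps,t_max,dt,curve_seed forwarded to [model_duration_curve()].
#' @param penalty loss added per missing (NaN) curve entry.
#' @return List with `par` (named best values), `profile` (with best values
#'   applied), `loss`, `history` (best loss per generation), `n_eval`.
#' @export
fit_model_durations <- function(target, free = c("sigma", "tau_alpha"),
                                budget = 200, seed = 1,
                                profile = model_profile("fig5fit"),
                                bounds = NULL, pop_size = 16,
                                reps = 1, t_max = 200, dt = 5e-5,
                                curve_seed = 99, penalty = 100) {
  stopifnot(is.data.frame(target),
            all(c("delta_I", "mean_SIM", "mean_AM") %in% names(target)))
  if (nrow(target) < 2) stop("target must cover at least 2 conditions")
  if (budget < pop_size) {
    stop(sprintf("budget (%d) must be at least the population size (%d)",
                 budget, pop_size))
  }
  defb <- .fit_bounds()
  lo <- hi <- numeric(length(free))
  for (i in seq_along(free)) {
    b <- if (!is.null(bounds[[free[i]]])) bounds[[free[i]]]
      else if (!is.null(defb[[free[i]]])) defb[[free[i]]]
      else c(1, 5)
    lo[i] <- b[1]; hi[i] <- b[2]
  }
  loss_fun <- function(v) {
    prof <- .apply_free(profile, free, v)
    cur <- model_duration_curve(target$delta_I, prof, reps = reps,
                                t_max = t_max, seed = curve_seed, dt = dt)
    resid <- c(cur$mean_SIM - target$mean_SIM, cur$mean_AM - target$mean_AM)
    bad <- !is.finite(resid)
    sum(resid[!bad]^2) + penalty * sum(bad)
  }
  set.seed(seed)
  pop <- matrix(stats::runif(pop_size * length(free), lo, hi),
                nrow = pop_size, byrow = TRUE)
  fit <- apply(pop, 1, loss_fun)
  n_eval <- pop_size
  history <- min(fit)
  while (n_eval + pop_size <= budget) {
    newpop <- matrix(NA_real_, pop_size, length(free))
    best_i <- which.min(fit)
    newpop[1, ] <- pop[best_i, ]                      # elitism
    for (k in 2:pop_size) {
      pick <- function() {
        cand <- sample.int(pop_size, 3)
        cand[which.min(fit[cand])]
      }
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      mask <- stats::runif(length(free)) < 0.5
      child <- ifelse(mask, pa, pb)
      mut <- stats::rnorm(length(free), 0, 0.1 * (hi - lo))
      child <- pmin(pmax(child + mut, lo), hi)
      newpop[k, ] <- child
    }
    pop <- newpop
    fit <- apply(pop, 1, loss_fun)
    n_eval <- n_eval + pop_size
    history <- c(history, min(fit))
  }
  if (!any(is.finite(fit))) {
    stop("evolutionary search exhausted its budget without a finite loss")
  }
  best_i <- which.min(fit)
  par <- stats::setNames(pop[best_i, ], free)
  list(par = par, profile = .apply_free(profile, free, par),
       loss = fit[best_i], history = cummin(history), n_eval = n_eval)
}
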