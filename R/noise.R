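#' Generate an Ornstein-Uhlenbeck noise path
#'
#' Euler-Maruyama discretisation of the mean-reverting Gaussian process used
#' as the first-stage stochastic drive, starting at `zeta_0 = 0`. Under the
#' default rate convention the update is
#' `zeta <- zeta - tau_n*zeta*dt + sigma*sqrt(2*tau_n*dt)*eta`; under the
#' correlation-time convention `tau_n` divides instead. The stationary
#' standard deviation is `sigma` in both cases, and the autocorrelation decays
#' as `exp(-lag/tau_corr)` with `tau_corr = 1/tau_n` (rate convention) or
#' `tau_n` (time convention).
#'
#' @param np [noise_params()].
#' @param dt time step (s), `> 0`. A warning is raised if the process is
#'   under-resolved (`dt >= tau_corr`).
#' @param n_steps number of steps, `>= 0`.
#' @param seed optional integer seed; if supplied, `set.seed(seed)` is called
#'   so identical arguments give bit-identical paths.
#' @return Numeric vector of length `n_steps + 1` (the path including
#'   `zeta_0`).
#' @export
ou_path <- function(np, dt, n_steps, seed = NULL) {
  stopifnot(inherits(np, "noise_params"), dt > 0, n_steps >= 0)
  tau_corr <- if (np$rate_convention) 1 / np$tau_n else np$tau_n
  if (dt >= tau_corr) {
    warning(sprintf("dt = %g does not resolve the noise correlation time %g",
                    dt, tau_corr))
  }
  if (!is.null(seed)) set.seed(seed)
  .ou_path_cpp(np$sigma, np$tau_n, dt, as.integer(n_steps),
               np$rate_convention)
}

#' Write an OU path to CSV
#'
#' @inheritParams ou_path
#' @param path output file; columns `t`, `zeta`.
#' @return `path`, invisibly.
#' @export
write_ou_path <- function(np, dt, n_steps, path, seed = NULL) {
  z <- ou_path(np, dt, n_steps, seed = seed)
  utils::write.csv(data.frame(t = dt * (0:n_steps), zeta = z), path,
                   row.names = FALSE)
  invisible(path)
}
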