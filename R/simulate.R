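.cpp_pars <- function(p1, p2) {
  list(w = p1$w, g = p1$g, tau_nu = p1$tau_nu, tau_alpha = p1$tau_alpha,
       x0 = p1$x0, k_A = p1$k_A, nu0 = p1$nu0,
       w_pool = p1$w_pool, adapt_pool = p1$adapt_pool,
       a = p2$a, b = p2$b, c = p2$c, d = p2$d, tau = p2$tau,
       tau_i = p2$tau_i, theta = p2$theta, alpha_x = p2$alpha_x,
       beta_x = p2$beta_x, theta_s = p2$theta_s, k_H = p2$k_H,
       heaviside = p2$heaviside)
}

#' Integrate the tactile rivalry model
#'
#' Euler-Maruyama integration of the full (ten-variable) or simplified
#' (eight-variable) model with Ornstein-Uhlenbeck noise, stepping at `dt` and
#' storing every `store_dt`. All rate-like variables remain in `[0, 1]`
#' exactly for `dt <= tau` because each update is a convex combination.
#'
#' @param model `"full"` or `"simplified"`.
#' @param stim [stimulus_params()]; its `delta_I` selects the drive strength
#'   through the profile's nonlinearity.
#' @param profile parameter profile from [model_profile()] (or an equivalent
#'   list); noise settings may be overridden with `noise`.
#' @param t_max simulated time (s), `> 0`.
#' @param dt integration step (s); the published step is 1e-5 s, and 5e-5 s
#'   remains 20x below the fastest timescale (see vignette for the
#'   convergence check).
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @param D constant first-stage drive for the simplified model; defaults to
#'   `f(delta_I)` from the profile's nonlinearity.
#' @param noise optional [noise_params()] overriding the profile's.
#' @param init optional named initial state (defaults to all zero, the
#'   convention that makes the first percept SIM).
#' @param store_dt storage stride (s), a multiple of `dt`; default 1 ms.
#' @param clamp_nu optionally clamp both first-stage rates to a constant (used
#'   to probe the percept encoding); `NULL` for normal dynamics.
#' @param drive_mode,drive_offset,input_smoothing,f_mode,nu_weight model
#'   conventions, see [full_drift()] and [simplified_drift()].
#' @param burn_in transient (s) excluded from downstream percept statistics
#'   (recorded in the trajectory metadata; the data are stored from `t = 0`).
#' @return A `trajectory`: a data.frame of stored time points (columns `t`,
#'   the state variables, `zeta`, `i_R`, `i_L`) with a `meta` attribute
#'   holding all effective parameters.
#' @export
simulate_model <- function(model = c("full", "simplified"),
                           stim = stimulus_params(2),
                           profile = model_profile("table1"),
                           t_max = 90, dt = 1e-5, seed = NULL,
                           D = NULL, noise = NULL, init = NULL,
                           store_dt = 1e-3, clamp_nu = NULL,
                           drive_mode = "collapsed", drive_offset = 1,
                           input_smoothing = "sigmoid_centered",
                           f_mode = "auto", nu_weight = 2, burn_in = 2) {
  model <- match.arg(model)
  stopifnot(t_max > 0, dt > 0, store_dt >= dt)
  p1 <- profile$first_stage; p2 <- profile$second_stage
  nl <- profile$nonlinearity
  nz <- if (is.null(noise)) profile$noise else noise
  if (dt > p2$tau / 10) {
    warning(sprintf("dt = %g exceeds tau/10 = %g; dynamics under-resolved",
                    dt, p2$tau / 10))
  }
  stride <- as.integer(round(store_dt / dt))
  if (abs(stride * dt - store_dt) > 1e-12 * max(1, store_dt)) {
    stop("store_dt must be an integer multiple of dt")
  }
  fv <- .f_auto(nl, stim$delta_I)
  if (!is.null(seed)) set.seed(seed)

  if (model == "full") {
    x0 <- rep(0, 10)
    names(x0) <- c("nu_R", "nu_L", "alpha_R", "alpha_L", "u_R", "u_L",
                   "y_R", "y_L", "x_R", "x_L")
    if (!is.null(init)) x0[names(init)] <- init
    .check_unit_interval(x0)
    res <- .sim_full_cpp(.cpp_pars(p1, p2), stim$delta_I, stim$TD, stim$TR,
                         fv, .smooth_mode_code(drive_mode), drive_offset,
                         .smooth_mode_code(input_smoothing),
                         stim$smoothing_slope,
                         nz$sigma, nz$tau_n, nz$shared, nz$rate_convention,
                         t_max, dt, stride, unname(x0),
                         if (is.null(clamp_nu)) NA_real_ else clamp_nu)
  } else {
    if (is.null(D)) D <- fv
    stopifnot(D >= 0)
    x0 <- rep(0, 8)
    names(x0) <- c("nu", "alpha", "u_R", "u_L", "y_R", "y_L", "x_R", "x_L")
    if (!is.null(init)) x0[names(init)] <- init
    .check_unit_interval(x0)
    res <- .sim_simplified_cpp(.cpp_pars(p1, p2), D, nu_weight,
                               stim$delta_I, stim$TD, stim$TR,
                               .smooth_mode_code(input_smoothing),
                               stim$smoothing_slope,
                               nz$sigma, nz$tau_n, nz$rate_convention,
                               t_max, dt, stride, unname(x0))
  }
  traj <- as.data.frame(res$states)
  meta <- list(model = model, stim = stim, profile_name = profile$profile,
               first_stage = p1, second_stage = p2, noise = nz,
               nonlinearity = nl, f_value = fv,
               D = if (model == "simplified") D else NULL,
               nu_weight = if (model == "simplified") nu_weight else NULL,
               t_max = t_max, dt = dt, store_dt = store_dt, seed = seed,
               drive_mode = drive_mode, drive_offset = drive_offset,
               input_smoothing = input_smoothing, f_mode = f_mode,
               clamp_nu = clamp_nu, burn_in = burn_in)
  attr(traj, "meta") <- meta
  class(traj) <- c("trajectory", "data.frame")
  traj
}

.check_unit_interval <- function(x) {
  if (any(x < 0 | x > 1)) stop("initial state variables must lie in [0, 1]")
}

#' @export
print.trajectory <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<trajectory: %s model, %d stored points, t_max = %g s, dt = %g s>\n",
              m$model, nrow(x), m$t_max, m$dt))
  cat(sprintf("  delta_I = %g dB, f = %.3g, sigma = %g, tau_n = %g, seed = %s\n",
              m$stim$delta_I, m$f_value, m$noise$sigma, m$noise$tau_n,
              if (is.null(m$seed)) "none" else m$seed))
  invisible(x)
}

#' Write / read a trajectory as annotated CSV
#'
#' The seed, model variant and effective parameters are embedded as `#`
#' comment lines so every output references what regenerates it.
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the data.frame with a `header` attribute of the annotation
#'   lines (full metadata is not reconstructed).
#' @export
write_trajectory <- function(traj, path) {
  m <- attr(traj, "meta")
  hdr <- c(sprintf("# model: %s", m$model),
           sprintf("# profile: %s", m$profile_name),
           sprintf("# delta_I: %g", m$stim$delta_I),
           sprintf("# f_value: %.10g", m$f_value),
           sprintf("# sigma: %g", m$noise$sigma),
           sprintf("# tau_n: %g", m$noise$tau_n),
           sprintf("# dt: %g", m$dt),
           sprintf("# seed: %s", if (is.null(m$seed)) "NA" else m$seed),
           sprintf("# drive_mode: %s", m$drive_mode),
           sprintf("# input_smoothing: %s", m$input_smoothing))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- lines[startsWith(lines, "#")]
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "header") <- hdr
  df
}
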