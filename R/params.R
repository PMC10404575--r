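#' First-stage (adapting recurrent population) parameters
#'
#' Constants of the two adapting recurrent units that generate UP/DOWN
#' alternations. Defaults are the published reference values of the tactile
#' rivalry model (recurrent excitation `w`, adaptation strength `g`, rate and
#' adaptation timescales, activation threshold `x0`, and the adaptation
#' sigmoid's slope `k_A` and midpoint `nu0`).
#'
#' Two reconstruction switches control how the pair of units is wired:
#' `adapt_pool = TRUE` drives adaptation by the population-mean rate
#' \eqn{(\nu_R+\nu_L)/2} (under the symmetric collapse this reduces exactly to
#' the one-unit model's \eqn{A(\nu)}); `FALSE` uses each unit's own rate.
#' `w_pool` mixes recurrent excitation across the two units
#' (\eqn{w[(1-\chi)\nu_j + \chi\nu_{\bar j}]}); 0 is pure self-excitation.
#'
#' @param w recurrent excitation strength.
#' @param g adaptation strength.
#' @param tau_nu firing-rate timescale (s).
#' @param tau_alpha adaptation timescale (s).
#' @param x0 activation threshold of the rate sigmoid `N`.
#' @param k_A slope of the adaptation sigmoid `A`.
#' @param nu0 midpoint of the adaptation sigmoid `A`.
#' @param adapt_pool logical; adaptation driven by the population-mean rate.
#' @param w_pool cross-unit mixing fraction of recurrent excitation in
#'   `[0, 1]`.
#' @return An object of class `first_stage_params` (a named list).
#' @export
first_stage_params <- function(w = 6, g = 1.5, tau_nu = 0.9, tau_alpha = 4.5,
                               x0 = 5, k_A = 15, nu0 = 0.5,
                               adapt_pool = TRUE, w_pool = 0) {
  stopifnot(tau_nu > 0, tau_alpha > 0, w >= 0, g >= 0, k_A > 0,
            w_pool >= 0, w_pool <= 1)
  structure(list(w = w, g = g, tau_nu = tau_nu, tau_alpha = tau_alpha,
                 x0 = x0, k_A = k_A, nu0 = nu0,
                 adapt_pool = isTRUE(adapt_pool), w_pool = w_pool),
            class = "first_stage_params")
}

#' Second-stage (percept-encoding) parameters
#'
#' Constants of the two mutually coupled percept units: fast cross excitation
#' `a`, delayed slowly decaying cross inhibition `b` with decay timescale
#' `tau_i`, stimulus drive strength `c`, feed-forward inhibition `d` from the
#' first stage, rate timescale `tau`, threshold `theta`, and the
#' indirect-synapse gate (`alpha_x`, `beta_x`, `theta_s`) that realises the
#' nominal inhibition onset delay `delta` as ordinary differential equations.
#'
#' The gate's closed-form onset delay,
#' \deqn{t^* = -\log(1 - \theta_s(\alpha_x+\beta_x)/\alpha_x)/(\alpha_x+\beta_x),}
#' must agree with `delta` to within 20% or construction fails; with the
#' defaults it is 5.08 ms against a nominal 5 ms.
#'
#' @param a cross-excitation strength.
#' @param b delayed-inhibition strength.
#' @param c_input stimulus input strength (the model's `c`).
#' @param d first-to-second-stage inhibition strength.
#' @param tau second-stage rate timescale (s).
#' @param tau_i inhibition decay timescale (s).
#' @param theta activation threshold.
#' @param delta nominal inhibition onset delay (s).
#' @param alpha_x gate rise rate (1/s).
#' @param beta_x gate decay rate (1/s).
#' @param theta_s gate threshold in (0, 1).
#' @param k_H slope of the steep sigmoid `S` replacing the Heaviside gain.
#' @param heaviside logical; use the exact Heaviside step instead of `S`
#'   (mainly for unit tests).
#' @return An object of class `second_stage_params`.
#' @export
second_stage_params <- function(a = 3.4, b = 2.8, c_input = 5.5, d = 2.6,
                                tau = 0.001, tau_i = 0.25, theta = 0.5,
                                delta = 0.005, alpha_x = 50, beta_x = 8,
                                theta_s = 0.22, k_H = 20, heaviside = FALSE) {
  stopifnot(tau > 0, tau_i > 0, alpha_x > 0, beta_x > 0,
            theta_s > 0, theta_s < 1, k_H > 0)
  t_star <- gate_onset_delay(alpha_x, beta_x, theta_s)
  if (!is.finite(t_star) || abs(t_star - delta) > 0.2 * delta) {
    stop(sprintf(paste0("gate onset delay %.4g s from (alpha_x, beta_x, ",
                        "theta_s) is inconsistent with delta = %.4g s ",
                        "(must agree within 20%%)"), t_star, delta))
  }
  structure(list(a = a, b = b, c = c_input, d = d, tau = tau, tau_i = tau_i,
                 theta = theta, delta = delta, alpha_x = alpha_x,
                 beta_x = beta_x, theta_s = theta_s, k_H = k_H,
                 heaviside = isTRUE(heaviside)),
            class = "second_stage_params")
}

#' Closed-form onset delay of the indirect-synapse gate
#'
#' Time for the gate variable `y`, driven at full presynaptic activation from
#' `y = 0`, to reach the threshold `theta_s`:
#' \eqn{-\log(1-\theta_s(\alpha_x+\beta_x)/\alpha_x)/(\alpha_x+\beta_x)}.
#'
#' @param alpha_x gate rise rate (1/s).
#' @param beta_x gate decay rate (1/s).
#' @param theta_s gate threshold.
#' @return Delay in seconds (`NaN` if the gate never reaches threshold).
#' @export
gate_onset_delay <- function(alpha_x, beta_x, theta_s) {
  r <- alpha_x + beta_x
  arg <- 1 - theta_s * r / alpha_x
  if (arg <= 0) return(NaN)
  -log(arg) / r
}

#' Ornstein-Uhlenbeck noise parameters
#'
#' The stochastic drive shared by the first-stage units. With
#' `rate_convention = TRUE` (default) the process follows the model equation
#' as printed, \eqn{d\zeta = -\tau_n \zeta\, dt + \sigma\sqrt{2\tau_n dt}\,
#' W_t}, so `tau_n` acts as a decay rate and the correlation time is
#' `1/tau_n`. With `FALSE`, `tau_n` is read as the correlation time
#' (decay rate `1/tau_n`). Either way the stationary standard deviation is
#' `sigma`.
#'
#' @param sigma stationary standard deviation.
#' @param tau_n noise timescale parameter (see Details).
#' @param shared logical; one path fed to both first-stage units (default) or
#'   independent paths.
#' @param rate_convention logical; interpret `tau_n` as a rate (default) or a
#'   correlation time.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma = 1, tau_n = 0.05, shared = TRUE,
                         rate_convention = TRUE) {
  stopifnot(sigma >= 0, tau_n > 0)
  structure(list(sigma = sigma, tau_n = tau_n, shared = isTRUE(shared),
                 rate_convention = isTRUE(rate_convention)),
            class = "noise_params")
}

#' Packaged model parameter profiles
#'
#' Three reference configurations:
#' \describe{
#'   \item{`table1`}{the published reference parameter set
#'     (adaptation timescale 4.5 s, noise `sigma = 1`, `tau_n = 0.05`).}
#'   \item{`fig5fit`}{the optimisation-stage profile used for the
#'     duration-statistics and input-strength results: adaptation timescale
#'     5 s, `sigma = 0.3`, `tau_n = 0.05`, all other constants as `table1`.}
#'   \item{`fig3_simplified`}{the noise-driven simplified-model demonstration:
#'     adaptation disabled (`g = 0`), `sigma = 0.79`, `tau_n = 0.98`.}
#' }
#'
#' @param name profile name.
#' @return A list with elements `first_stage`, `second_stage`, `noise`,
#'   `nonlinearity` and `profile` (the name).
#' @export
model_profile <- function(name = c("table1", "fig5fit", "fig3_simplified")) {
  name <- match.arg(name)
  p1 <- first_stage_params()
  p2 <- second_stage_params()
  nz <- noise_params()
  if (name == "fig5fit") {
    p1$tau_alpha <- 5
    nz$sigma <- 0.3
  } else if (name == "fig3_simplified") {
    p1$g <- 0
    nz$sigma <- 0.79
    nz$tau_n <- 0.98
  }
  list(first_stage = p1, second_stage = p2, noise = nz,
       nonlinearity = nonlinearity_params(), profile = name)
}

# flat key-value view used for config round-trips; names follow the
# published parameter table exactly
.flat_param_names <- c("w", "g", "tau_nu", "tau_alpha", "x0", "k_A", "nu0",
                       "a", "b", "c", "d", "tau", "tau_i", "theta", "delta",
                       "alpha_x", "beta_x", "theta_s", "sigma", "tau_n")

#' Flatten a model profile to the published key-value naming
#'
#' @param profile a list as returned by [model_profile()].
#' @return Named list of the 20 scalar constants.
#' @export
flatten_params <- function(profile) {
  p1 <- profile$first_stage; p2 <- profile$second_stage; nz <- profile$noise
  out <- list(w = p1$w, g = p1$g, tau_nu = p1$tau_nu,
              tau_alpha = p1$tau_alpha, x0 = p1$x0, k_A = p1$k_A,
              nu0 = p1$nu0, a = p2$a, b = p2$b, c = p2$c, d = p2$d,
              tau = p2$tau, tau_i = p2$tau_i, theta = p2$theta,
              delta = p2$delta, alpha_x = p2$alpha_x, beta_x = p2$beta_x,
              theta_s = p2$theta_s, sigma = nz$sigma, tau_n = nz$tau_n)
  out[.flat_param_names]
}

#' Write/read a flat parameter configuration
#'
#' Round-trips the 20 scalar model constants through a flat YAML key-value
#' file. Unknown keys in a file are an error.
#'
#' @param profile list as returned by [model_profile()].
#' @param path file path.
#' @return `read_params_config` returns a profile list; the writer returns
#'   `path` invisibly.
#' @export
write_params_config <- function(profile, path) {
  yaml::write_yaml(flatten_params(profile), path, precision = 15)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .flat_param_names)
  if (length(unknown) > 0) {
    stop("unknown parameter key(s) in config: ", paste(unknown, collapse = ", "))
  }
  prof <- model_profile("table1")
  v <- function(key, default) if (!is.null(vals[[key]])) vals[[key]] else default
  p1 <- prof$first_stage
  for (k in c("w", "g", "tau_nu", "tau_alpha", "x0", "k_A", "nu0"))
    p1[[k]] <- v(k, p1[[k]])
  p2 <- prof$second_stage
  for (k in c("a", "b", "c", "d", "tau", "tau_i", "theta", "delta",
              "alpha_x", "beta_x", "theta_s"))
    p2[[k]] <- v(k, p2[[k]])
  nz <- prof$noise
  nz$sigma <- v("sigma", nz$sigma)
  nz$tau_n <- v("tau_n", nz$tau_n)
  list(first_stage = p1, second_stage = p2, noise = nz,
       nonlinearity = prof$nonlinearity, profile = "custom")
}
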