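#' Logistic activation
#'
#' The shared sigmoid building block `1/(1 + exp(-slope*(x - center)))`,
#' overflow-safe for large `|x|`. The model's three gain functions are
#' special cases: the rate activation `N` (`center = x0`, `slope = 1`), the
#' steep Heaviside replacement `S` (`center = 0`, `slope = k_H`), and the
#' adaptation sigmoid `A` (`center = nu0`, `slope = k_A`).
#'
#' @param x input (vectorised).
#' @param center midpoint.
#' @param slope slope, `> 0`.
#' @return Values in (0, 1).
#' @export
sigmoid_activation <- function(x, center = 0, slope = 1) {
  stopifnot(slope > 0)
  stats::plogis(slope * (x - center))
}

.N <- function(x, p1) stats::plogis(x - p1$x0)
.A <- function(nu, p1) stats::plogis(p1$k_A * (nu - p1$nu0))
.S <- function(x, p2) {
  if (isTRUE(p2$heaviside)) as.numeric(x >= 0) else stats::plogis(p2$k_H * x)
}

# second-stage input levels at time t given the smoothing convention
.u_inputs <- function(stim, t, input_smoothing) {
  lev <- .raw_levels(stim, t)
  k <- stim$smoothing_slope
  if (input_smoothing == "ideal") lev
  else list(i_R = .apply_smoothing(lev$i_R, input_smoothing, k),
            i_L = .apply_smoothing(lev$i_L, input_smoothing, k))
}

# stage-1 drive pair (R, L) at time t: symmetric component drive_offset*f
# plus the antiphase component under drive_mode
.stage1_drive <- function(stim, fv, t, drive_mode, drive_offset) {
  dI <- stim$delta_I
  base <- drive_offset * fv
  if (drive_mode == "collapsed" || dI == 0) return(c(base, base))
  lev <- .raw_levels(stim, t)
  k <- stim$smoothing_slope
  if (drive_mode != "ideal") {
    lev$i_R <- .apply_smoothing(lev$i_R, drive_mode, k)
    lev$i_L <- .apply_smoothing(lev$i_L, drive_mode, k)
  }
  eps <- fv * (lev$i_L - lev$i_R) / dI
  c(base + eps, base - eps)
}

#' Deterministic drift of the full two-stage model
#'
#' Right-hand side of the ten coupled rate equations (noise value supplied,
#' not generated). For each side `j` with opposite side `o`:
#' \deqn{\tau_\nu \dot\nu_j = -\nu_j + N(w[(1-\chi)\nu_j + \chi\nu_o]
#'   - g\,\alpha_j + drive_j + \zeta)}
#' \deqn{\tau_\alpha \dot\alpha_j = -\alpha_j + A(\cdot)}
#' \deqn{\tau \dot u_j = -u_j + S(a u_o - b x_o - d(\nu_R+\nu_L) + c\,i_j
#'   - \theta)}
#' \deqn{\dot y_j = \alpha_x (1-y_j) S(u_j-\theta) - \beta_x y_j, \qquad
#'   \tau_i \dot x_j = -x_j + S(y_j - \theta_s)}
#' where the adaptation argument is the population-mean rate when
#' `p1$adapt_pool` is `TRUE` (default) and `nu_j` otherwise, and `drive_j`
#' combines the cycle-symmetric component `drive_offset * f(delta_I)` with the
#' antiphase component selected by `drive_mode` (see the vignette; `"ideal"`
#' with `drive_offset = 0` is the verbatim published form, `"collapsed"` the
#' default symmetric reduction).
#'
#' @param state named numeric vector `nu_R, nu_L, alpha_R, alpha_L, u_R, u_L,
#'   y_R, y_L, x_R, x_L`, each in `[0, 1]`.
#' @param t time (s).
#' @param stim [stimulus_params()].
#' @param nl [nonlinearity_params()].
#' @param p1 [first_stage_params()].
#' @param p2 [second_stage_params()].
#' @param zeta noise value(s); length 1 (shared) or 2 (`R`, `L`).
#' @param drive_mode antiphase drive treatment: `"collapsed"`, `"ideal"`,
#'   `"sigmoid_printed"`, `"sigmoid_centered"`.
#' @param drive_offset gain of the symmetric drive component (default 1).
#' @param input_smoothing second-stage input treatment (same choices as the
#'   stimulus smoothing; default centered sigmoid).
#' @param f_mode forwarded to the nonlinearity evaluation, see
#'   [first_stage_drive()].
#' @return Named vector of time derivatives (same names as `state`).
#' @export
full_drift <- function(state, t, stim, nl, p1, p2, zeta = 0,
                       drive_mode = c("collapsed", "ideal", "sigmoid_printed",
                                      "sigmoid_centered"),
                       drive_offset = 1,
                       input_smoothing = c("sigmoid_centered", "ideal",
                                           "sigmoid_printed"),
                       f_mode = "auto") {
  drive_mode <- match.arg(drive_mode)
  input_smoothing <- match.arg(input_smoothing)
  if (any(!is.finite(state))) stop("non-finite state")
  s <- as.list(state)
  zR <- zeta[1]; zL <- if (length(zeta) > 1) zeta[2] else zeta[1]
  fv <- if (stim$delta_I == 0) .f_auto(nl, 0) else .f_auto(nl, stim$delta_I)
  drv <- .stage1_drive(stim, fv, t, drive_mode, drive_offset)
  ui <- .u_inputs(stim, t, input_smoothing)

  excR <- p1$w * ((1 - p1$w_pool) * s$nu_R + p1$w_pool * s$nu_L)
  excL <- p1$w * ((1 - p1$w_pool) * s$nu_L + p1$w_pool * s$nu_R)
  aR_in <- if (p1$adapt_pool) (s$nu_R + s$nu_L) / 2 else s$nu_R
  aL_in <- if (p1$adapt_pool) (s$nu_R + s$nu_L) / 2 else s$nu_L
  inh <- p2$d * (s$nu_R + s$nu_L)

  c(nu_R = (-s$nu_R + .N(excR - p1$g * s$alpha_R + drv[1] + zR, p1)) / p1$tau_nu,
    nu_L = (-s$nu_L + .N(excL - p1$g * s$alpha_L + drv[2] + zL, p1)) / p1$tau_nu,
    alpha_R = (-s$alpha_R + .A(aR_in, p1)) / p1$tau_alpha,
    alpha_L = (-s$alpha_L + .A(aL_in, p1)) / p1$tau_alpha,
    u_R = (-s$u_R + .S(p2$a * s$u_L - p2$b * s$x_L - inh +
                         p2$c * ui$i_R - p2$theta, p2)) / p2$tau,
    u_L = (-s$u_L + .S(p2$a * s$u_R - p2$b * s$x_R - inh +
                         p2$c * ui$i_L - p2$theta, p2)) / p2$tau,
    y_R = p2$alpha_x * (1 - s$y_R) * .S(s$u_R - p2$theta, p2) -
      p2$beta_x * s$y_R,
    y_L = p2$alpha_x * (1 - s$y_L) * .S(s$u_L - p2$theta, p2) -
      p2$beta_x * s$y_L,
    x_R = (-s$x_R + .S(s$y_R - p2$theta_s, p2)) / p2$tau_i,
    x_L = (-s$x_L + .S(s$y_L - p2$theta_s, p2)) / p2$tau_i)
}

#' Deterministic drift of the simplified one-unit model
#'
#' The symmetric reduction of the full model: a single adapting recurrent
#' unit with constant drive `D = f(delta_I)`,
#' \deqn{\tau_\nu \dot\nu = -\nu + N(w\nu - g\alpha + D + \zeta),}
#' feeding the same second stage with inhibition `-nu_weight * d * nu`.
#' `nu_weight = 2` (default) is the exact collapse of the full model's
#' `-d(nu_R + nu_L)` with `nu_R = nu_L = nu`; `nu_weight = 1` is the
#' published one-unit form.
#'
#' @param state named vector `nu, alpha, u_R, u_L, y_R, y_L, x_R, x_L`.
#' @param t time (s).
#' @param D constant first-stage drive, `>= 0`.
#' @param stim [stimulus_params()] (drives the second stage).
#' @param p1 [first_stage_params()].
#' @param p2 [second_stage_params()].
#' @param zeta noise value.
#' @param nu_weight weight of the first-to-second-stage inhibition.
#' @param input_smoothing second-stage input treatment.
#' @return Named vector of time derivatives.
#' @export
simplified_drift <- function(state, t, D, stim, p1, p2, zeta = 0,
                             nu_weight = 2,
                             input_smoothing = c("sigmoid_centered", "ideal",
                                                 "sigmoid_printed")) {
  input_smoothing <- match.arg(input_smoothing)
  if (any(!is.finite(state))) stop("non-finite state")
  stopifnot(D >= 0)
  s <- as.list(state)
  ui <- .u_inputs(stim, t, input_smoothing)
  inh <- nu_weight * p2$d * s$nu
  c(nu = (-s$nu + .N(p1$w * s$nu - p1$g * s$alpha + D + zeta, p1)) / p1$tau_nu,
    alpha = (-s$alpha + .A(s$nu, p1)) / p1$tau_alpha,
    u_R = (-s$u_R + .S(p2$a * s$u_L - p2$b * s$x_L - inh +
                         p2$c * ui$i_R - p2$theta, p2)) / p2$tau,
    u_L = (-s$u_L + .S(p2$a * s$u_R - p2$b * s$x_R - inh +
                         p2$c * ui$i_L - p2$theta, p2)) / p2$tau,
    y_R = p2$alpha_x * (1 - s$y_R) * .S(s$u_R - p2$theta, p2) -
      p2$beta_x * s$y_R,
    y_L = p2$alpha_x * (1 - s$y_L) * .S(s$u_L - p2$theta, p2) -
      p2$beta_x * s$y_L,
    x_R = (-s$x_R + .S(s$y_R - p2$theta_s, p2)) / p2$tau_i,
    x_L = (-s$x_L + .S(s$y_L - p2$theta_s, p2)) / p2$tau_i)
}
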