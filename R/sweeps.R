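#' Mean dominance durations versus intensity difference
#'
#' The generalized input-strength experiment: for each intensity difference,
#' the full model is simulated `reps` times with distinct sub-seeds, percepts
#' are classified, and uncensored dominance durations are pooled per percept
#' type. The published calibration table supplies the drive strengths at the
#' experimental intensity differences (sigmoid evaluation off-grid).
#'
#' @param delta_I_values intensity differences (dB), `> 0`.
#' @param nl [nonlinearity_params()].
#' @param reps simulations per condition, `>= 1`.
#' @param t_max simulated seconds per repetition.
#' @param seed base seed; repetition `k` of condition `i` uses
#'   `seed + 1000*i + k`.
#' @param profile parameter profile (default the optimisation-stage profile).
#' @param dt integration step (s).
#' @param ... forwarded to [simulate_model()].
#' @return data.frame with one row per intensity difference: `delta_I`, `f`,
#'   `mean_SIM`, `sem_SIM`, `n_SIM`, `mean_AM`, `sem_AM`, `n_AM`. Conditions
#'   with no complete uncensored phase of a percept carry `NaN` (flagged, not
#'   dropped).
#' @export
levelt_curve <- function(delta_I_values, nl = nonlinearity_params(),
                         reps = 5, t_max = 600, seed = 1,
                         profile = model_profile("fig5fit"), dt = 5e-5, ...) {
  stopifnot(reps >= 1, all(delta_I_values > 0))
  profile$nonlinearity <- nl
  rows <- lapply(seq_along(delta_I_values), function(i) {
    dI <- delta_I_values[i]
    dur <- character(0)
    d_all <- data.frame(label = character(0), duration = numeric(0))
    for (k in seq_len(reps)) {
      traj <- simulate_model("full", stim = stimulus_params(dI),
                             profile = profile, t_max = t_max, dt = dt,
                             seed = seed + 1000L * i + k, ...)
      seqk <- tryCatch(percept_durations(traj), error = function(e) NULL)
      if (!is.null(seqk)) d_all <- rbind(d_all, uncensored_durations(seqk))
    }
    stat1 <- function(lab) {
      x <- d_all$duration[d_all$label == lab]
      if (length(x) == 0) return(c(NaN, NaN, 0))
      c(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
    }
    s <- stat1("SIM"); a <- stat1("AM")
    data.frame(delta_I = dI, f = .f_auto(nl, dI),
               mean_SIM = s[1], sem_SIM = s[2], n_SIM = s[3],
               mean_AM = a[1], sem_AM = a[2], n_AM = a[3])
  })
  do.call(rbind, rows)
}

.settled_label <- function(traj, settle_frac = 0.2) {
  m <- attr(traj, "meta")
  lab <- classify_cycles(traj)
  n <- length(lab)
  k <- max(1L, ceiling(settle_frac * n))
  tail_lab <- lab[(n - k + 1L):n]
  if (length(unique(tail_lab)) == 1L) {
    list(settled = TRUE, label = tail_lab[1], oscillatory = FALSE)
  } else {
    # alternation persisting to the end of a noise-free run
    list(settled = TRUE, label = NA_character_, oscillatory = TRUE)
  }
}

#' Map dynamical regimes by forward simulation
#'
#' Noise-free replacement for numerical continuation: for each value of the
#' control parameter the model is integrated from two initial conditions —
#' first stage DOWN (all zero) and first stage UP (`nu = 1`,
#' `alpha = A(1)`) — and each attractor is labelled through the percept
#' read-out. A value is `bistable` when the two initial conditions settle on
#' different percepts, `SIM_only`/`AM_only` when they agree, `oscillatory`
#' when a single noise-free run keeps alternating labels, and `undetermined`
#' when the settling criterion (constant cycle label over the trailing
#' `settle_frac` of the run) fails.
#'
#' @param grid sorted control values.
#' @param model `"simplified"` (default) or `"full"`.
#' @param control `"D"` (constant first-stage drive; simplified model) or
#'   `"delta_I"`.
#' @param profile parameter profile; default the noise-driven simplified
#'   demonstration profile (whose noise is disabled here).
#' @param stim stimulus driving the second stage (its `delta_I` is held fixed
#'   when `control = "D"`).
#' @param t_max,dt integration horizon and step.
#' @param settle_frac trailing fraction that must hold a constant label.
#' @param nu_weight first-to-second-stage inhibition weight (simplified).
#' @return data.frame with columns `value`, `label_down`, `label_up`,
#'   `regime`.
#' @export
bistability_scan <- function(grid, model = c("simplified", "full"),
                             control = c("D", "delta_I"),
                             profile = model_profile("fig3_simplified"),
                             stim = stimulus_params(0.5),
                             t_max = 50, dt = 5e-5, settle_frac = 0.2,
                             nu_weight = 2) {
  model <- match.arg(model)
  control <- match.arg(control)
  stopifnot(!is.unsorted(grid))
  profile$noise$sigma <- 0
  A1 <- sigmoid_activation(1, profile$first_stage$nu0,
                           profile$first_stage$k_A)
  rows <- lapply(grid, function(v) {
    if (control == "D" && model == "full") {
      stop("control = 'D' applies to the simplified model")
    }
    st <- if (control == "delta_I") stimulus_params(v, TD = stim$TD,
                                                    TR = stim$TR) else stim
    run1 <- function(init) {
      if (model == "simplified") {
        simulate_model("simplified", stim = st, profile = profile,
                       t_max = t_max, dt = dt, seed = 1,
                       D = if (control == "D") v else NULL,
                       nu_weight = nu_weight, init = init)
      } else {
        simulate_model("full", stim = st, profile = profile,
                       t_max = t_max, dt = dt, seed = 1, init = init)
      }
    }
    down <- run1(NULL)
    up_init <- if (model == "simplified") c(nu = 1, alpha = A1)
      else c(nu_R = 1, nu_L = 1, alpha_R = A1, alpha_L = A1)
    up <- run1(up_init)
    sd_ <- .settled_label(down, settle_frac)
    su_ <- .settled_label(up, settle_frac)
    regime <- if (sd_$oscillatory || su_$oscillatory) "oscillatory"
      else if (!sd_$settled || !su_$settled) "undetermined"
      else if (sd_$label != su_$label) "bistable"
      else if (sd_$label == "SIM") "SIM_only" else "AM_only"
    data.frame(value = v,
               label_down = if (sd_$oscillatory) "osc" else sd_$label,
               label_up = if (su_$oscillatory) "osc" else su_$label,
               regime = regime, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hysteresis sweep of a control parameter
#'
#' Sweeps the control value upward and then downward with state carry-over
#' (the final state of each run seeds the next), recording the settled percept
#' label at each value. Together with [bistability_scan()] this brackets the
#' fold points: the up- and down-sweep transitions should sit at the two ends
#' of the bistable interval.
#'
#' @inheritParams bistability_scan
#' @return data.frame with columns `value`, `label_up_sweep`,
#'   `label_down_sweep`.
#' @export
hysteresis_scan <- function(grid, model = "simplified", control = "D",
                            profile = model_profile("fig3_simplified"),
                            stim = stimulus_params(0.5),
                            t_max = 30, dt = 5e-5, settle_frac = 0.2,
                            nu_weight = 2) {
  stopifnot(model == "simplified", control == "D", !is.unsorted(grid))
  profile$noise$sigma <- 0
  sweep1 <- function(values) {
    init <- NULL
    out <- character(length(values))
    for (i in seq_along(values)) {
      traj <- simulate_model("simplified", stim = stim, profile = profile,
                             t_max = t_max, dt = dt, seed = 1,
                             D = values[i], nu_weight = nu_weight,
                             init = init)
      fin <- traj[nrow(traj), ]
      init <- c(nu = fin$nu, alpha = fin$alpha, u_R = fin$u_R, u_L = fin$u_L,
                y_R = fin$y_R, y_L = fin$y_L, x_R = fin$x_R, x_L = fin$x_L)
      s <- .settled_label(traj, settle_frac)
      out[i] <- if (s$oscillatory) "osc" else s$label
    }
    out
  }
  up <- sweep1(grid)
  dn <- rev(sweep1(rev(grid)))
  data.frame(value = grid, label_up_sweep = up, label_down_sweep = dn,
             stringsAsFactors = FALSE)
}
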