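#' Stimulus specification for antiphase vibrotactile pulse trains
#'
#' The stimulus is a pair of antiphase periodic square waves: the right hand
#' receives a high-intensity pulse on `[2k*TR, 2k*TR + TD)` and a
#' low-intensity pulse (level `1 - delta_I`) on `[(2k+1)*TR, (2k+1)*TR + TD)`;
#' the left hand receives the complementary pattern. `delta_I` is the
#' high/low intensity difference in dB, substituted literally, so the low
#' level goes negative for `delta_I > 1`.
#'
#' `smoothing` selects how waveform levels are evaluated by
#' [input_waveforms()] and [first_stage_drive()]: `"ideal"` uses the
#' discontinuous indicator levels; `"sigmoid_printed"` applies the steep
#' logistic `1/(1+exp(-k i))` (which maps the 0 baseline to 1/2);
#' `"sigmoid_centered"` applies `1/(1+exp(-k (i - 1/2)))`, preserving a
#' zero-ish baseline while saturating the high level.
#'
#' @param delta_I intensity difference (dB), `>= 0`.
#' @param TD pulse duration (s).
#' @param TR pulse repetition time (s); `0 < TD <= TR`.
#' @param smoothing waveform smoothing mode.
#' @param smoothing_slope slope `k` of the smoothing sigmoid.
#' @return An object of class `stimulus_params`. The presentation rate
#'   `PR = 1/TR` is exposed read-only through [presentation_rate()].
#' @export
stimulus_params <- function(delta_I, TD = 0.4, TR = 0.8,
                            smoothing = c("ideal", "sigmoid_printed",
                                          "sigmoid_centered"),
                            smoothing_slope = 20) {
  smoothing <- match.arg(smoothing)
  stopifnot(is.numeric(delta_I), length(delta_I) == 1, is.finite(delta_I),
            delta_I >= 0, TD > 0, TD <= TR, smoothing_slope > 0)
  structure(list(delta_I = delta_I, TD = TD, TR = TR, smoothing = smoothing,
                 smoothing_slope = smoothing_slope),
            class = "stimulus_params")
}

#' @rdname stimulus_params
#' @param params a `stimulus_params` object.
#' @export
presentation_rate <- function(params) 1 / params$TR

.smooth_mode_code <- function(mode) {
  switch(mode, ideal = 0L, sigmoid_printed = 1L, sigmoid_centered = 2L,
         collapsed = 3L,
         stop("unknown smoothing mode: ", mode))
}

.apply_smoothing <- function(level, mode, k) {
  switch(mode,
         ideal = level,
         sigmoid_printed = stats::plogis(k * level),
         sigmoid_centered = stats::plogis(k * (level - 0.5)),
         stop("unknown smoothing mode: ", mode))
}

#' Pulse on/off intervals of one side
#'
#' Enumerates the high- and low-intensity pulse intervals of one hand within
#' `[0, t_max)`. Intervals are half-open `[onset, offset)`; the right side
#' starts with a high pulse at `t = 0`, the left side with a low pulse
#' (antiphase).
#'
#' @param params [stimulus_params()].
#' @param side `"R"` or `"L"`.
#' @param t_max horizon (s), finite and `>= 0`.
#' @return data.frame with columns `onset`, `offset`, `level`
#'   (`"high"`/`"low"`), sorted, disjoint, clipped to `[0, t_max]`.
#' @export
pulse_intervals <- function(params, side = c("R", "L"), t_max) {
  side <- match.arg(side)
  if (!is.numeric(t_max) || length(t_max) != 1 || !is.finite(t_max))
    stop("t_max must be a finite number")
  if (t_max < 0) stop("t_max must be non-negative")
  TR <- params$TR; TD <- params$TD
  out <- data.frame(onset = numeric(0), offset = numeric(0),
                    level = character(0), stringsAsFactors = FALSE)
  if (t_max == 0) return(out)
  k_max <- ceiling(t_max / TR) + 1
  onsets <- (0:k_max) * TR
  # even multiples of TR: right-high / left-low; odd: right-low / left-high
  even <- (0:k_max) %% 2 == 0
  level <- if (side == "R") ifelse(even, "high", "low")
           else ifelse(even, "low", "high")
  offsets <- pmin(onsets + TD, t_max)
  keep <- onsets < t_max
  out <- data.frame(onset = onsets[keep], offset = offsets[keep],
                    level = level[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate the two input waveforms
#'
#' Raw levels are 1 on the side's high pulse, `1 - delta_I` on its low pulse
#' and 0 in gaps; the stimulus' smoothing mode is then applied pointwise.
#' Sampling uses the half-open convention: a sample exactly at a pulse
#' boundary belongs to the new segment.
#'
#' @param params [stimulus_params()].
#' @param t vector of times (s), `>= 0`.
#' @return data.frame with columns `t`, `i_R`, `i_L`.
#' @export
input_waveforms <- function(params, t) {
  stopifnot(all(is.finite(t)), all(t >= 0))
  lev <- .raw_levels(params, t)
  k <- params$smoothing_slope
  if (params$smoothing != "ideal") {
    lev$i_R <- .apply_smoothing(lev$i_R, params$smoothing, k)
    lev$i_L <- .apply_smoothing(lev$i_L, params$smoothing, k)
  }
  data.frame(t = t, i_R = lev$i_R, i_L = lev$i_L)
}

.raw_levels <- function(params, t) {
  TR <- params$TR; TD <- params$TD
  low <- 1 - params$delta_I
  eps <- 1e-9   # half-open windows robust to accumulated float error
  ph <- t - floor(t / (2 * TR) + eps) * (2 * TR)
  in_first <- ph < TD - eps
  in_second <- ph >= TR - eps & ph < TR + TD - eps
  i_R <- ifelse(in_first, 1, ifelse(in_second, low, 0))
  i_L <- ifelse(in_first, low, ifelse(in_second, 1, 0))
  list(i_R = i_R, i_L = i_L)
}

#' Input nonlinearity parameters
#'
#' The offset-and-scaled sigmoid mapping intensity difference to first-stage
#' drive strength, \eqn{f(\Delta I) = f_0 + f_1 / (1 + e^{-r(\Delta I -
#' \Delta I_0)})}, together with the optional table of calibration points.
#' Defaults are the published least-squares fit and the five published
#' calibration pairs.
#'
#' @param f0 offset.
#' @param f1 scale, `>= 0`.
#' @param r slope (per dB), `> 0`.
#' @param delta_I0 midpoint (dB); the equidominance point.
#' @param table optional data.frame with columns `delta_I` (strictly
#'   increasing) and `f`.
#' @return An object of class `nonlinearity_params`.
#' @export
nonlinearity_params <- function(f0 = 2.12, f1 = 1.80, r = 1.57,
                                delta_I0 = 2.64, table = f_points()) {
  stopifnot(f1 >= 0, r > 0)
  if (!is.null(table)) {
    stopifnot(is.data.frame(table), all(c("delta_I", "f") %in% names(table)))
    if (any(diff(table$delta_I) <= 0))
      stop("calibration table must have strictly increasing delta_I")
  }
  structure(list(f0 = f0, f1 = f1, r = r, delta_I0 = delta_I0, table = table),
            class = "nonlinearity_params")
}

#' Published drive-strength calibration points
#'
#' The five (intensity difference, drive strength) pairs estimated at the
#' experimental conditions, shipped as a plain-text fixture.
#'
#' @return data.frame with columns `delta_I` and `f`.
#' @export
f_points <- function() {
  path <- system.file("extdata", "f_points.csv", package = "tactrivalry")
  if (path == "") {      # package not installed yet (e.g. load_all)
    return(data.frame(delta_I = c(0.5, 1, 2, 4, 6),
                      f = c(2.16, 2.3, 2.6, 3.75, 3.92)))
  }
  utils::read.csv(path)
}

#' Evaluate the input nonlinearity
#'
#' `mode = "sigmoid"` evaluates the fitted sigmoid (monotone nondecreasing,
#' bounded in `[f0, f0 + f1]`); `mode = "table"` looks the value up among the
#' calibration points and errors on any `delta_I` that is not an exact table
#' entry — there is deliberately no interpolation, the sigmoid being the
#' documented way to evaluate off-grid intensity differences.
#'
#' @param nl [nonlinearity_params()].
#' @param delta_I intensity difference(s), dB, `>= 0`.
#' @param mode `"sigmoid"` or `"table"`.
#' @return Numeric drive strength(s).
#' @export
f_eval <- function(nl, delta_I, mode = c("sigmoid", "table")) {
  mode <- match.arg(mode)
  stopifnot(all(delta_I >= 0))
  if (mode == "sigmoid") {
    return(nl$f0 + nl$f1 * stats::plogis(nl$r * (delta_I - nl$delta_I0)))
  }
  if (is.null(nl$table)) stop("nonlinearity has no calibration table")
  idx <- match(delta_I, nl$table$delta_I)
  if (anyNA(idx)) {
    stop("no calibration table entry for delta_I = ",
         paste(delta_I[is.na(idx)], collapse = ", "),
         " (table mode does not interpolate)")
  }
  nl$table$f[idx]
}

# table value when available, sigmoid otherwise
.f_auto <- function(nl, delta_I) {
  if (!is.null(nl$table) && delta_I %in% nl$table$delta_I) {
    f_eval(nl, delta_I, mode = "table")
  } else {
    f_eval(nl, delta_I, mode = "sigmoid")
  }
}

#' Antiphase first-stage drive component
#'
#' The net stimulus term of the first-stage rate equations:
#' `drive_R = f(delta_I) * (i_L - i_R) / delta_I` and `drive_L = -drive_R`,
#' evaluated on the stimulus' (possibly smoothed) waveforms. With ideal
#' smoothing this is `+f` while the left pulse is high, `-f` while the right
#' pulse is high, and 0 in gaps. At `delta_I = 0` the 0/0 expression is
#' defined as 0 (the two waveforms coincide).
#'
#' This is the zero-mean antiphase component only; see the package vignette
#' for how the simulator combines it with the cycle-symmetric drive
#' `D = f(delta_I)`.
#'
#' @param params [stimulus_params()].
#' @param nl [nonlinearity_params()].
#' @param t times (s), `>= 0`.
#' @param f_mode how to evaluate `f(delta_I)`: `"auto"` (table entry if the
#'   stimulus' `delta_I` matches one, else sigmoid), `"sigmoid"`, `"table"`.
#' @return data.frame with columns `t`, `drive_R`, `drive_L`
#'   (`drive_R + drive_L == 0` at every `t`).
#' @export
first_stage_drive <- function(params, nl, t,
                              f_mode = c("auto", "sigmoid", "table")) {
  f_mode <- match.arg(f_mode)
  stopifnot(all(is.finite(t)), all(t >= 0))
  dI <- params$delta_I
  if (dI == 0) {
    return(data.frame(t = t, drive_R = rep(0, length(t)),
                      drive_L = rep(0, length(t))))
  }
  fv <- switch(f_mode,
               auto = .f_auto(nl, dI),
               sigmoid = f_eval(nl, dI, "sigmoid"),
               table = f_eval(nl, dI, "table"))
  wf <- input_waveforms(params, t)
  dR <- fv * (wf$i_L - wf$i_R) / dI
  data.frame(t = t, drive_R = dR, drive_L = -dR)
}

#' Export stimulus waveforms and drives to CSV
#'
#' @param params [stimulus_params()].
#' @param nl [nonlinearity_params()].
#' @param t times (s).
#' @param path output file.
#' @return `path`, invisibly. Columns: `t, i_R, i_L, drive_R, drive_L`.
#' @export
write_waveforms <- function(params, nl, t, path) {
  wf <- input_waveforms(params, t)
  dr <- first_stage_drive(params, nl, t)
  utils::write.csv(cbind(wf, dr[c("drive_R", "drive_L")]), path,
                   row.names = FALSE)
  invisible(path)
}
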