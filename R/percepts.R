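#' Classify each stimulus cycle as SIM or AM
#'
#' Reads the percept from the second-stage activity, one label per stimulus
#' period (length `2*TR`). Within a cycle, a side "responds" to a pulse
#' window when its unit's activity is at or above `u_resp` for at least a
#' fraction `resp_frac` of the window. A cycle is `SIM` when both sides
#' respond during their LOW-intensity windows (both percept units track every
#' pulse), `AM` when neither does (units only track their high-intensity
#' pulses), and otherwise inherits the previous cycle's label; an undetermined
#' first cycle defaults to `SIM` (the zero initial state's percept).
#'
#' The sustained-fraction rule rather than a peak rule is deliberate: during
#' AM the suppressed unit typically fires for a few tens of milliseconds at
#' pulse onset before the delayed inhibition arrives, which a max-based
#' read-out would miscount as a full response. `resp_frac` near 0 recovers
#' the peak rule.
#'
#' @param traj a `trajectory` from [simulate_model()].
#' @param stim stimulus; defaults to the trajectory's own.
#' @param u_resp response threshold on `u` (default 0.5).
#' @param resp_frac minimum fraction of the window at/above threshold.
#' @param burn_in transient to discard (s); defaults to the trajectory's.
#' @return Character vector of per-cycle labels (`"SIM"`/`"AM"`), with
#'   attributes `t0` (start of the first classified cycle) and `period`.
#' @export
classify_cycles <- function(traj, stim = NULL, u_resp = 0.5, resp_frac = 0.5,
                            burn_in = NULL) {
  m <- attr(traj, "meta")
  if (is.null(stim)) stim <- m$stim
  if (is.null(burn_in)) burn_in <- if (!is.null(m)) m$burn_in else 2
  TR <- stim$TR; TD <- stim$TD; per <- 2 * TR
  t <- traj$t
  t0 <- ceiling(burn_in / per) * per
  ncyc <- floor((max(t) - t0) / per + 1e-9)
  if (ncyc < 1) {
    stop("trajectory covers less than one full stimulus cycle after burn-in")
  }
  rel <- t - t0
  cyc <- floor(rel / per + 1e-9) + 1L
  ph <- rel - (cyc - 1L) * per
  ok <- rel >= -1e-12 & cyc >= 1L & cyc <= ncyc
  # low-intensity windows: right [TR, TR+TD), left [0, TD)
  iR <- ok & ph >= TR & ph < TR + TD
  iL <- ok & ph >= 0 & ph < TD
  fR <- tapply(traj$u_R[iR] >= u_resp, cyc[iR], mean)
  fL <- tapply(traj$u_L[iL] >= u_resp, cyc[iL], mean)
  fRv <- rep(NA_real_, ncyc); fLv <- rep(NA_real_, ncyc)
  fRv[as.integer(names(fR))] <- fR
  fLv[as.integer(names(fL))] <- fL
  lab <- character(ncyc)
  prev <- "SIM"
  for (k in seq_len(ncyc)) {
    lab[k] <- if (isTRUE(fRv[k] >= resp_frac) && isTRUE(fLv[k] >= resp_frac))
      "SIM"
    else if (isTRUE(fRv[k] < resp_frac) && isTRUE(fLv[k] < resp_frac)) "AM"
    else prev
    prev <- lab[k]
  }
  structure(lab, t0 = t0, period = per)
}

#' Merge cycle labels into dominance phases
#'
#' Run-length encodes the per-cycle labels into perceptual phases. Internal
#' phases shorter than `min_cycles` cycles are absorbed into the surrounding
#' phase (repeatedly, until stable). The first and last phases are flagged
#' censored — their true extent is unknown — and excluded from statistics by
#' default downstream.
#'
#' @param labels per-cycle labels from [classify_cycles()].
#' @param stim stimulus (for the cycle length); or supply `period`.
#' @param min_cycles minimum internal phase length in cycles (default 1, i.e.
#'   no merging).
#' @param period cycle length (s), overrides `stim`.
#' @return A `percept_sequence`: data.frame with columns `index`, `label`,
#'   `t_start`, `t_end`, `duration`, `censored`.
#' @export
extract_durations <- function(labels, stim = NULL, min_cycles = 1,
                              period = NULL) {
  if (length(labels) < 1) stop("need at least one classified cycle")
  if (is.null(period)) {
    period <- if (!is.null(attr(labels, "period"))) attr(labels, "period")
      else if (!is.null(stim)) 2 * stim$TR
      else stop("supply stim or period")
  }
  t0 <- attr(labels, "t0")
  if (is.null(t0)) t0 <- 0
  lab <- as.character(labels)
  if (min_cycles > 1 && length(lab) > 1) {
    repeat {
      r <- rle(lab)
      n <- length(r$lengths)
      short <- which(r$lengths < min_cycles)
      short <- short[short > 1 & short < n]
      if (length(short) == 0) break
      j <- short[1]
      idx_end <- cumsum(r$lengths)
      idx <- (idx_end[j] - r$lengths[j] + 1):idx_end[j]
      lab[idx] <- r$values[j - 1]
    }
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- data.frame(index = seq_along(r$values), label = r$values,
                    t_start = t0 + (starts - 1) * period,
                    t_end = t0 + ends * period,
                    stringsAsFactors = FALSE)
  out$duration <- out$t_end - out$t_start
  out$censored <- seq_len(nrow(out)) %in% c(1L, nrow(out))
  class(out) <- c("percept_sequence", "data.frame")
  out
}

#' Classify a trajectory and extract dominance phases in one call
#'
#' @inheritParams classify_cycles
#' @inheritParams extract_durations
#' @return A `percept_sequence`.
#' @export
percept_durations <- function(traj, stim = NULL, u_resp = 0.5,
                              resp_frac = 0.5, burn_in = NULL,
                              min_cycles = 1) {
  lab <- classify_cycles(traj, stim = stim, u_resp = u_resp,
                         resp_frac = resp_frac, burn_in = burn_in)
  extract_durations(lab, min_cycles = min_cycles)
}

#' Uncensored durations of a percept sequence
#'
#' @param seq a `percept_sequence`.
#' @return data.frame with columns `label` and `duration`, censored phases
#'   dropped, chronological order preserved.
#' @export
uncensored_durations <- function(seq) {
  keep <- !seq$censored
  data.frame(label = seq$label[keep], duration = seq$duration[keep],
             stringsAsFactors = FALSE)
}

#' Write / read a percept sequence as CSV
#'
#' @param seq a `percept_sequence`.
#' @param path file path.
#' @return the path (writer, invisibly) or the data.frame (reader).
#' @export
write_percepts <- function(seq, path) {
  utils::write.csv(as.data.frame(seq), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_percepts
#' @export
read_percepts <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$censored <- as.logical(out$censored)
  class(out) <- c("percept_sequence", "data.frame")
  out
}
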