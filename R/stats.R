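#' Moment ratios of dominance durations
#'
#' Coefficient of variation, sample skewness and their ratio on
#' mean-normalized durations. With `normalization = "per_percept"` (default)
#' each percept type's durations are divided by that type's mean before
#' pooling, removing the SIM/AM mean asymmetry; `"pooled"` divides by the
#' grand mean. Skewness is the biased moment estimator
#' \eqn{\gamma_1 = m_3 / m_2^{3/2}}, and the cv uses the `n-1` standard
#' deviation; both choices are part of the definition of the reported ratio.
#' The statistics are exactly scale-invariant.
#'
#' @param durations numeric vector of durations, `> 0`.
#' @param labels optional percept labels (required for per-percept
#'   normalization when more than one type is present).
#' @param normalization `"per_percept"` or `"pooled"`.
#' @return List with `cv`, `gamma1`, `ratio` (`gamma1/cv`) and `n`.
#' @export
moment_ratios <- function(durations, labels = NULL,
                          normalization = c("per_percept", "pooled")) {
  normalization <- match.arg(normalization)
  x <- as.numeric(durations)
  if (length(x) < 3) stop("need at least 3 durations")
  if (stats::var(x) == 0) stop("zero variance: skewness undefined")
  if (normalization == "per_percept" && !is.null(labels)) {
    stopifnot(length(labels) == length(x))
    for (l in unique(labels)) {
      sel <- labels == l
      x[sel] <- x[sel] / mean(x[sel])
    }
  } else {
    x <- x / mean(x)
  }
  cv <- stats::sd(x) / mean(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  gamma1 <- m3 / m2^1.5
  list(cv = cv, gamma1 = gamma1, ratio = gamma1 / cv, n = length(x))
}

#' Kolmogorov-Smirnov comparison with fitted log-normal and gamma
#'
#' Maximum-likelihood fits of the log-normal and gamma families to
#' mean-normalized durations, followed by one-sample KS tests of the data
#' against each fitted distribution. Following the source procedure, no
#' correction is applied for the fitting-induced optimism of the p-values; a
#' value below .05 reads "rejected".
#'
#' @param durations numeric vector, `> 0`, length `>= 20`.
#' @param labels optional labels for per-percept normalization.
#' @return List with `ks_lognormal_p`, `ks_gamma_p`, `lognormal` (meanlog,
#'   sdlog), `gamma` (shape, rate), `n`.
#' @export
ks_distribution_fit <- function(durations, labels = NULL) {
  x <- as.numeric(durations)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("durations must be positive and finite")
  }
  if (length(x) < 20) stop("need at least 20 durations for distribution fits")
  if (!is.null(labels)) {
    for (l in unique(labels)) {
      sel <- labels == l
      x[sel] <- x[sel] / mean(x[sel])
    }
  } else {
    x <- x / mean(x)
  }
  fln <- fitdistrplus::fitdist(x, "lnorm")
  fga <- fitdistrplus::fitdist(x, "gamma")
  p_ln <- suppressWarnings(
    stats::ks.test(x, "plnorm", fln$estimate[["meanlog"]],
                   fln$estimate[["sdlog"]])$p.value)
  p_ga <- suppressWarnings(
    stats::ks.test(x, "pgamma", fga$estimate[["shape"]],
                   fga$estimate[["rate"]])$p.value)
  list(ks_lognormal_p = p_ln, ks_gamma_p = p_ga,
       lognormal = fln$estimate, gamma = fga$estimate, n = length(x))
}

#' Lag correlations of successive dominance durations
#'
#' Pearson correlation between `duration[i]` and `duration[i + lag]` over the
#' chronological sequence of uncensored phases (percept types mixed, as lag-1
#' neighbours necessarily alternate). Durations are mean-normalized per
#' percept type by default.
#'
#' @param seq a `percept_sequence` (or a data.frame with `label`, `duration`,
#'   optionally `censored`).
#' @param lags integer lags, `>= 0`.
#' @param normalize mean-normalize per percept type first.
#' @return data.frame with columns `lag`, `n`, `estimate`, `p`.
#' @export
lag_correlations <- function(seq, lags = 1:2, normalize = TRUE) {
  d <- if (!is.null(seq$censored)) seq[!seq$censored, , drop = FALSE] else seq
  x <- d$duration
  if (normalize && !is.null(d$label)) {
    for (l in unique(d$label)) {
      sel <- d$label == l
      x[sel] <- x[sel] / mean(x[sel])
    }
  }
  out <- lapply(lags, function(l) {
    n_pairs <- length(x) - l
    if (n_pairs < 3) {
      stop(sprintf("need at least %d uncensored phases for lag %d", l + 3, l))
    }
    if (l == 0) {
      return(data.frame(lag = 0L, n = length(x), estimate = 1, p = 0))
    }
    ct <- stats::cor.test(x[seq_len(n_pairs)], x[seq_len(n_pairs) + l])
    data.frame(lag = as.integer(l), n = n_pairs,
               estimate = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}

#' Full duration-statistics report
#'
#' Per-percept means, moment ratios, distribution fits and lag correlations of
#' a percept sequence.
#'
#' @param seq a `percept_sequence`.
#' @param lags lags for [lag_correlations()]; lags with too few pairs are
#'   skipped.
#' @return A `duration_stats` list: `n`, `mean_SIM`, `mean_AM`, `cv`,
#'   `gamma1`, `ratio`, `ks_lognormal_p`, `ks_gamma_p`, `lag_corr`.
#' @export
duration_stats <- function(seq, lags = 1:2) {
  ud <- uncensored_durations(seq)
  if (nrow(ud) < 3) stop("need at least 3 uncensored phases")
  mr <- moment_ratios(ud$duration, ud$label)
  ks <- if (nrow(ud) >= 20) {
    ks_distribution_fit(ud$duration, ud$label)
  } else {
    list(ks_lognormal_p = NA_real_, ks_gamma_p = NA_real_)
  }
  lc <- tryCatch(lag_correlations(seq, lags = lags), error = function(e) NULL)
  structure(list(
    n = nrow(ud),
    mean_SIM = mean(ud$duration[ud$label == "SIM"]),
    mean_AM = mean(ud$duration[ud$label == "AM"]),
    cv = mr$cv, gamma1 = mr$gamma1, ratio = mr$ratio,
    ks_lognormal_p = ks$ks_lognormal_p, ks_gamma_p = ks$ks_gamma_p,
    lag_corr = lc), class = "duration_stats")
}

#' @export
print.duration_stats <- function(x, ...) {
  cat(sprintf("dominance-duration statistics (n = %d uncensored phases)\n", x$n))
  cat(sprintf("  mean SIM %.2f s | mean AM %.2f s\n", x$mean_SIM, x$mean_AM))
  cat(sprintf("  cv %.3f | gamma1 %.3f | gamma1/cv %.3f\n",
              x$cv, x$gamma1, x$ratio))
  cat(sprintf("  KS p: lognormal %.3g, gamma %.3g\n",
              x$ks_lognormal_p, x$ks_gamma_p))
  if (!is.null(x$lag_corr)) {
    for (i in seq_len(nrow(x$lag_corr))) {
      cat(sprintf("  lag %d: r = %.3f (p = %.3g)\n", x$lag_corr$lag[i],
                  x$lag_corr$estimate[i], x$lag_corr$p[i]))
    }
  }
  invisible(x)
}

#' Write a duration-statistics report as JSON
#'
#' @param stats a `duration_stats` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  obj <- unclass(stats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
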