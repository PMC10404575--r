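test_that("moment ratios recover closed forms for known distributions", {
  set.seed(101)
  x <- rexp(2e4)
  mr <- moment_ratios(x)
  expect_equal(mr$cv, 1, tolerance = 0.1)
  expect_equal(mr$gamma1, 2, tolerance = 0.15)
  expect_equal(mr$ratio, 2, tolerance = 0.15)

  set.seed(102)
  y <- rlnorm(2e4, 0, 0.5)
  mr <- moment_ratios(y)
  cv_true <- sqrt(exp(0.25) - 1)            # 0.5329
  g1_true <- (exp(0.25) + 2) * cv_true      # 1.7502
  expect_equal(mr$cv, cv_true, tolerance = 0.05)
  expect_equal(mr$gamma1, g1_true, tolerance = 0.15)
})

test_that("moment ratios are exactly scale-invariant and guard their inputs", {
  set.seed(7)
  x <- rgamma(50, 2)
  a <- moment_ratios(x)
  b <- moment_ratios(1000 * x)
  expect_equal(a$cv, b$cv)
  expect_equal(a$gamma1, b$gamma1)
  expect_error(moment_ratios(c(2, 2, 2)), "variance")
  expect_error(moment_ratios(c(2, 4)), "at least 3")
})

test_that("per-percept normalization removes the mean asymmetry", {
  set.seed(8)
  d <- c(rlnorm(300, log(10), 0.4), rlnorm(300, log(3), 0.4))
  lab <- rep(c("SIM", "AM"), each = 300)
  per <- moment_ratios(d, lab, "per_percept")
  pooled <- moment_ratios(d, lab, "pooled")
  expect_lt(per$cv, pooled$cv)   # pooling means inflates spread
  expect_equal(per$cv, sqrt(exp(0.16) - 1), tolerance = 0.08)
})

test_that("KS fit does not reject the true family on log-normal samples", {
  ok <- 0
  for (s in 1:30) {
    set.seed(s)
    x <- rlnorm(400, 0, 0.6)
    r <- ks_distribution_fit(x)
    expect_true(r$ks_lognormal_p >= 0 && r$ks_lognormal_p <= 1)
    expect_true(r$ks_gamma_p >= 0 && r$ks_gamma_p <= 1)
    if (r$ks_lognormal_p >= 0.05) ok <- ok + 1
  }
  expect_gte(ok, 24)   # true family retained in >= 80% of samples

  expect_error(ks_distribution_fit(c(-1, rep(1, 30))), "positive")
  expect_error(ks_distribution_fit(rlnorm(10)), "at least 20")
})

test_that("lag correlations match direct computation", {
  seqp <- data.frame(label = rep(c("SIM", "AM"), 3),
                     duration = c(1, 3, 1, 3, 1, 3),
                     censored = FALSE)
  lc <- lag_correlations(seqp, lags = 0:1, normalize = FALSE)
  expect_equal(lc$estimate[lc$lag == 0], 1)
  expect_equal(lc$estimate[lc$lag == 1], -1)

  set.seed(33)
  iid <- data.frame(label = rep(c("SIM", "AM"), 500),
                    duration = rexp(1000) + 0.1, censored = FALSE)
  lc <- lag_correlations(iid, lags = 1)
  expect_equal(lc$estimate, 0, tolerance = 0.1)
  expect_error(lag_correlations(iid[1:4, ], lags = 3), "at least")
})

test_that("duration_stats assembles a coherent report", {
  set.seed(11)
  n <- 60
  lab <- rep(c("SIM", "AM"), n / 2)
  seqp <- data.frame(index = 1:n, label = lab,
                     duration = rlnorm(n, log(8), 0.5),
                     censored = seq_len(n) %in% c(1, n))
  st <- duration_stats(seqp)
  expect_equal(st$n, n - 2)
  expect_true(is.finite(st$mean_SIM) && is.finite(st$mean_AM))
  expect_gt(st$ks_lognormal_p, 0)
  path <- tempfile(fileext = ".json")
  write_stats_json(st, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n, st$n)
  unlink(path)
})
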