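test_that("pulse intervals follow the antiphase timing of the two hands", {
  st <- stimulus_params(2, TD = 0.4, TR = 0.8)
  r <- pulse_intervals(st, "R", 1.6)
  expect_equal(r$onset, c(0, 0.8))
  expect_equal(r$offset, c(0.4, 1.2))
  expect_equal(r$level, c("high", "low"))
  l <- pulse_intervals(st, "L", 1.6)
  expect_equal(l$level, c("low", "high"))
  expect_equal(l$onset, r$onset)

  expect_equal(nrow(pulse_intervals(st, "R", 0)), 0)
  expect_error(pulse_intervals(st, "R", Inf), "finite")

  # disjoint, sorted, clipped over a longer horizon
  long <- pulse_intervals(st, "L", 5)
  expect_true(all(diff(long$onset) > 0))
  expect_true(all(long$offset > long$onset))
  expect_true(all(long$offset <= 5))
  expect_true(all(long$onset[-1] >= long$offset[-nrow(long)]))
})

test_that("ideal waveforms take levels 1, 1 - delta_I and 0", {
  st <- stimulus_params(0.5)
  wf <- input_waveforms(st, c(0.1, 0.9, 0.6))
  expect_equal(wf$i_R, c(1, 0.5, 0))
  expect_equal(wf$i_L, c(0.5, 1, 0))

  # equal intensities
  wf0 <- input_waveforms(stimulus_params(0), 0.1)
  expect_equal(wf0$i_R, 1)
  expect_equal(wf0$i_L, 1)

  # delta_I > 1 makes the low level negative (literal dB substitution)
  wf2 <- input_waveforms(stimulus_params(2), 0.9)
  expect_equal(wf2$i_R, -1)
})

test_that("waveforms are antiphase: i_R(t) = i_L(t + TR)", {
  st <- stimulus_params(1.5)
  t <- seq(0, 3.1, by = 0.05)
  a <- input_waveforms(st, t)
  b <- input_waveforms(st, t + st$TR)
  expect_equal(a$i_R, b$i_L)
  expect_equal(a$i_L, b$i_R)
})

test_that("boundary samples belong to the new segment (half-open windows)", {
  st <- stimulus_params(2)
  wf <- input_waveforms(st, c(0, 0.4, 0.8, 1.2, 1.6))
  expect_equal(wf$i_R, c(1, 0, -1, 0, 1))
})

test_that("smoothed waveforms follow the selected sigmoid dialect", {
  t <- c(0.1, 0.6)
  pr <- input_waveforms(stimulus_params(2, smoothing = "sigmoid_printed"), t)
  expect_equal(pr$i_R[1], plogis(20 * 1))
  expect_equal(pr$i_R[2], 0.5)              # printed sigmoid maps 0 to 1/2
  ce <- input_waveforms(stimulus_params(2, smoothing = "sigmoid_centered"), t)
  expect_equal(ce$i_R[1], plogis(20 * 0.5))
  expect_lt(ce$i_R[2], 1e-4)                # centered keeps a ~zero baseline
})

test_that("nonlinearity table lookup is exact with no interpolation", {
  nl <- nonlinearity_params()
  expect_equal(f_eval(nl, 2, "table"), 2.6)
  expect_equal(f_eval(nl, c(0.5, 6), "table"), c(2.16, 3.92))
  expect_error(f_eval(nl, 3, "table"), "interpolate")
})

test_that("sigmoid nonlinearity is monotone, bounded, correct at midpoint", {
  nl <- nonlinearity_params(f0 = 2.12, f1 = 1.80, r = 1.57, delta_I0 = 2.64)
  expect_equal(f_eval(nl, 2.64, "sigmoid"), 2.12 + 0.90)
  expect_equal(f_eval(nl, 1e6, "sigmoid"), 3.92)
  grid <- f_eval(nl, seq(0, 10, by = 0.1), "sigmoid")
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= nl$f0 & grid <= nl$f0 + nl$f1))
  expect_error(f_eval(nl, -1, "sigmoid"))
})

test_that("first-stage drive is the antisymmetric weighted difference", {
  st <- stimulus_params(2)
  nl <- nonlinearity_params()
  d <- first_stage_drive(st, nl, c(0.1, 0.9, 0.6))
  # right-high window: i_L - i_R = -2, so drive_R = 2.6 * (-2)/2 = -2.6
  expect_equal(d$drive_R, c(-2.6, 2.6, 0))
  expect_equal(d$drive_L, -d$drive_R)

  t <- seq(0, 4, by = 0.07)
  dd <- first_stage_drive(st, nl, t)
  expect_true(all(dd$drive_R + dd$drive_L == 0))

  d0 <- first_stage_drive(stimulus_params(0), nl, t)
  expect_true(all(d0$drive_R == 0))           # 0/0 limit convention
})

test_that("stimulus invariants are enforced at construction", {
  expect_error(stimulus_params(-1), "delta_I")
  expect_error(stimulus_params(2, TD = 0.9, TR = 0.8))
  expect_error(stimulus_params(2, smoothing_slope = 0))
  expect_equal(presentation_rate(stimulus_params(2)), 1.25)
})
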