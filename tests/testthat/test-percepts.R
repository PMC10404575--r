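test_that("constructed traces classify as all-SIM or all-AM", {
  # both units active in every pulse window -> SIM
  sim <- synthetic_traj(6, function(side, level, k) 1)
  lab <- classify_cycles(sim, stim = stimulus_params(2), burn_in = 0)
  expect_equal(as.character(lab), rep("SIM", 6))
  # units active only in their own high windows -> AM
  am <- synthetic_traj(6, function(side, level, k) as.numeric(level == "high"))
  lab <- classify_cycles(am, stim = stimulus_params(2), burn_in = 0)
  expect_equal(as.character(lab), rep("AM", 6))
})

test_that("ambiguous cycles inherit and an undetermined start is SIM", {
  # one side responds to its low window, the other does not: ambiguous
  mixed <- synthetic_traj(3, function(side, level, k) {
    if (level == "high") 1 else as.numeric(side == "R")
  })
  lab <- classify_cycles(mixed, stim = stimulus_params(2), burn_in = 0)
  expect_equal(as.character(lab), rep("SIM", 3))

  # SIM SIM AM AM with an ambiguous middle cycle inherits SIM
  seq5 <- synthetic_traj(5, function(side, level, k) {
    if (level == "high") return(1)
    if (k <= 2) 1 else if (k == 3) as.numeric(side == "L") else 0
  })
  lab <- classify_cycles(seq5, stim = stimulus_params(2), burn_in = 0)
  expect_equal(as.character(lab), c("SIM", "SIM", "SIM", "AM", "AM"))
})

test_that("brief onset transients are not counted as full responses", {
  # suppressed side fires only the first 10% of its low window
  st <- stimulus_params(2)
  tr <- synthetic_traj(4, function(side, level, k) 1)
  ph <- tr$t - floor(tr$t / 1.6) * 1.6
  low_R <- ph >= 0.8 & ph < 1.2
  tr$u_R[low_R & ph >= 0.84] <- 0
  low_L <- ph < 0.4
  tr$u_L[low_L & ph >= 0.04] <- 0
  lab <- classify_cycles(tr, stim = st, burn_in = 0)
  expect_true(all(lab == "AM"))
  # with a peak-style rule (tiny resp_frac) the same trace reads as SIM
  lab_peak <- classify_cycles(tr, stim = st, burn_in = 0, resp_frac = 1e-9)
  expect_true(all(lab_peak == "SIM"))
})

test_that("run-length extraction matches direct arithmetic", {
  lab <- structure(c("SIM", "SIM", "SIM", "AM", "AM"), t0 = 0, period = 1.6)
  seqp <- extract_durations(lab)
  expect_equal(seqp$duration, c(4.8, 3.2))
  expect_equal(seqp$label, c("SIM", "AM"))
  expect_true(all(seqp$censored))

  one <- extract_durations(structure(rep("AM", 4), t0 = 0, period = 1.6))
  expect_equal(nrow(one), 1)
  expect_true(one$censored)
})

test_that("short internal phases merge into their surroundings", {
  lab <- structure(c("SIM", "AM", "SIM"), t0 = 0, period = 1.6)
  merged <- extract_durations(lab, min_cycles = 2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$label, "SIM")
  expect_equal(merged$duration, 3 * 1.6)

  # merging is idempotent
  lab2 <- structure(c("SIM", "SIM", "AM", "AM", "AM", "SIM", "SIM"),
                    t0 = 0, period = 1.6)
  a <- extract_durations(lab2, min_cycles = 2)
  b <- extract_durations(structure(rep(a$label, round(a$duration / 1.6)),
                                   t0 = 0, period = 1.6), min_cycles = 2)
  expect_equal(a$duration, b$duration)
})

test_that("phases tile the analysed window and alternate labels", {
  traj <- quick_full(t_max = 120, seed = 5)
  lab <- classify_cycles(traj)
  seqp <- extract_durations(lab)
  expect_equal(sum(seqp$duration), length(lab) * 1.6)
  expect_equal(seqp$t_start[-1], seqp$t_end[-nrow(seqp)])
  if (nrow(seqp) > 1) {
    expect_true(all(seqp$label[-1] != seqp$label[-nrow(seqp)]))
  }
  ud <- uncensored_durations(seqp)
  expect_equal(nrow(ud), max(0, nrow(seqp) - 2))
})

test_that("a too-short trajectory is an explicit error", {
  tr <- synthetic_traj(1, function(...) 1)
  expect_error(classify_cycles(tr[tr$t < 1, ], stim = stimulus_params(2),
                               burn_in = 0), "cycle")
})

test_that("percept sequences round-trip through CSV", {
  lab <- structure(c("SIM", "AM", "AM", "SIM"), t0 = 1.6, period = 1.6)
  seqp <- extract_durations(lab)
  path <- tempfile(fileext = ".csv")
  write_percepts(seqp, path)
  back <- read_percepts(path)
  expect_equal(back$duration, seqp$duration)
  expect_equal(back$censored, seqp$censored)
  unlink(path)
})
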