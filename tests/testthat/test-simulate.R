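test_that("one Euler step of the compiled kernel matches the R drift", {
  prof <- fig5()
  st <- stimulus_params(2)
  s0 <- random_state(9)
  for (mode in c("collapsed", "ideal", "sigmoid_centered")) {
    traj <- simulate_model("full", st, prof, t_max = 2e-5, dt = 1e-5,
                           store_dt = 1e-5, init = s0, drive_mode = mode,
                           noise = noise_params(sigma = 0))
    d <- full_drift(s0, 0, st, prof$nonlinearity, prof$first_stage,
                    prof$second_stage, drive_mode = mode)
    stepped <- s0 + 1e-5 * d
    got <- unlist(traj[2, names(s0)])
    expect_equal(got, stepped, tolerance = 1e-12)
  }

  # simplified kernel against simplified_drift
  s8 <- c(nu = 0.3, alpha = 0.4, u_R = 0.7, u_L = 0.1, y_R = 0.5,
          y_L = 0.02, x_R = 0.6, x_L = 0.01)
  traj <- simulate_model("simplified", st, prof, t_max = 2e-5, dt = 1e-5,
                         store_dt = 1e-5, init = s8, D = 2.6,
                         noise = noise_params(sigma = 0))
  d <- simplified_drift(s8, 0, 2.6, st, prof$first_stage, prof$second_stage)
  expect_equal(unlist(traj[2, names(s8)]), s8 + 1e-5 * d, tolerance = 1e-12)
})

test_that("identical seeds give identical trajectories end-to-end", {
  a <- quick_full(t_max = 10, seed = 21)
  b <- quick_full(t_max = 10, seed = 21)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- quick_full(t_max = 10, seed = 22)
  expect_false(identical(a$nu_R, c_$nu_R))
})

test_that("all stored state variables stay inside [0,1]", {
  traj <- quick_full(t_max = 40, seed = 2, sigma = 1)
  vars <- c("nu_R", "nu_L", "alpha_R", "alpha_L", "u_R", "u_L",
            "y_R", "y_L", "x_R", "x_L")
  for (v in vars) {
    expect_gte(min(traj[[v]]), -1e-6)
    expect_lte(max(traj[[v]]), 1 + 1e-6)
  }
})

test_that("halving dt converges: slow variables pointwise, fast in L1", {
  # a switch-free condition isolates integrator error from the (real)
  # dt-sensitivity of switching times; threshold variables with tau = 1 ms
  # shift their crossing instants by O(dt), so they are compared in L1
  st <- stimulus_params(1)
  prof <- fig5()
  a <- simulate_model("simplified", st, prof, t_max = 10, dt = 5e-5, D = 1,
                      noise = noise_params(sigma = 0), seed = 1)
  b <- simulate_model("simplified", st, prof, t_max = 10, dt = 2.5e-5, D = 1,
                      noise = noise_params(sigma = 0), seed = 1)
  for (v in c("nu", "alpha")) expect_lt(max(abs(a[[v]] - b[[v]])), 1e-3)
  for (v in c("u_R", "u_L", "x_R", "x_L")) {
    expect_lt(mean(abs(a[[v]] - b[[v]])), 1e-3)
  }
})

test_that("equal intensities and no noise read out as all-SIM", {
  traj <- simulate_model("full", stimulus_params(0), fig5(), t_max = 15,
                         dt = 5e-5, noise = noise_params(sigma = 0), seed = 1)
  lab <- classify_cycles(traj)
  expect_true(all(lab == "SIM"))
})

test_that("clamped first stage pins the encoded percept", {
  st <- stimulus_params(2)
  prof <- fig5()
  down <- simulate_model("full", st, prof, t_max = 15, dt = 5e-5,
                         noise = noise_params(sigma = 0), clamp_nu = 0)
  expect_true(all(classify_cycles(down) == "SIM"))
  up <- simulate_model("full", st, prof, t_max = 15, dt = 5e-5,
                       noise = noise_params(sigma = 0), clamp_nu = 1)
  expect_true(all(classify_cycles(up) == "AM"))
})

test_that("an unstable step size aborts with a diagnostic", {
  expect_error(
    suppressWarnings(simulate_model("full", stimulus_params(2), fig5(),
                                    t_max = 8, dt = 0.01, store_dt = 0.01,
                                    noise = noise_params(sigma = 0))),
    "non-finite state at step")
})

test_that("trajectories round-trip through annotated CSV", {
  traj <- quick_full(t_max = 5, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$nu_R, traj$nu_R, tolerance = 1e-6)
  expect_true(any(grepl("seed: 4", attr(back, "header"))))
  unlink(path)
})
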