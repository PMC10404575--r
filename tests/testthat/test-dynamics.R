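test_that("logistic activation matches hand-computed values", {
  expect_equal(sigmoid_activation(5, center = 5), 0.5)
  expect_equal(sigmoid_activation(7, center = 5, slope = 1),
               1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(sigmoid_activation(-1e4, slope = 20), 0)
  expect_equal(sigmoid_activation(1e4, slope = 20), 1)
})

test_that("full drift reproduces direct evaluations of the rate equations", {
  prof <- fig5()
  st <- stimulus_params(2)
  s0 <- setNames(rep(0, 10), names(random_state(1)))
  # from rest in a stimulus gap with d = 0: u relaxes toward S(-theta)
  p2 <- prof$second_stage; p2$d <- 0
  d <- full_drift(s0, t = 0.6, st, prof$nonlinearity, prof$first_stage, p2,
                  input_smoothing = "ideal")
  expect_equal(unname(d["u_R"]), plogis(20 * -0.5) / 0.001, tolerance = 1e-10)

  # nu equation with the collapsed drive D = f(2) = 2.6 at nu = alpha = 0
  dN <- full_drift(s0, 0.6, st, prof$nonlinearity, prof$first_stage,
                   prof$second_stage)
  expect_equal(unname(dN["nu_R"]), plogis(2.6 - 5) / 0.9, tolerance = 1e-10)
})

test_that("swapping R and L labels swaps the derivatives exactly", {
  prof <- fig5()
  st <- stimulus_params(2)
  s <- random_state(42)
  swap <- function(v) {
    nm <- names(v)
    sw <- sub("_R$", "_X", nm); sw <- sub("_L$", "_R", sw)
    sw <- sub("_X$", "_L", sw)
    setNames(v, sw)[nm]
  }
  for (tt in c(0.1, 0.6, 0.9)) {
    # at t and t + TR the stimulus roles are interchanged
    d1 <- full_drift(s, tt, st, prof$nonlinearity, prof$first_stage,
                     prof$second_stage, drive_mode = "ideal")
    d2 <- full_drift(swap(s), tt + st$TR, st, prof$nonlinearity,
                     prof$first_stage, prof$second_stage,
                     drive_mode = "ideal")
    expect_equal(d1, swap(d2), tolerance = 1e-12)
  }
})

test_that("drift keeps [0,1]^10 forward-invariant at the boundaries", {
  prof <- fig5()
  st <- stimulus_params(2)
  nm <- names(random_state(1))
  for (seed in 1:20) {
    s <- random_state(seed)
    for (v in nm) {
      lo <- s; lo[v] <- 0
      hi <- s; hi[v] <- 1
      tt <- runif(1, 0, 1.6)
      dlo <- full_drift(lo, tt, st, prof$nonlinearity, prof$first_stage,
                        prof$second_stage, zeta = rnorm(1, 0, 2),
                        drive_mode = "ideal")
      dhi <- full_drift(hi, tt, st, prof$nonlinearity, prof$first_stage,
                        prof$second_stage, zeta = rnorm(1, 0, 2),
                        drive_mode = "ideal")
      expect_gte(unname(dlo[v]), 0)
      expect_lte(unname(dhi[v]), 0)
    }
  }
})

test_that("simplified drift matches its closed-form pieces and symmetry", {
  prof <- model_profile("fig3_simplified")
  st <- stimulus_params(0.5)
  s0 <- setNames(rep(0, 8), c("nu", "alpha", "u_R", "u_L", "y_R", "y_L",
                              "x_R", "x_L"))
  d <- simplified_drift(s0, 0.6, D = 0, st, prof$first_stage,
                        prof$second_stage)
  # g = 0, zeta = 0, D = 0: nu-dot at rest is N(0)/tau_nu
  expect_equal(unname(d["nu"]), (1 / (1 + exp(5))) / 0.9, tolerance = 1e-10)

  # symmetric second-stage state with equal inputs stays symmetric (gap)
  s <- setNames(c(0.3, 0.2, 0.6, 0.6, 0.4, 0.4, 0.5, 0.5), names(s0))
  ds <- simplified_drift(s, 0.6, D = 1, st, prof$first_stage,
                         prof$second_stage)
  expect_equal(unname(ds["u_R"]), unname(ds["u_L"]))
  expect_equal(unname(ds["x_R"]), unname(ds["x_L"]))
})

test_that("simplified model is the exact symmetric collapse of the full one", {
  prof <- fig5()
  st <- stimulus_params(2)
  nl <- prof$nonlinearity
  D <- f_eval(nl, 2, "table")
  nu <- 0.37; al <- 0.52
  s8 <- c(nu = nu, alpha = al, u_R = 0.8, u_L = 0.1, y_R = 0.6, y_L = 0.05,
          x_R = 0.3, x_L = 0.02)
  s10 <- c(nu_R = nu, nu_L = nu, alpha_R = al, alpha_L = al,
           u_R = 0.8, u_L = 0.1, y_R = 0.6, y_L = 0.05, x_R = 0.3,
           x_L = 0.02)
  for (tt in c(0.2, 0.5, 1.0)) {
    dF <- full_drift(s10, tt, st, nl, prof$first_stage, prof$second_stage,
                     drive_mode = "collapsed")
    dS <- simplified_drift(s8, tt, D, st, prof$first_stage,
                           prof$second_stage, nu_weight = 2)
    expect_equal(unname(dF["nu_R"]), unname(dS["nu"]), tolerance = 1e-12)
    expect_equal(unname(dF["alpha_R"]), unname(dS["alpha"]), tolerance = 1e-12)
    for (v in c("u_R", "u_L", "y_R", "y_L", "x_R", "x_L")) {
      expect_equal(unname(dF[v]), unname(dS[v]), tolerance = 1e-12)
    }
  }
})

test_that("gate onset delay from the closed form matches the nominal delay", {
  expect_equal(gate_onset_delay(50, 8, 0.22), -log(1 - 0.22 * 58 / 50) / 58)
  expect_equal(gate_onset_delay(50, 8, 0.22), 0.005, tolerance = 0.02)
  # simulated gate rise reproduces the closed form
  p2 <- second_stage_params()
  y <- 0; dt <- 1e-6; t <- 0
  while (y < p2$theta_s) {
    y <- y + dt * (p2$alpha_x * (1 - y) - p2$beta_x * y)  # u clamped at 1
    t <- t + dt
  }
  expect_equal(t, gate_onset_delay(50, 8, 0.22), tolerance = 1e-3)
  # inconsistent gate constants are rejected at construction
  expect_error(second_stage_params(theta_s = 0.5), "delta")
})

test_that("non-finite states are rejected", {
  prof <- fig5()
  s <- random_state(1); s["u_R"] <- NaN
  expect_error(full_drift(s, 0, stimulus_params(2), prof$nonlinearity,
                          prof$first_stage, prof$second_stage), "finite")
})
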