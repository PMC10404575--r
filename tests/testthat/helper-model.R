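# shared helpers: cheap simulations and canonical parameter objects

fig5 <- function() model_profile("fig5fit")

quick_full <- function(delta_I = 2, t_max = 60, seed = 1, sigma = NULL,
                       dt = 5e-5, ...) {
  prof <- model_profile("fig5fit")
  if (!is.null(sigma)) prof$noise$sigma <- sigma
  simulate_model("full", stimulus_params(delta_I), prof, t_max = t_max,
                 dt = dt, seed = seed, ...)
}

# random valid model state for property tests
random_state <- function(seed) {
  set.seed(seed)
  s <- runif(10)
  names(s) <- c("nu_R", "nu_L", "alpha_R", "alpha_L", "u_R", "u_L",
                "y_R", "y_L", "x_R", "x_L")
  s
}

# synthetic trajectory with prescribed per-window second-stage responses;
# resp is a function(side, level, cycle) -> 0/1 activity inside that window
synthetic_traj <- function(n_cycles, resp, TR = 0.8, TD = 0.4,
                           step = 0.01) {
  per <- 2 * TR
  t <- seq(0, n_cycles * per, by = step)
  cyc <- pmin(floor(t / per) + 1, n_cycles)
  ph <- t - (cyc - 1) * per
  u_R <- numeric(length(t)); u_L <- numeric(length(t))
  w1 <- ph < TD                      # right high / left low
  w2 <- ph >= TR & ph < TR + TD      # right low / left high
  for (k in unique(cyc)) {
    i1 <- w1 & cyc == k; i2 <- w2 & cyc == k
    u_R[i1] <- resp("R", "high", k); u_L[i1] <- resp("L", "low", k)
    u_R[i2] <- resp("R", "low", k);  u_L[i2] <- resp("L", "high", k)
  }
  data.frame(t = t, u_R = u_R, u_L = u_L)
}
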