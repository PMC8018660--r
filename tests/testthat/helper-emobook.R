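# Brute-force numerical integration of the curve derivatives (classical
# Runge-Kutta at 0.001-minute steps), independent of the closed-form updates
# it checks. First-order Euler at this step size carries ~1e-5 error on the
# steep logistic increase, above the 1e-6 agreement demanded here, so the
# oracle uses fourth-order steps of the same size.
euler_update <- function(value, minutes, params, mode, step = 0.001) {
  deriv <- if (mode == "increase") {
    if (params$increase_kind == "linear") function(v) params$a
    else function(v) params$k_inc * v * (1 - v)
  } else {
    if (params$dec_kind == 2L) function(v) -params$lin_rate
    else if (params$decrease_kind == "exponential")
      function(v) -log(2) / params$lhw_eff * v
    else function(v) -params$k_dec * v * (1 - v)
  }
  rk4_step <- function(v, h) {
    k1 <- deriv(v)
    k2 <- deriv(v + h / 2 * k1)
    k3 <- deriv(v + h / 2 * k2)
    k4 <- deriv(v + h * k3)
    min(params$upper, max(params$lower, v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)))
  }
  v <- value
  nsteps <- floor(minutes / step)
  for (i in seq_len(nsteps)) v <- rk4_step(v, step)
  rest <- minutes - nsteps * step
  if (rest > 0) v <- rk4_step(v, rest)
  v
}

all_dynamics_names <- c("original", "alternative", "dynamics3", "dynamics4")
linc_levels <- c(fast = 10, intermediate = 30, slow = 60)

# a small scaled run used by several engine tests
tiny_run <- function(dynamics = "original", linc = "fast", lhw = 720,
                     lps = 0.99, seed = 7, scale = 0.01, ...) {
  run_simulation(run_config(dynamics, linc, lhw, lps = lps, seed = seed,
                            scale = scale, ...))
}
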