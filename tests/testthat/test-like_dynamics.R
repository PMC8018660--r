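test_that("calibration constants follow the speed contracts", {
  d <- make_dynamics("original", "fast", 720)
  expect_equal(d$a, 0.1)
  expect_equal(d$lower, 0)
  expect_equal(d$upper, 1)

  alt <- make_dynamics("alternative", "fast", 2880)
  expect_equal(alt$k_inc, 2 * log(99) / 10)
  expect_equal(alt$k_dec, log(99) / 2880)
  expect_equal(alt$lower, 0.01)
  expect_equal(alt$upper, 0.99)

  # the four named dynamics map one-to-one onto the curve-shape combinations
  kinds <- t(vapply(all_dynamics_names, function(nm) {
    d <- make_dynamics(nm, "fast", 720)
    c(d$increase_kind, d$decrease_kind)
  }, character(2)))
  expect_equal(nrow(unique(kinds)), 4L)
})

test_that("grooming increase matches closed-form expectations", {
  d <- make_dynamics("original", "fast", 720)
  expect_equal(groom_increase(0.5, 2, d), 0.7)
  expect_equal(groom_increase(0.37, 0, d), 0.37)
  expect_equal(groom_increase(0.95, 10, d), 1) # clipped at the upper bound

  alt <- make_dynamics("alternative", "fast", 2880)
  # the calibrated sigmoid is symmetric about its midpoint: the lower bound
  # sits at minus half the traversal time
  expect_equal(groom_increase(0.01, 5, alt), 0.5, tolerance = 1e-9)
  expect_error(groom_increase(0.5, -1, d), "non-negative")
})

test_that("idle decay matches half-life and logistic crossing contracts", {
  d <- make_dynamics("original", "fast", 21600)
  expect_equal(idle_decay(0.8, 21600, d), 0.4)
  d720 <- make_dynamics("original", "fast", 720)
  expect_equal(idle_decay(0.8, 720, d720), 0.4)
  expect_equal(idle_decay(0.64, 0, d720), 0.64)

  alt <- make_dynamics("alternative", "fast", 2880)
  expect_equal(idle_decay(0.99, 2880, alt), 0.5, tolerance = 1e-9)
  expect_error(idle_decay(0.5, -3, alt), "non-negative")
})

test_that("traversal times equal the LINC period for all dynamics and speeds", {
  for (nm in all_dynamics_names) {
    for (lv in names(linc_levels)) {
      d <- make_dynamics(nm, lv, 2880)
      expect_equal(time_to_reach(d$lower, d$upper, "increase", d),
                   unname(linc_levels[lv]), tolerance = 1e-9,
                   info = paste(nm, lv))
    }
  }
})

test_that("time_to_reach inverts decay, including the lhw = 0 rules", {
  d <- make_dynamics("original", "fast", 720)
  expect_equal(time_to_reach(0.8, 0.4, "decrease", d), 720)

  z <- make_dynamics("original", "fast", 0)
  expect_equal(z$decrease_kind, "exponential")
  expect_equal(time_to_reach(1, 0, "decrease", z), 50)
  expect_lte(time_to_reach(1, 0, "decrease", z), 50)

  # logistic dynamics map lhw = 0 to the matching very-fast setting 25
  za <- make_dynamics("alternative", "fast", 0)
  expect_equal(za$lhw_eff, 25)
  expect_equal(idle_decay(0.99, 25, za), 0.5, tolerance = 1e-9)

  expect_error(time_to_reach(0.4, 0.8, "decrease", d), "higher target")
  expect_error(time_to_reach(0.8, 0.4, "increase", d), "lower target")
  expect_error(time_to_reach(0.5, 0.5, "increase", d), "differ")
})

test_that("updates compose as semigroups under split durations", {
  set.seed(1)
  for (nm in all_dynamics_names) {
    d <- make_dynamics(nm, "intermediate", 2880)
    v <- runif(50, d$lower, d$upper)
    t1 <- runif(50, 0, 40)
    t2 <- runif(50, 0, 40)
    expect_equal(groom_increase(groom_increase(v, t1, d), t2, d),
                 groom_increase(v, t1 + t2, d), tolerance = 1e-9)
    expect_equal(idle_decay(idle_decay(v, t1 * 50, d), t2 * 50, d),
                 idle_decay(v, (t1 + t2) * 50, d), tolerance = 1e-9)
  }
})

test_that("closed-form updates agree with brute-force Euler integration", {
  set.seed(42)
  for (nm in c("original", "alternative")) {
    d <- make_dynamics(nm, "slow", 180)
    v <- runif(12, d$lower + 0.02, d$upper - 0.02)
    t_inc <- runif(12, 0, 25)
    t_dec <- runif(12, 0, 60)
    for (i in seq_along(v)) {
      expect_equal(groom_increase(v[i], t_inc[i], d),
                   euler_update(v[i], t_inc[i], d, "increase"),
                   tolerance = 1e-5, info = paste(nm, "inc", i))
      expect_equal(idle_decay(v[i], t_dec[i], d),
                   euler_update(v[i], t_dec[i], d, "decrease"),
                   tolerance = 1e-5, info = paste(nm, "dec", i))
    }
  }
})

test_that("curve shapes: slow logistic start, fast logistic middle", {
  lin <- make_dynamics("original", "fast", 2880)
  log_ <- make_dynamics("alternative", "fast", 2880)
  eps <- 1e-3
  # increase rate near the lower bound: logistic strictly below linear
  rate_lin <- (groom_increase(lin$lower, eps, lin) - lin$lower) / eps
  rate_log <- (groom_increase(log_$lower, eps, log_) - log_$lower) / eps
  expect_lt(rate_log, rate_lin)
  # logistic decrease: fast in the middle, slow at the top
  drop_mid <- 0.5 - idle_decay(0.5, 1, log_)
  drop_top <- 0.9 - idle_decay(0.9, 1, log_)
  expect_gt(drop_mid, drop_top)
})

test_that("values never escape the dynamics bounds", {
  set.seed(99)
  for (nm in all_dynamics_names) {
    d <- make_dynamics(nm, "fast", 180)
    v <- runif(200, d$lower, d$upper)
    for (k in 1:20) {
      v <- if (k %% 2) groom_increase(v, runif(200, 0, 120), d)
           else idle_decay(v, runif(200, 0, 3000), d)
      expect_true(all(v >= d$lower - 1e-12 & v <= d$upper + 1e-12))
    }
  }
})

test_that("configuration errors are caught", {
  expect_error(make_dynamics("nonsense", "fast", 720))
  expect_error(make_dynamics("original", "warp", 720))
  expect_error(make_dynamics("original", "fast", -5), "non-negative")
  expect_error(make_dynamics("original", 17, 720), "10, 30, 60")
})

test_that("like_curve tabulates both regimes on the minute grid", {
  d <- make_dynamics("alternative", "fast", 2880)
  tab <- like_curve(d, 0:10)
  expect_equal(nrow(tab), 22)
  inc <- tab[tab$mode == "increase", ]
  expect_equal(inc$like[1], d$lower)
  expect_equal(inc$like[11], d$upper, tolerance = 1e-9)
  dec <- tab[tab$mode == "decrease", ]
  expect_true(all(diff(dec$like) <= 0))
})
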