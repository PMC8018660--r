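test_that("init_group builds the dominance ladder and 380 directed dyads", {
  g <- init_group(20, seed = 3)
  expect_equal(nrow(g$individuals), 20)
  expect_equal(g$individuals$dominance[1], 1.0)
  expect_equal(g$individuals$dominance[20], 0.05)
  expect_true(all(diff(g$individuals$dominance) < 0))
  expect_equal(sum(!is.na(g$like)), 380)
  expect_true(all(g$like[row(g$like) != col(g$like)] == g$dynamics$lower))
  # determinism
  g2 <- init_group(20, seed = 3)
  expect_identical(g$individuals, g2$individuals)
  expect_error(init_group(1), "at least 2")
})

test_that("fear is the normalized upward dominance gap", {
  expect_equal(fear_value(1.0, 1.0), 0)
  expect_equal(fear_value(0.05, 1.0), 1.0)
  expect_equal(fear_value(1.0, 0.05), 0)
  # monotone in the gap
  gaps <- fear_value(0.3, seq(0.3, 1, by = 0.1))
  expect_true(all(diff(gaps) > 0))
})

test_that("partner_weights mixes uniform and LIKE-proportional choice", {
  expect_equal(partner_weights(c(0.3, 0.7, 0.1), 0), rep(1 / 3, 3))
  expect_equal(partner_weights(c(0.2, 0.8), 1), c(0.2, 0.8))
  expect_equal(partner_weights(c(0.2, 0.8), 0.5), c(0.4, 0.6))
  # monotone non-decreasing in like, for every selectivity level
  for (lps in c(0.5, 0.9, 0.95, 0.99)) {
    w <- partner_weights(seq(0.01, 0.99, length.out = 10), lps)
    expect_true(all(diff(w) >= 0))
    expect_equal(sum(w), 1)
  }
  expect_error(partner_weights(numeric(0), 0.5), "empty")
  expect_error(partner_weights(0.5, 1.2), "lps")
})

test_that("select_behavior gates on arousal and falls back to movement", {
  g <- init_group(20, seed = 1)
  g$individuals$myAROUSAL[1] <- 0
  set.seed(1)
  for (i in 1:20)
    expect_equal(select_behavior(1, g, perceived = 2:5)$action, "rest")
  g$individuals$myAROUSAL[1] <- 1
  set.seed(1)
  expect_equal(select_behavior(1, g, perceived = integer(0))$action,
               "random_walk")
})

test_that("realized grooming-partner frequencies follow partner_weights", {
  g <- init_group(5, seed = 2)
  # focal is the top-ranked individual: fear = 0 toward everyone
  g$individuals$myAROUSAL[1] <- 1
  g$individuals$mySATISFACTION[1] <- 0
  # all candidates in reach
  g$individuals$x <- rep(10, 5)
  g$individuals$y <- 10 + c(0, 0.2, 0.4, 0.6, 0.8)
  g$like[1, 2:5] <- c(0.9, 0.01, 0.01, 0.01)
  g$like_ts[] <- 0
  g$time <- 0
  cfg <- behavior_config(lps = 0.99, agonism_p = 0)
  set.seed(8)
  draws <- replicate(10000, {
    b <- select_behavior(1, g, perceived = 2:5, cfg)
    if (b$action == "groom") b$target else NA_integer_
  })
  draws <- draws[!is.na(draws)]
  freq <- tabulate(draws, 5)[2:5] / length(draws)
  want <- partner_weights(c(0.9, 0.01, 0.01, 0.01), 0.99)
  # binomial error at n ~ several thousand
  se <- sqrt(want * (1 - want) / length(draws))
  expect_true(all(abs(freq - want) < 4 * se + 0.01))
})

test_that("grooming raises only the receiver's LIKE toward the actor", {
  g <- init_group(4, seed = 4, dynamics = make_dynamics("alternative", "fast", 2880))
  g$individuals$x <- rep(1, 4)
  g$individuals$y <- c(1, 1.5, 50, 60)
  before <- g$like
  g2 <- execute_grooming(g, actor = 1, receiver = 2, minutes = 10)
  # receiver's valuation of the actor: minimum to maximum in 10 fast minutes
  expect_equal(g2$like[2, 1], 0.99)
  # the actor's own valuation of the receiver is untouched
  expect_equal(g2$like[1, 2], before[1, 2])
  # no third-party valuation was touched
  untouched <- !(row(before) == 2 & col(before) == 1)
  expect_identical(g2$like[untouched], before[untouched])
  expect_equal(g2$grooming_minutes[1, 2], 10)
  expect_equal(g2$grooming_minutes[2, 1], 0)
  expect_equal(g2$individuals$mySATISFACTION[2],
               behavior_config()$satisfaction_gain * 10)

  expect_error(execute_grooming(g, 1, 3, 10), "within reach")
  expect_error(execute_grooming(g, 1, 2, 0), "at least 1")
})

test_that("agonism never touches the LIKE matrix", {
  g <- init_group(6, seed = 5)
  before_like <- g$like
  before_ts <- g$like_ts
  g2 <- execute_agonism(g, actor = 1, receiver = 4)
  expect_identical(g2$like, before_like)
  expect_identical(g2$like_ts, before_ts)
  expect_equal(g2$individuals$myANXIETY[4], behavior_config()$anxiety_gain)
  expect_equal(g2$individuals$last_aggressor[4], 1)

  # anxiety is clipped at 1 under repeated attacks
  for (k in 1:10) g2 <- execute_agonism(g2, 1, 4)
  expect_equal(g2$individuals$myANXIETY[4], 1)
  expect_identical(g2$like, before_like)

  # a submissive signal carries no anxiety cost for its receiver
  g3 <- execute_agonism(g, actor = 6, receiver = 1, signal = "submissive_signal")
  expect_equal(g3$individuals$myANXIETY[1], 0)
})

test_that("emotional states and LIKE stay in range over many random events", {
  d <- make_dynamics("dynamics4", "fast", 180)
  set.seed(11)
  v <- runif(1e5, d$lower, d$upper)
  sat <- runif(1e5)
  for (k in 1:10) {
    v <- if (k %% 2) groom_increase(v, rexp(1e5, 1 / 10), d)
         else idle_decay(v, rexp(1e5, 1 / 500), d)
    sat <- pmin(1, pmax(0, sat + runif(1e5, -0.3, 0.3)))
  }
  expect_true(all(v >= d$lower & v <= d$upper))
  expect_true(all(sat >= 0 & sat <= 1))
})
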