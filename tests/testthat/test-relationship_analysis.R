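test_that("second-year averaging selects the right window", {
  n <- 4
  mk <- function(v) { m <- matrix(v, n, n); diag(m) <- NA; m }
  samples <- simplify2array(lapply(c(0.2, 0.2, 0.8, 0.8), mk))
  times <- c(0, 100, 300, 400)
  expect_equal(second_year_mean(samples, times)[1, 2], 0.8)

  # constant samples return the constant
  const <- simplify2array(lapply(rep(0.42, 6), mk))
  expect_equal(second_year_mean(const, seq(0, 500, 100))[2, 1], 0.42)

  # per-dyad linear ramp: window mean is the midpoint of the second segment
  ramps <- simplify2array(lapply(seq(0, 1, length.out = 11), mk))
  got <- second_year_mean(ramps, seq(0, 1000, 100))[1, 2]
  expect_equal(got, mean(seq(0.5, 1, by = 0.1)))

  expect_error(second_year_mean(samples, times, window = c(1000, 2000)),
               "window")
})

test_that("categorization uses the printed boundary conventions", {
  m <- matrix(0.5, 20, 20)
  cs <- categorize(m)
  expect_equal(c(cs$n_high, cs$n_intermediate, cs$n_low), c(0, 380, 0))
  expect_equal(cs$mean_like_intermediate, 0.5)
  expect_true(is.na(cs$mean_like_high))

  # boundary values: 0.75 is high, 0.25 is low
  m2 <- matrix(0.5, 5, 5)
  m2[1, 2] <- 0.75
  m2[1, 3] <- 0.25
  cs2 <- categorize(m2)
  expect_equal(cs2$n_high, 1)
  expect_equal(cs2$n_low, 1)
  expect_equal(cs2$n_high + cs2$n_intermediate + cs2$n_low, 20)

  # partition property on random matrices
  set.seed(12)
  for (k in 1:20) {
    r <- matrix(runif(400), 20, 20)
    cr <- categorize(r)
    expect_equal(cr$n_high + cr$n_intermediate + cr$n_low, 380)
    if (cr$n_high > 0) expect_gte(cr$mean_like_high, 0.75)
    if (cr$n_low > 0) expect_lte(cr$mean_like_low, 0.25)
  }
})

test_that("transition R-squared is a squared dyadic Pearson correlation", {
  set.seed(13)
  a <- matrix(runif(400), 20, 20)
  expect_equal(transition_r2(a, a), 1)
  expect_equal(transition_r2(a, 0.5 * a + 0.1), 1)
  expect_equal(transition_r2(a, -2 * a + 3), 1) # affine invariance, any sign
  b <- matrix(runif(400), 20, 20)
  expect_equal(transition_r2(a, b), transition_r2(b, a))
  off <- row(a) != col(a)
  expect_equal(transition_r2(a, b), cor(a[off], b[off])^2)
  expect_true(is.na(transition_r2(a, matrix(0.5, 20, 20))))
  expect_error(transition_r2(a, matrix(0, 5, 5)), "identical dimensions")
})

test_that("stability_score averages the four consecutive transitions", {
  a <- matrix(runif(400), 20, 20)
  s <- stability_score(rep(list(a), 5))
  expect_equal(length(s$transition_r2), 4)
  expect_equal(s$mean_r2, 1)

  # alternating uncorrelated patterns sit near the null level
  set.seed(14)
  vals <- replicate(50, {
    p1 <- matrix(runif(400), 20, 20)
    p2 <- matrix(runif(400), 20, 20)
    stability_score(list(p1, p2, p1, p2, p1))$mean_r2
  })
  expect_lt(mean(vals), 3 / 379)

  expect_error(stability_score(list(a)), "at least 2")
  expect_warning(stability_score(list(a, matrix(0.2, 20, 20), a)),
                 "undefined")
})

test_that("planted fixture structure is recovered by the analysis suite", {
  snaps <- generate_fixture_snapshots(n = 20, n_high_per_individual = 2,
                                      persistence = 1, noise_sd = 0,
                                      seed = 21)
  expect_equal(stability_score(snaps)$mean_r2, 1)
  cs <- categorize(snaps[[1]])
  expect_equal(cs$n_high, 40)
  expect_equal(cs$n_low, 340)

  # AR(1) persistence maps to mean transition R2 ~ rho^2
  for (rho in c(0.5, 0.9)) {
    set.seed(22)
    r2s <- sapply(1:40, function(k)
      stability_score(generate_fixture_snapshots(20, 2, rho, 0, seed = 1000 + k))$mean_r2)
    expect_lt(abs(mean(r2s) - rho^2), 0.05)
  }
})

test_that("dyadic matrices round-trip through CSV and stability through JSON", {
  m <- matrix(runif(400), 20, 20)
  diag(m) <- NA
  p <- tempfile(fileext = ".csv")
  write_dyadic_csv(m, p)
  expect_equal(read_dyadic_csv(p), m, tolerance = 1e-12)

  s <- stability_score(generate_fixture_snapshots(10, 2, 0.8, 0.01, seed = 2))
  j <- tempfile(fileext = ".json")
  write_stability_json(s, j)
  back <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(back$mean_r2, s$mean_r2, tolerance = 1e-9)
  expect_equal(length(back$transition_r2), 4)
})

test_that("analyze_run bundles the full suite for a simulation run", {
  run <- tiny_run(seed = 33)
  res <- analyze_run(run)
  expect_equal(res$categories$n_dyads, 380)
  expect_equal(length(res$stability$transition_r2), 4)
  expect_equal(dim(res$second_year), c(20, 20))
})
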