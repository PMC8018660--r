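#' Calibrated LIKE bookkeeping dynamics
#'
#' Constructs the parameter set for one of the four partner-valuation
#' ("LIKE") bookkeeping dynamics. A LIKE value is a directed, dimensionless
#' valuation of one group member by another; it is raised by received
#' grooming and erodes during periods without grooming. The four dynamics
#' are the four combinations of increase and decrease curve shapes:
#'
#' * `original`: linear increase, exponential decrease;
#' * `alternative`: logistic increase, logistic decrease;
#' * `dynamics3`: linear increase, logistic decrease;
#' * `dynamics4`: logistic increase, exponential decrease.
#'
#' All constants are derived from two speed parameters with exact timing
#' semantics. `linc` (LIKE-increase speed) fixes the number of minutes of
#' uninterrupted grooming needed to raise LIKE from its minimum to its
#' maximum: 10 (`"fast"`), 30 (`"intermediate"`) or 60 (`"slow"`). `lhw`
#' (LIKE-history weight, minutes) fixes the decrease speed: exponential
#' decay halves the value every `lhw` minutes, and logistic decay starting
#' at the upper bound first reaches 0.5 after exactly `lhw` minutes.
#'
#' Purely linear/exponential bookkeeping (the original dynamics) operates on
#' the range \[0, 1\] with slope `a = 1/linc_period`; any dynamics with a
#' logistic component operates on \[0.01, 0.99\], since a logistic curve only
#' approaches its asymptotes. The logistic steepness constants follow from
#' the timing contracts: `k_inc = 2*log(99)/linc_period` and
#' `k_dec = log(99)/lhw`.
#'
#' `lhw = 0` selects special fast-decay rules rather than a degenerate
#' half-life: with exponential decrease the decay is linear at a rate that
#' empties the full range in 50 minutes; with logistic decrease `lhw = 0` is
#' mapped to `lhw = 25` (the matching very-fast setting).
#'
#' @param name Dynamics name: `"original"`, `"alternative"`, `"dynamics3"`
#'   or `"dynamics4"`.
#' @param linc Increase-speed level: `"fast"`, `"intermediate"` or `"slow"`,
#'   or directly the traversal time in minutes (10, 30 or 60).
#' @param lhw Decrease-speed parameter in minutes (`>= 0`).
#' @return An object of class `emo_dynamics`: a list with the curve kinds,
#'   the bounds, `linc_period`, `lhw`, and the derived constants `a`,
#'   `k_inc`, `k_dec`.
#' @examples
#' d <- make_dynamics("original", "fast", 720)
#' d$a                     # 0.1 LIKE per minute
#' groom_increase(0.5, 2, d)
#' idle_decay(0.8, 720, d) # halves in lhw minutes
#' @export
make_dynamics <- function(name = c("original", "alternative", "dynamics3", "dynamics4"),
                          linc = c("fast", "intermediate", "slow"),
                          lhw = 2880) {
  name <- match.arg(name)
  if (is.numeric(linc)) {
    if (!linc %in% c(10, 30, 60))
      stop("numeric `linc` must be one of 10, 30, 60 (minutes)", call. = FALSE)
    linc_period <- linc
  } else {
    linc <- match.arg(linc)
    linc_period <- c(fast = 10, intermediate = 30, slow = 60)[[linc]]
  }
  if (!is.numeric(lhw) || length(lhw) != 1L || is.na(lhw) || lhw < 0)
    stop("`lhw` must be a single non-negative number of minutes", call. = FALSE)

  increase_kind <- switch(name,
    original = "linear", dynamics3 = "linear",
    alternative = "logistic", dynamics4 = "logistic")
  decrease_kind <- switch(name,
    original = "exponential", dynamics4 = "exponential",
    alternative = "logistic", dynamics3 = "logistic")

  # logistic curves never touch 0/1, so any dynamics with a logistic
  # component lives on the clipped range [0.01, 0.99]
  logistic_any <- increase_kind == "logistic" || decrease_kind == "logistic"
  lower <- if (logistic_any) 0.01 else 0
  upper <- if (logistic_any) 0.99 else 1

  lhw_eff <- lhw
  lin_rate <- 0
  dec_kind_code <- if (decrease_kind == "exponential") 0L else 1L
  if (lhw == 0) {
    if (decrease_kind == "exponential") {
      # special rule: full range empties in exactly 50 minutes
      dec_kind_code <- 2L
      lin_rate <- (upper - lower) / 50
      lhw_eff <- NA_real_
    } else {
      lhw_eff <- 25
    }
  }

  structure(list(
    name = name,
    increase_kind = increase_kind,
    decrease_kind = decrease_kind,
    linc = if (is.character(linc)) linc else names(which(c(fast = 10, intermediate = 30, slow = 60) == linc_period)),
    linc_period = linc_period,
    lhw = lhw,
    lhw_eff = lhw_eff,
    lower = lower,
    upper = upper,
    a = if (increase_kind == "linear") (upper - lower) / linc_period else 0,
    k_inc = if (increase_kind == "logistic") 2 * log(99) / linc_period else 0,
    k_dec = if (decrease_kind == "logistic") log(99) / (if (lhw == 0) 25 else lhw) else 0,
    lin_rate = lin_rate,
    inc_kind = if (increase_kind == "linear") 0L else 1L,
    dec_kind = dec_kind_code
  ), class = "emo_dynamics")
}

#' @export
print.emo_dynamics <- function(x, ...) {
  cat(sprintf("<emo_dynamics> %s: %s increase, %s decrease\n",
              x$name, x$increase_kind, x$decrease_kind))
  cat(sprintf("  bounds [%g, %g], linc %s (%g min min->max), lhw %g min\n",
              x$lower, x$upper, x$linc, x$linc_period, x$lhw))
  consts <- c(a = x$a, k_inc = x$k_inc, k_dec = x$k_dec, lin_rate = x$lin_rate)
  consts <- consts[consts != 0]
  cat("  constants:", paste(sprintf("%s = %.6g", names(consts), consts), collapse = ", "), "\n")
  invisible(x)
}

check_dynamics <- function(params) {
  if (!inherits(params, "emo_dynamics"))
    stop("`params` must be created by make_dynamics()", call. = FALSE)
  params
}

#' Raise a LIKE value by a period of received grooming
#'
#' Applies the calibrated increase curve for `minutes` of uninterrupted
#' received grooming. The linear rule adds `a * minutes`; the logistic rule
#' inverts the increasing sigmoid at the current value (closed-form logit),
#' advances the effective time by `minutes` and re-evaluates. The result is
#' clipped to the dynamics' upper bound. Composing two updates over split
#' durations equals one update over the summed duration.
#'
#' @param like Current LIKE value(s), within the dynamics bounds.
#' @param minutes Non-negative grooming duration(s) in minutes.
#' @param params An [make_dynamics()] object.
#' @return Updated LIKE value(s), never above the upper bound.
#' @export
groom_increase <- function(like, minutes, params) {
  check_dynamics(params)
  if (any(minutes < 0)) stop("`minutes` must be non-negative", call. = FALSE)
  emo_increase_cpp(as.numeric(like), as.numeric(minutes), params)
}

#' Erode a LIKE value over a period without grooming
#'
#' Applies the calibrated decrease curve over `minutes` without grooming.
#' Exponential decay multiplies by `0.5^(minutes/lhw)`; logistic decay
#' inverts the decreasing sigmoid at the current value and advances it;
#' the `lhw = 0` rule for exponential dynamics decays linearly so the full
#' range empties in 50 minutes. Results are floored at the lower bound.
#' The update satisfies the semigroup law (decaying t1 then t2 equals
#' decaying t1 + t2), which is what makes lazy timestamped evaluation in the
#' simulation engine exact.
#'
#' @inheritParams groom_increase
#' @param minutes Non-negative idle duration(s) in minutes.
#' @return Updated LIKE value(s), never below the lower bound.
#' @export
idle_decay <- function(like, minutes, params) {
  check_dynamics(params)
  if (any(minutes < 0)) stop("`minutes` must be non-negative", call. = FALSE)
  emo_decay_cpp(as.numeric(like), as.numeric(minutes), params)
}

#' Time for a LIKE value to travel between two levels
#'
#' Closed-form inverse of [groom_increase()] / [idle_decay()]: the smallest
#' number of minutes after which the update maps `from` onto `to`. Used for
#' calibration checks (e.g. the min-to-max traversal time must equal the
#' LINC period, and exponential decay must halve any value in `lhw` minutes).
#'
#' @param from Starting LIKE value.
#' @param to Target LIKE value, within bounds.
#' @param mode `"increase"` (grooming) or `"decrease"` (idle decay).
#' @param params An [make_dynamics()] object.
#' @return Travel time in minutes.
#' @export
time_to_reach <- function(from, to, mode = c("increase", "decrease"), params) {
  mode <- match.arg(mode)
  check_dynamics(params)
  if (from == to) stop("`from` and `to` must differ", call. = FALSE)
  if (to < params$lower - 1e-12 || to > params$upper + 1e-12)
    stop("`to` is outside the dynamics bounds", call. = FALSE)
  logit <- function(p) log(p / (1 - p))
  if (mode == "increase") {
    if (to < from) stop("increase cannot reach a lower target", call. = FALSE)
    if (params$increase_kind == "linear") {
      (to - from) / params$a
    } else {
      p0 <- pmin(pmax(from, 1e-12), 1 - 1e-12)
      p1 <- pmin(pmax(to, 1e-12), 1 - 1e-12)
      (logit(p1) - logit(p0)) / params$k_inc
    }
  } else {
    if (to > from) stop("decrease cannot reach a higher target", call. = FALSE)
    if (params$dec_kind == 2L) {
      (from - to) / params$lin_rate
    } else if (params$decrease_kind == "exponential") {
      if (to <= 0) stop("exponential decay never reaches zero", call. = FALSE)
      params$lhw_eff * log2(from / to)
    } else {
      p0 <- pmin(pmax(from, 1e-12), 1 - 1e-12)
      p1 <- pmin(pmax(to, 1e-12), 1 - 1e-12)
      (logit(p0) - logit(p1)) / params$k_dec
    }
  }
}

#' Tabulate LIKE trajectories for plotting
#'
#' Evaluates the increase curve (from the lower bound, uninterrupted
#' grooming) and the decrease curve (from the upper bound, no grooming) on a
#' minute grid, for inspection or plotting of the curve shapes.
#'
#' @param params An [make_dynamics()] object.
#' @param minutes Numeric vector of elapsed minutes.
#' @return A data frame with columns `dynamics`, `linc`, `lhw`, `minute`,
#'   `mode`, `like`.
#' @export
like_curve <- function(params, minutes) {
  check_dynamics(params)
  rbind(
    data.frame(dynamics = params$name, linc = params$linc, lhw = params$lhw,
               minute = minutes, mode = "increase",
               like = vapply(minutes, function(m) groom_increase(params$lower, m, params), 0)),
    data.frame(dynamics = params$name, linc = params$linc, lhw = params$lhw,
               minute = minutes, mode = "decrease",
               like = vapply(minutes, function(m) idle_decay(params$upper, m, params), 0))
  )
}
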