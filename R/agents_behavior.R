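#' Default behaviour-engine configuration
#'
#' Tunable constants of the behaviour engine. The partner-selectivity level
#' `lps` is the probability weight LIKE receives in grooming-partner choice
#' (0 = indifferent, 1 = fully LIKE-proportional); the study grid uses 0.5,
#' 0.9, 0.95 and 0.99. The remaining constants shape the emotional state
#' couplings and activity levels; they are qualitative in origin and kept
#' configurable.
#'
#' @param lps LIKE-partner selectivity in `[0, 1]`.
#' @param groom_continue_p Per-minute probability a grooming bout continues
#'   (geometric bout length, expected 10 min at 0.9).
#' @param satisfaction_gain Satisfaction gained per received grooming
#'   minute. Satisfaction gates grooming motivation and lets satiated
#'   receivers decline bouts, so this constant sets the group's grooming
#'   tempo; the default is calibrated so that bond formation and decay
#'   complete within the recording protocol across the full decrease-speed
#'   range.
#' @param satisfaction_halflife Relaxation half-life of satisfaction (min).
#' @param anxiety_gain Anxiety gained per received aggression.
#' @param anxiety_halflife Relaxation half-life of anxiety (min).
#' @param arousal_baseline Resting level of arousal (probability of choosing
#'   an active behaviour on activation).
#' @param arousal_halflife Relaxation half-life of arousal excursions (min).
#' @param arousal_bump Arousal gained from taking part in an interaction.
#' @param agonism_p Probability an active decision initiates agonism toward
#'   a lower-ranked visible individual.
#' @param leave_radius Distance (grid units) within which a satiated
#'   individual moves away from its nearest neighbour instead of resting.
#' @param cohesion_radius Distance (grid units) beyond which an unmotivated
#'   individual drifts back toward its nearest visible neighbour, keeping
#'   the group spatially coherent.
#' @param pscan Probability per activation of a 360-degree scan.
#' @param view_angle Default view angle (degrees).
#' @param perception_radius Perception radius (grid units).
#' @param grooming_reach Maximum distance for grooming ("arm's reach").
#' @param step_length Movement step per minute (grid units).
#' @return An object of class `emo_behavior_config`.
#' @export
behavior_config <- function(lps = 0.99,
                            groom_continue_p = 0.9,
                            satisfaction_gain = 0.002,
                            satisfaction_halflife = 180,
                            anxiety_gain = 0.2,
                            anxiety_halflife = 120,
                            arousal_baseline = 0.5,
                            arousal_halflife = 60,
                            arousal_bump = 0.1,
                            agonism_p = 0.02,
                            leave_radius = 5,
                            cohesion_radius = 20,
                            pscan = 0.2,
                            view_angle = 120,
                            perception_radius = 50,
                            grooming_reach = 1,
                            step_length = 1) {
  stopifnot(lps >= 0, lps <= 1, groom_continue_p >= 0, groom_continue_p < 1)
  structure(as.list(environment()), class = "emo_behavior_config")
}

#' Fixed partner-specific FEAR
#'
#' FEAR is a fixed, directed attitude determined by the dominance gap in a
#' dyad, consistent with a stable hierarchy: zero toward equally or
#' lower-ranked partners and scaled by the maximum possible dominance
#' difference (1.0 - 0.05 = 0.95) so the lowest-ranked individual fears the
#' highest-ranked maximally.
#'
#' @param dom_self,dom_other Dominance strengths in `(0, 1]`.
#' @return FEAR in `[0, 1]`, vectorized.
#' @export
fear_value <- function(dom_self, dom_other) {
  pmax(0, dom_other - dom_self) / 0.95
}

#' Initialize a group
#'
#' Creates `n` identical primate-like individuals (no variation in sex or
#' age) on uniformly random torus positions, with a fixed linear dominance
#' ladder: dominance of the rank-`r` individual is `(n + 1 - r)/n`, so for
#' `n = 20` it spans 1.0 (rank 1, highest) down to 0.05 (rank 20). All
#' directed LIKE values start at the dynamics' lower bound and the fixed
#' FEAR matrix is precomputed from the dominance gaps.
#'
#' @param n Group size (`>= 2`).
#' @param seed Integer seed for reproducible placement.
#' @param dynamics An [make_dynamics()] object (sets the LIKE lower bound).
#' @param world An [world_config()] object.
#' @return A group state: list with `individuals` (data frame), `like`,
#'   `like_ts`, `fear`, `grooming_minutes` matrices, `time`, `world`.
#' @export
init_group <- function(n = 20, seed = 1,
                       dynamics = make_dynamics("original", "fast", 720),
                       world = world_config()) {
  if (!is.numeric(n) || n < 2) stop("`n` must be at least 2", call. = FALSE)
  n <- as.integer(n)
  set.seed(seed)
  rank <- seq_len(n)
  dominance <- (n + 1 - rank) / n
  individuals <- data.frame(
    id = seq_len(n),
    rank = rank,
    dominance = dominance,
    x = stats::runif(n, 0, world$width),
    y = stats::runif(n, 0, world$height),
    heading = stats::runif(n, 0, 2 * pi),
    myTIME = 0,
    myPscan = 0.2,
    myVIEW_ANGLE = 120,
    myAROUSAL = 0.5,
    myANXIETY = 0,
    mySATISFACTION = 0,
    last_aggressor = NA_integer_
  )
  fear <- outer(dominance, dominance, function(ds, dother) fear_value(ds, dother))
  diag(fear) <- 0
  like <- matrix(dynamics$lower, n, n)
  diag(like) <- NA_real_
  list(
    individuals = individuals,
    like = like,
    like_ts = matrix(0, n, n),
    fear = fear,
    grooming_minutes = matrix(0, n, n),
    dynamics = dynamics,
    time = 0,
    world = world
  )
}

#' Grooming-partner choice probabilities
#'
#' Mixes an indifferent (uniform) component with a LIKE-proportional
#' component: the unnormalized weight of candidate `j` is
#' `(1 - lps) + lps * like_j`, normalized to sum to one. `lps = 0` gives the
#' uniform distribution, `lps = 1` LIKE-proportional choice, and the
#' probability of any candidate is non-decreasing in its LIKE value.
#'
#' @param like_row LIKE values toward the candidates (length `>= 1`).
#' @param lps Selectivity in `[0, 1]`.
#' @return Normalized probability vector.
#' @export
partner_weights <- function(like_row, lps) {
  if (length(like_row) == 0) stop("empty candidate set", call. = FALSE)
  if (lps < 0 || lps > 1) stop("`lps` must be in [0, 1]", call. = FALSE)
  w <- (1 - lps) + lps * like_row
  w / sum(w)
}

#' Select the next behaviour of an activated individual
#'
#' The decision cascade of one activation. With probability `myAROUSAL` an
#' active behaviour is drawn, otherwise the individual rests. An active
#' individual without visible others random-walks. Otherwise, with a small
#' probability agonism is directed at a random lower-ranked visible
#' individual. Grooming motivation is gated by satisfaction: with
#' probability `mySATISFACTION` the individual is satiated and instead
#' leaves its nearest neighbour (when crowded) or rests. A motivated
#' individual draws a grooming partner from the visible candidates with
#' [partner_weights()] probabilities, damped by FEAR toward the chosen
#' partner (a fearful draw becomes avoidance); the chosen partner is
#' groomed when within reach and approached when not.
#'
#' @param me Row index of the activated individual.
#' @param state Group state from [init_group()].
#' @param perceived Integer indices of currently visible individuals.
#' @param cfg An [behavior_config()] object.
#' @return A list with `action` (one of `"groom"`, `"affiliative_signal"`,
#'   `"attack"`, `"aggressive_signal"`, `"submissive_signal"`, `"approach"`,
#'   `"leave"`, `"avoid"`, `"random_walk"`, `"rest"`) and `target` (index or
#'   `NA`).
#' @export
select_behavior <- function(me, state, perceived, cfg = behavior_config()) {
  ind <- state$individuals
  if (stats::runif(1) >= ind$myAROUSAL[me])
    return(list(action = "rest", target = NA_integer_))
  if (length(perceived) == 0)
    return(list(action = "random_walk", target = NA_integer_))
  if (stats::runif(1) < cfg$agonism_p) {
    lower <- perceived[ind$dominance[perceived] < ind$dominance[me]]
    if (length(lower) > 0) {
      target <- if (length(lower) == 1) lower else sample(lower, 1)
      return(list(action = "attack", target = target))
    }
  }
  if (stats::runif(1) < ind$mySATISFACTION[me]) {
    d_all <- torus_distance(ind$x[me], ind$y[me], ind$x[perceived], ind$y[perceived],
                            state$world)
    nearest <- perceived[which.min(d_all)]
    if (min(d_all) <= cfg$leave_radius)
      return(list(action = "leave", target = nearest))
    if (min(d_all) > cfg$cohesion_radius)
      return(list(action = "approach", target = nearest))
    return(list(action = "rest", target = NA_integer_))
  }
  # a candidate is encountered uniformly at random; the affiliative act
  # proceeds with probability (1 - lps) + lps * LIKE, so realized grooming
  # partners follow the normalized partner_weights() mixture
  target <- if (length(perceived) == 1) perceived else sample(perceived, 1)
  like_t <- lazy_like(state, me, target, state$time)
  if (stats::runif(1) >= (1 - cfg$lps) + cfg$lps * like_t)
    return(list(action = "rest", target = NA_integer_))
  # fear-driven avoidance is anxiety-modulated: a mild baseline plus a
  # strong component when the actor is anxious
  p_avoid <- state$fear[me, target] * (0.2 + 0.8 * ind$myANXIETY[me])
  if (stats::runif(1) < p_avoid)
    return(list(action = "avoid", target = target))
  d <- torus_distance(ind$x[me], ind$y[me], ind$x[target], ind$y[target], state$world)
  if (d <= cfg$grooming_reach)
    list(action = "groom", target = target)
  else
    list(action = "approach", target = target)
}

#' Apply a grooming bout to the group state
#'
#' Received grooming is what drives emotional bookkeeping: the receiver's
#' LIKE toward the actor is first decayed lazily up to the bout start and
#' then advanced by [groom_increase()] over the bout duration; the
#' receiver's satisfaction rises by `satisfaction_gain` per minute (clipped
#' at 1); the directed grooming-minutes matrix is incremented. No other
#' dyad's LIKE is touched (they continue to decay lazily), and the actor's
#' own LIKE toward the receiver is unaffected except by that lazy decay.
#'
#' @param state Group state.
#' @param actor,receiver Indices of groomer and groomee.
#' @param minutes Bout duration (`>= 1`).
#' @param cfg An [behavior_config()] object.
#' @return The updated group state (time advanced by `minutes` for the pair).
#' @export
execute_grooming <- function(state, actor, receiver, minutes, cfg = behavior_config()) {
  ind <- state$individuals
  d <- torus_distance(ind$x[actor], ind$y[actor], ind$x[receiver], ind$y[receiver], state$world)
  if (d > cfg$grooming_reach)
    stop("grooming requires the pair to be within reach", call. = FALSE)
  if (minutes < 1) stop("grooming bouts last at least 1 minute", call. = FALSE)
  now <- state$time
  v0 <- idle_decay(state$like[receiver, actor], now - state$like_ts[receiver, actor],
                   state$dynamics)
  state$like[receiver, actor] <- groom_increase(v0, minutes, state$dynamics)
  state$like_ts[receiver, actor] <- now + minutes
  state$grooming_minutes[actor, receiver] <-
    state$grooming_minutes[actor, receiver] + minutes
  state$individuals$mySATISFACTION[receiver] <-
    min(1, ind$mySATISFACTION[receiver] + cfg$satisfaction_gain * minutes)
  state$individuals$myTIME[c(actor, receiver)] <- now + minutes
  state
}

#' Apply an agonistic interaction to the group state
#'
#' Agonism raises the receiver's anxiety and primes an avoidance response
#' on its next activation, but never touches the LIKE matrix: partner
#' valuations are influenced by affiliative behaviour only. A submissive
#' signal from a lower-ranked individual carries no anxiety cost for the
#' higher-ranked receiver.
#'
#' @param state Group state.
#' @param actor,receiver Indices of aggressor and victim.
#' @param cfg An [behavior_config()] object.
#' @param signal One of `"attack"`, `"aggressive_signal"`,
#'   `"submissive_signal"`.
#' @return The updated group state.
#' @export
execute_agonism <- function(state, actor, receiver, cfg = behavior_config(),
                            signal = "attack") {
  if (signal %in% c("attack", "aggressive_signal")) {
    state$individuals$myANXIETY[receiver] <-
      min(1, state$individuals$myANXIETY[receiver] + cfg$anxiety_gain)
    state$individuals$last_aggressor[receiver] <- actor
  }
  # submissive signals are acknowledgements; no anxiety gain for the receiver
  state
}

#' Read LIKE values with lazy decay
#'
#' Returns the current LIKE of `actor` toward `partners` at time `now`,
#' applying [idle_decay()] over the gap since each dyad's last update
#' without advancing the stored timestamps (reading is free of side
#' effects). By the decay semigroup law this equals eager per-minute decay.
#'
#' @param state Group state.
#' @param actor Focal index.
#' @param partners Indices of partners to read.
#' @param now Current time (minutes, `>=` the stored timestamps).
#' @return Numeric vector of current LIKE values.
#' @export
lazy_like <- function(state, actor, partners, now) {
  gaps <- now - state$like_ts[actor, partners]
  if (any(gaps < 0)) stop("time reversal in lazy LIKE read", call. = FALSE)
  idle_decay(state$like[actor, partners], gaps, state$dynamics)
}
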