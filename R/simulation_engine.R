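#' Stabilization period before data recording
#'
#' A slower LIKE decrease (higher `lhw`) needs a longer burn-in before the
#' attitude matrix reaches its regime: the stabilization period is at least
#' 6000 minutes and `30 * lhw` for high `lhw`.
#'
#' @param lhw LIKE-history weight in minutes (`>= 0`).
#' @return Stabilization length in minutes: `max(6000, 30 * lhw)`.
#' @export
stabilization_length <- function(lhw) {
  stopifnot(lhw >= 0)
  pmax(6000, 30 * lhw)
}

#' Assemble a simulation run configuration
#'
#' Bundles dynamics, selectivity, seed and schedule into a validated run
#' configuration. Defaults reproduce the full study protocol: 20
#' individuals, a stabilization period of `max(6000, 30 * lhw)` minutes,
#' a 2-year recording period (504000 minutes at 720 min/day, 350 days/year)
#' with 5 LIKE snapshots separated by half a year, daily LIKE samples for
#' second-year averaging, and proximity sampled every 10 minutes within a
#' 2-unit radius. `scale` divides the stabilization and recording durations
#' and all sampling/snapshot spacings proportionally for desk-scale runs;
#' the attitude dynamics themselves are never rescaled.
#'
#' @param dynamics Dynamics name passed to [make_dynamics()], or an
#'   `emo_dynamics` object (in which case `linc`/`lhw` are ignored).
#' @param linc,lhw Speed parameters for [make_dynamics()].
#' @param lps LIKE-partner selectivity in `[0, 1]`.
#' @param seed Integer seed; every stochastic draw in the run flows from it.
#' @param n Number of individuals.
#' @param scale Duration scale factor in `(0, 1]`.
#' @param recording_minutes Recording length before scaling.
#' @param like_sample_interval,proximity_sample_interval Sampling intervals
#'   in minutes (before scaling).
#' @param proximity_radius Proximity criterion in grid units.
#' @param cfg An [behavior_config()] object; its `lps` is overridden by
#'   `lps`.
#' @param world An [world_config()] object.
#' @return An object of class `emo_run_config`.
#' @export
run_config <- function(dynamics = "original", linc = "fast", lhw = 720,
                       lps = 0.99, seed = 1, n = 20, scale = 1,
                       recording_minutes = 504000,
                       like_sample_interval = 1440,
                       proximity_sample_interval = 10,
                       proximity_radius = 2,
                       cfg = behavior_config(),
                       world = world_config()) {
  dyn <- if (inherits(dynamics, "emo_dynamics")) dynamics
         else make_dynamics(dynamics, linc, lhw)
  stopifnot(scale > 0, scale <= 1, lps >= 0, lps <= 1, n >= 2)
  stab <- stabilization_length(dyn$lhw) * scale
  rec <- recording_minutes * scale
  structure(list(
    dynamics = dyn,
    lps = lps,
    seed = as.integer(seed),
    n = as.integer(n),
    scale = scale,
    stabilization_minutes = stab,
    recording_minutes = rec,
    snapshot_times = seq(0, rec, length.out = 5),
    like_sample_interval = max(1, like_sample_interval * scale),
    proximity_sample_interval = max(1, proximity_sample_interval * scale),
    proximity_radius = proximity_radius,
    behavior = cfg,
    world = world
  ), class = "emo_run_config")
}

#' @export
print.emo_run_config <- function(x, ...) {
  cat(sprintf("<emo_run_config> %s / %s / lhw %g / lps %g, seed %d\n",
              x$dynamics$name, x$dynamics$linc, x$dynamics$lhw, x$lps, x$seed))
  cat(sprintf("  n = %d, stabilization %g min, recording %g min (scale %g)\n",
              x$n, x$stabilization_minutes, x$recording_minutes, x$scale))
  invisible(x)
}

#' Run one simulation
#'
#' Executes the event-driven loop: the individual with the smallest
#' activation clock acts next (ties broken by index), resolves its
#' perception and behaviour, and is rescheduled one minute later, except
#' that grooming bouts occupy both partners for the bout duration. LIKE
#' values are stored with per-dyad last-update timestamps and decayed
#' lazily on read, which the decay semigroup law makes exactly equivalent
#' to eager per-minute decay. Recording structures are populated only after
#' the stabilization period. Runs are fully reproducible from the
#' configuration and seed.
#'
#' @param config An [run_config()] object.
#' @return An object of class `emo_run`: list with `snapshots` (5 realized
#'   LIKE matrices), `snapshot_times`, `like_samples` (n x n x samples
#'   array) and `like_sample_times` (relative to recording start),
#'   `grooming_minutes` (directed totals over the recording window),
#'   `proximity_rate` (symmetric fraction of samples within the proximity
#'   radius), `final_like`, `counters`, time-accounting vectors, and a
#'   `manifest` recording the full configuration.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "emo_run_config"))
  dyn <- config$dynamics
  b <- config$behavior
  n <- config$n
  dominance <- (n + 1 - seq_len(n)) / n
  fear <- outer(dominance, dominance, fear_value)
  diag(fear) <- 0
  like0 <- matrix(dyn$lower, n, n)
  diag(like0) <- 0 # unused, kept finite for the engine

  engine_cfg <- list(
    n = n, lps = config$lps,
    stabilization = config$stabilization_minutes,
    recording = config$recording_minutes,
    snapshot_times = config$snapshot_times,
    like_sample_interval = config$like_sample_interval,
    proximity_sample_interval = config$proximity_sample_interval,
    proximity_radius = config$proximity_radius,
    width = config$world$width, height = config$world$height,
    perception_radius = b$perception_radius,
    view_angle = b$view_angle, pscan = b$pscan,
    grooming_reach = b$grooming_reach,
    groom_continue_p = b$groom_continue_p,
    satisfaction_gain = b$satisfaction_gain,
    satisfaction_halflife = b$satisfaction_halflife,
    anxiety_gain = b$anxiety_gain, anxiety_halflife = b$anxiety_halflife,
    arousal_baseline = b$arousal_baseline, arousal_halflife = b$arousal_halflife,
    arousal_bump = b$arousal_bump, agonism_p = b$agonism_p,
    leave_radius = b$leave_radius,
    cohesion_radius = b$cohesion_radius,
    step_length = b$step_length,
    dominance = dominance, fear = fear, like0 = like0
  )

  set.seed(config$seed)
  out <- run_engine_cpp(unclass(dyn), engine_cfg)
  out$snapshots <- lapply(out$snapshots, identity)
  out$config <- config
  out$manifest <- list(
    package = "emobook",
    version = as.character(utils::packageVersion("emobook")),
    dynamics = dyn$name, linc = dyn$linc, lhw = dyn$lhw, lps = config$lps,
    seed = config$seed, n = n, scale = config$scale,
    stabilization_minutes = config$stabilization_minutes,
    recording_minutes = config$recording_minutes,
    snapshot_times = config$snapshot_times
  )
  class(out) <- "emo_run"
  out
}

#' @export
print.emo_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<emo_run> %s / %s / lhw %g / lps %g, seed %d\n",
              cfg$dynamics$name, cfg$dynamics$linc, cfg$dynamics$lhw,
              cfg$lps, cfg$seed))
  cat(sprintf("  %d snapshots, %d LIKE samples, %.0f grooming bouts\n",
              length(x$snapshots), length(x$like_sample_times),
              x$counters$bouts))
  invisible(x)
}
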