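#' Specify a parameter sweep
#'
#' The study grid crosses 2 dynamics (original, alternative), 3 increase
#' speeds, 6 decrease speeds and 4 selectivity levels: 144 cells, each run
#' with 2 independent replicates. A small extra subset probes the two
#' cross-combined dynamics (dynamics 3 and 4) at fast and slow increase,
#' `lhw = 2880` and `lps = 0.99`, run once each.
#'
#' @param dynamics,linc,lhw,lps Axis levels.
#' @param replicates Replicates per grid cell.
#' @param base_seed Base seed; per-run seeds are derived deterministically.
#' @param extra If `TRUE`, append the dynamics-3/4 subset.
#' @return An object of class `emo_sweep_spec`.
#' @export
sweep_spec <- function(dynamics = c("original", "alternative"),
                       linc = c("fast", "intermediate", "slow"),
                       lhw = c(0, 180, 720, 2880, 5400, 21600),
                       lps = c(0.5, 0.9, 0.95, 0.99),
                       replicates = 2,
                       base_seed = 20210402,
                       extra = TRUE) {
  if (!length(dynamics) || !length(linc) || !length(lhw) || !length(lps))
    stop("every sweep axis needs at least one level", call. = FALSE)
  structure(list(dynamics = dynamics, linc = linc, lhw = lhw, lps = lps,
                 replicates = replicates, base_seed = base_seed,
                 extra = extra),
            class = "emo_sweep_spec")
}

#' Expand a sweep specification into run configurations
#'
#' Full factorial product of the axes times the replicate count, plus the
#' dynamics-3/4 extra subset (single replicate), in a deterministic order.
#' Per-run seeds are derived reproducibly from the base seed and the row
#' index.
#'
#' @param spec An [sweep_spec()] object.
#' @return A data frame with one row per run: `cell`, `dynamics`, `linc`,
#'   `lhw`, `lps`, `replicate`, `seed`.
#' @export
build_grid <- function(spec = sweep_spec()) {
  stopifnot(inherits(spec, "emo_sweep_spec"))
  cells <- expand.grid(lps = spec$lps, lhw = spec$lhw, linc = spec$linc,
                       dynamics = spec$dynamics,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("dynamics", "linc", "lhw", "lps")]
  grid <- cells[rep(seq_len(nrow(cells)), each = spec$replicates), ]
  grid$replicate <- rep(seq_len(spec$replicates), nrow(cells))
  if (isTRUE(spec$extra)) {
    ext <- expand.grid(dynamics = c("dynamics3", "dynamics4"),
                       linc = c("fast", "slow"), lhw = 2880, lps = 0.99,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ext$replicate <- 1L
    grid <- rbind(grid, ext)
  }
  rownames(grid) <- NULL
  grid$cell <- paste(grid$dynamics, grid$linc, grid$lhw, grid$lps, sep = "_")
  # seeds below 2^31, deterministic in the row index
  grid$seed <- (spec$base_seed + 7919L * seq_len(nrow(grid))) %% .Machine$integer.max
  grid[, c("cell", "dynamics", "linc", "lhw", "lps", "replicate", "seed")]
}

#' Execute a sweep
#'
#' Runs every row of a grid (optionally duration-scaled), writing per-run
#' products (second-year mean LIKE, grooming and proximity matrices as CSV,
#' stability as JSON) and a sweep-level manifest. Completed cells, as
#' recorded in the manifest, are skipped on re-runs.
#'
#' @param grid Data frame from [build_grid()] (or a subset of its rows).
#' @param out_dir Output directory (created if needed).
#' @param scale Duration scale factor passed to [run_config()].
#' @param n Group size.
#' @param quiet Suppress per-run progress messages on stderr.
#' @return The manifest data frame, invisibly.
#' @export
run_sweep <- function(grid, out_dir, scale = 1, n = 20, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  done <- if (file.exists(manifest_path))
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)$run_id else character()
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    run_id <- sprintf("%s_rep%d_seed%d", g$cell, g$replicate, g$seed)
    if (run_id %in% done) next
    if (!quiet)
      message(sprintf("[%d/%d] %s", i, nrow(grid), run_id))
    cfg <- run_config(g$dynamics, g$linc, g$lhw, lps = g$lps, seed = g$seed,
                      n = n, scale = scale)
    t0 <- Sys.time()
    run <- run_simulation(cfg)
    res <- analyze_run(run)
    write_dyadic_csv(res$second_year, file.path(out_dir, paste0(run_id, "_like.csv")))
    write_dyadic_csv(run$grooming_minutes, file.path(out_dir, paste0(run_id, "_grooming.csv")))
    write_dyadic_csv(run$proximity_rate, file.path(out_dir, paste0(run_id, "_proximity.csv")))
    write_stability_json(res$stability, file.path(out_dir, paste0(run_id, "_stability.json")))
    rows[[length(rows) + 1]] <- data.frame(
      run_id = run_id, dynamics = g$dynamics, linc = g$linc, lhw = g$lhw,
      lps = g$lps, replicate = g$replicate, seed = g$seed, scale = scale,
      n_high = res$categories$n_high,
      n_intermediate = res$categories$n_intermediate,
      n_low = res$categories$n_low,
      mean_r2 = res$stability$mean_r2,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      version = as.character(utils::packageVersion("emobook")))
  }
  new_rows <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(new_rows)) {
    if (file.exists(manifest_path)) {
      old <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
      new_rows <- rbind(old, new_rows)
    }
    utils::write.csv(new_rows, manifest_path, row.names = FALSE)
  }
  invisible(if (is.null(new_rows) && file.exists(manifest_path))
    utils::read.csv(manifest_path, stringsAsFactors = FALSE) else new_rows)
}

#' Generate synthetic dyadic LIKE snapshots
#'
#' Fixture generator for exercising the analysis stage without simulation.
#' For each of `n` individuals, `n_high_per_individual` partners are
#' planted near the upper bound (0.9) and the remaining dyads near the
#' lower bound (0.05). Snapshots then evolve as a stationary AR(1) process
#' on the dyad deviations from the grand mean with per-transition
#' autocorrelation `persistence`, plus optional additive measurement noise,
#' clipped to `[0.01, 0.99]`. With `noise_sd = 0` the expected transition
#' R-squared is `persistence^2`; `persistence = 1, noise_sd = 0` gives
#' identical snapshots; `persistence = 0` gives independent snapshots at
#' the null R-squared level `1/(n*(n-1) - 1)`.
#'
#' @param n Individuals (`>= 2`).
#' @param n_high_per_individual Planted high-LIKE dyads per individual
#'   (`< n - 1`).
#' @param persistence AR(1) autocorrelation per transition, in `[0, 1]`.
#' @param noise_sd Additive Gaussian measurement noise (LIKE units).
#' @param seed Integer seed.
#' @param n_snapshots Number of snapshots to generate.
#' @return List of `n_snapshots` matrices (diagonal `NA`), with attributes
#'   `planted_high` (logical matrix) and the generator parameters.
#' @export
generate_fixture_snapshots <- function(n = 20, n_high_per_individual = 2,
                                       persistence = 0.9, noise_sd = 0.02,
                                       seed = 1, n_snapshots = 5) {
  if (n < 2 || n_high_per_individual >= n || n_high_per_individual < 0)
    stop("infeasible group size or planted-dyad count", call. = FALSE)
  if (persistence < 0 || persistence > 1)
    stop("`persistence` must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  planted <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    partners <- sample(setdiff(seq_len(n), i), n_high_per_individual)
    planted[i, partners] <- TRUE
  }
  base <- ifelse(planted, 0.9, 0.05)
  diag(base) <- NA_real_
  off <- row(base) != col(base)
  dev <- base[off] - mean(base[off])
  sd_dev <- stats::sd(dev)
  innov_sd <- sd_dev * sqrt(1 - persistence^2)
  snaps <- vector("list", n_snapshots)
  for (s in seq_len(n_snapshots)) {
    if (s > 1)
      dev <- persistence * dev + stats::rnorm(length(dev), 0, innov_sd)
    m <- base
    m[off] <- pmin(0.99, pmax(0.01,
      mean(base[off]) + dev + stats::rnorm(length(dev), 0, noise_sd)))
    snaps[[s]] <- m
  }
  attr(snaps, "planted_high") <- planted
  attr(snaps, "persistence") <- persistence
  attr(snaps, "noise_sd") <- noise_sd
  snaps
}
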