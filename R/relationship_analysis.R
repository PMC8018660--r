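#' Per-dyad mean LIKE over the second recording year
#'
#' Averages periodic LIKE samples over the second half of the recording
#' period (the "second year" under the full 2-year protocol; the window
#' scales with the recording length in scaled-down runs).
#'
#' @param samples An `n x n x s` array of LIKE samples (as in an
#'   `emo_run`), or a list of matrices.
#' @param times Sample times in minutes, relative to recording start.
#' @param window Length-2 numeric: the averaging window; defaults to the
#'   second half of the sampled span.
#' @return An `n x n` matrix of per-dyad means (diagonal `NA`).
#' @export
second_year_mean <- function(samples, times, window = NULL) {
  if (is.list(samples)) samples <- simplify2array(samples)
  stopifnot(length(dim(samples)) == 3, dim(samples)[3] == length(times))
  if (is.null(window)) window <- c(max(times) / 2, max(times))
  keep <- times >= window[1] & times <= window[2]
  if (!any(keep)) stop("no samples fall inside the averaging window", call. = FALSE)
  apply(samples[, , keep, drop = FALSE], c(1, 2), mean)
}

#' Categorize dyadic LIKE values by relationship quality
#'
#' Splits the directed off-diagonal dyads of a mean LIKE matrix into high
#' (`LIKE >= 0.75`), intermediate (`0.25 < LIKE < 0.75`) and low
#' (`LIKE <= 0.25`) quality, and reports the count and mean LIKE of each
#' category (mean is `NA` for an empty category). The three counts always
#' partition the `n * (n - 1)` directed dyads.
#'
#' @param matrix An `n x n` matrix of (mean) LIKE values; the diagonal is
#'   ignored.
#' @return An object of class `emo_categories`: list with `n_high`,
#'   `n_intermediate`, `n_low`, `mean_like_high`, `mean_like_intermediate`,
#'   `mean_like_low`, `n_dyads`.
#' @export
categorize <- function(matrix) {
  v <- offdiag(matrix)
  if (anyNA(v)) stop("off-diagonal LIKE values must not be missing", call. = FALSE)
  high <- v >= 0.75
  low <- v <= 0.25
  mid <- !high & !low
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  structure(list(
    n_high = sum(high), n_intermediate = sum(mid), n_low = sum(low),
    mean_like_high = mean_or_na(v[high]),
    mean_like_intermediate = mean_or_na(v[mid]),
    mean_like_low = mean_or_na(v[low]),
    n_dyads = length(v)
  ), class = "emo_categories")
}

#' @export
print.emo_categories <- function(x, ...) {
  cat(sprintf("<emo_categories> %d dyads: %d high (mean %.3g), %d intermediate (mean %.3g), %d low (mean %.3g)\n",
              x$n_dyads, x$n_high, x$mean_like_high,
              x$n_intermediate, x$mean_like_intermediate,
              x$n_low, x$mean_like_low))
  invisible(x)
}

offdiag <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[row(m) != col(m)]
}

#' Squared correlation between two dyadic snapshots
#'
#' The stability statistic for one transition: the squared Pearson
#' correlation over the vectors of all `n * (n - 1)` directed off-diagonal
#' dyads of two LIKE snapshot matrices. Invariant under affine rescaling of
#' either snapshot; returns `NA` when either snapshot has zero variance
#' across dyads (the statistic is then undefined).
#'
#' @param snap_a,snap_b Square matrices of equal dimension (`n >= 2`,
#'   at least 3 off-diagonal dyads).
#' @return R-squared in `[0, 1]`, or `NA`.
#' @export
transition_r2 <- function(snap_a, snap_b) {
  if (!all(dim(snap_a) == dim(snap_b)))
    stop("snapshots must have identical dimensions", call. = FALSE)
  a <- offdiag(snap_a)
  b <- offdiag(snap_b)
  if (length(a) < 3) stop("need at least 3 off-diagonal dyads", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Temporal stability of the LIKE distribution
#'
#' Computes the transition R-squared ([transition_r2()]) between each pair
#' of consecutive snapshots (under the full protocol: 5 snapshots half a
#' year apart, hence 4 transitions) and their arithmetic mean. Undefined
#' transitions (zero-variance snapshots) are excluded from the mean with a
#' warning.
#'
#' @param snapshots List of square LIKE matrices in time order (`>= 2`).
#' @param times Optional snapshot times (minutes).
#' @return An object of class `emo_stability`: list with `snapshot_times`,
#'   `transition_r2` (length `length(snapshots) - 1`) and `mean_r2`.
#' @export
stability_score <- function(snapshots, times = NULL) {
  if (!is.list(snapshots) || length(snapshots) < 2)
    stop("need at least 2 snapshots", call. = FALSE)
  k <- length(snapshots) - 1
  r2 <- vapply(seq_len(k), function(i)
    transition_r2(snapshots[[i]], snapshots[[i + 1]]), 0)
  if (anyNA(r2))
    warning(sum(is.na(r2)), " undefined transition(s) excluded from the mean")
  structure(list(
    snapshot_times = times,
    transition_r2 = r2,
    mean_r2 = mean(r2, na.rm = TRUE)
  ), class = "emo_stability")
}

#' @export
print.emo_stability <- function(x, ...) {
  cat("<emo_stability> transition R2:",
      paste(sprintf("%.3f", x$transition_r2), collapse = ", "),
      sprintf("| mean %.3f\n", x$mean_r2))
  invisible(x)
}

#' Full analysis of one simulation run
#'
#' Convenience wrapper applying the analysis suite to an `emo_run`:
#' second-year mean LIKE, relationship-quality categories, and the
#' snapshot-stability score.
#'
#' @param run An `emo_run` from [run_simulation()].
#' @return List with `second_year`, `categories`, `stability`.
#' @export
analyze_run <- function(run) {
  stopifnot(inherits(run, "emo_run"))
  sy <- second_year_mean(run$like_samples, run$like_sample_times)
  list(
    second_year = sy,
    categories = categorize(sy),
    stability = stability_score(run$snapshots, run$snapshot_times)
  )
}

#' Write / read a dyadic matrix as CSV
#'
#' Matrices are written with individual ids as header row and column,
#' ordered by rank (id 1 = highest rank), matching the layout used for
#' dyadic level plots.
#'
#' @param m Square matrix.
#' @param path File path.
#' @return `read_dyadic_csv` returns the matrix; `write_dyadic_csv` the
#'   path, invisibly.
#' @export
write_dyadic_csv <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- seq_len(ncol(m))
  df <- cbind(id = seq_len(nrow(m)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dyadic_csv
#' @export
read_dyadic_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Write a stability result as JSON
#'
#' @param x An `emo_stability` object.
#' @param path File path.
#' @export
write_stability_json <- function(x, path) {
  stopifnot(inherits(x, "emo_stability"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Grayscale level plot of a dyadic matrix
#'
#' Renders a dyadic LIKE (or grooming/proximity) matrix as a grayscale
#' level plot: high values dark, low values light, individuals ordered from
#' low rank (top/left) to high rank (bottom/right).
#'
#' @param m Square matrix.
#' @param zlim Value range mapped to white..black.
#' @param main Plot title.
#' @export
plot_dyadic_matrix <- function(m, zlim = c(0.01, 0.99), main = "") {
  n <- nrow(m)
  mm <- m
  diag(mm) <- zlim[1]
  # id 1 = highest rank goes bottom-right per the ordering convention
  graphics::image(seq_len(n), seq_len(n), pmin(pmax(t(mm[n:1, n:1]), zlim[1]), zlim[2]),
                  zlim = zlim, col = grDevices::gray(seq(1, 0, length.out = 256)),
                  xlab = "partner (low to high rank)",
                  ylab = "actor (low to high rank)", main = main, axes = FALSE)
  graphics::box()
}
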