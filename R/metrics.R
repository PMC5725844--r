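.FRAME_FIELDS <- c("tick", "hours", "cell_count",
                   "n_blue", "n_periwinkle", "n_green", "n_light_green",
                   "n_red", "n_orange", "cleaved", "uncleaved", "ligand_count",
                   "n_G1", "n_S", "n_G2", "n_M", "pct_in_S", "theo_pct_S",
                   "avg_motility", "realized_speed")

#' Collect one tick's monitor readout
#'
#' Reports the monitor quantities: total cell count and counts per color
#' class, cleaved (released) vs uncleaved cells, ligand count, phase counts
#' and the percentage of cells in S phase, the theoretical %S for the current
#' inhibition settings, and the reported average motility of the tracked
#' (initially at the edge) green cohort, in um/min. The reported average is
#' the cohort mean of the cells' signaling readout mu; with `motility_check`
#' on it is clamped at zero. `realized_speed` is the kinematic companion: the
#' cohort's mean per-tick displacement converted to um/min.
#'
#' @param world A `scratch_world`.
#' @return Named numeric vector with the fields above (NA average when the
#'   cohort is empty).
#' @export
collect_frame <- function(world) {
  stopifnot(inherits(world, "scratch_world"))
  cl <- world$cells
  n <- length(cl$x)
  col_counts <- tabulate(cl$color, nbins = 6L)
  phase_counts <- tabulate(cl$phase, nbins = 4L)
  cleaved <- sum(cl$released)
  tracked <- cl$tracked
  if (any(tracked)) {
    avg <- mean(cl$mu[tracked])
    if (world$params$motility_check) avg <- max(0, avg)
    realized <- mean(cl$disp[tracked]) * world$params$patch_scale
  } else {
    avg <- NA_real_
    realized <- NA_real_
  }
  c(tick = world$tick,
    hours = world$tick / 60,
    cell_count = n,
    n_blue = col_counts[1], n_periwinkle = col_counts[2],
    n_green = col_counts[3], n_light_green = col_counts[4],
    n_red = col_counts[5], n_orange = col_counts[6],
    cleaved = cleaved, uncleaved = n - cleaved,
    ligand_count = length(world$ligands$x),
    n_G1 = phase_counts[1], n_S = phase_counts[2],
    n_G2 = phase_counts[3], n_M = phase_counts[4],
    pct_in_S = if (n > 0) 100 * phase_counts[2] / n else NA_real_,
    theo_pct_S = world$theo_pct_S,
    avg_motility = avg,
    realized_speed = realized)
}

#' Interval-resampled mean of the reported average motility
#'
#' Mean of the per-tick reported average motility sampled every
#' `interval_min` simulated minutes (tick 0 excluded), mimicking image
#' acquisition every 1, 5 or 10 minutes. For an unbiased reported series the
#' three interval choices agree within Monte Carlo error.
#'
#' @param x A `scratch_run` or its `frames` data frame.
#' @param interval_min Sampling interval in minutes (ticks).
#' @return Mean motility, um/min.
#' @export
interval_average_motility <- function(x, interval_min) {
  frames <- if (inherits(x, "scratch_run")) x$frames else x
  stopifnot(is.data.frame(frames), nrow(frames) > 0,
            interval_min >= 1, interval_min == round(interval_min))
  ticks <- frames$tick
  sel <- ticks > 0 & ticks %% interval_min == 0
  if (!any(sel)) {
    stop("interval_min (", interval_min, ") is longer than the run", call. = FALSE)
  }
  mean(frames$avg_motility[sel])
}

#' Batch-means standard error of a (possibly autocorrelated) series mean
#'
#' The reported motility series inherits autocorrelation from the clamped
#' random-walk fluctuation of the cells' pathway values, so the naive
#' sd/sqrt(n) understates the uncertainty of its mean. Splitting the series
#' into consecutive batches and taking the sd of the batch means is robust to
#' that.
#'
#' @param x Numeric series.
#' @param n_batches Number of consecutive batches (default 24).
#' @return Standard error estimate of `mean(x)`.
#' @export
batch_means_se <- function(x, n_batches = 24) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 2 * n_batches)
  grp <- rep(seq_len(n_batches), each = ceiling(length(x) / n_batches),
             length.out = length(x))
  bm <- tapply(x, grp, mean)
  stats::sd(bm) / sqrt(n_batches)
}

#' Export a run's metrics, trails, and resolved parameters as CSV
#'
#' Writes `frames.csv` (one row per tick, one column per monitor field),
#' `trails.csv` (tidy long format: cell id, trailer color id, tick, x, y),
#' and `params.csv` (key/value rows of the resolved parameter set including
#' the seed) into `out_dir`. Numbers are written in full precision so the
#' files round-trip exactly.
#'
#' @param run A `scratch_run`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths of the written files.
#' @export
export_csv <- function(run, out_dir) {
  stopifnot(inherits(run, "scratch_run"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- file.path(out_dir, c("frames.csv", "trails.csv", "params.csv"))

  utils::write.csv(run$frames, paths[1], row.names = FALSE)

  tr <- run$trails
  if (!is.null(tr) && length(tr$ids) > 0) {
    keep <- which(colSums(!is.na(tr$tx)) > 0)
    trails_df <- data.frame(
      cell_id = rep(tr$ids, times = length(keep)),
      trailer_color = rep(tr$trailer_color, times = length(keep)),
      tick = rep(keep - 1L, each = length(tr$ids)),
      x = as.vector(tr$tx[, keep]),
      y = as.vector(tr$ty[, keep])
    )
  } else {
    trails_df <- data.frame(cell_id = integer(0), trailer_color = integer(0),
                            tick = integer(0), x = numeric(0), y = numeric(0))
  }
  utils::write.csv(trails_df, paths[2], row.names = FALSE)

  p <- run$params
  scalar <- vapply(p, function(v) length(v) == 1, logical(1))
  params_df <- data.frame(
    parameter = names(p)[scalar],
    value = vapply(p[scalar], function(v) format(v, digits = 17), character(1)),
    row.names = NULL
  )
  utils::write.csv(params_df, paths[3], row.names = FALSE)
  invisible(paths)
}
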