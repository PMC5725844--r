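#' Initialize a simulation world
#'
#' Seeds the RNG from `params$seed`, computes the signaling quantities once
#' (pathway ceilings, average response, theoretical %S, proliferation factor,
#' phase boundaries, dt), then populates the monolayer behind the scratch
#' line and marks the edge cells ([populate()], [make_scratch()]). Two calls
#' with the same parameters produce bitwise-identical worlds.
#'
#' @param params A `scratch_params` object.
#' @return A `scratch_world` at tick 0.
#' @export
init_world <- function(params) {
  stopifnot(inherits(params, "scratch_params"))
  set.seed(params$seed)
  world <- .make_world(params)
  world <- populate(world)
  world <- make_scratch(world)
  world <- update_density(world)
  if (params$trailers) {
    tracked <- which(world$cells$tracked)
    nt <- length(tracked)
    ncol_tr <- params$ticks_planned + 1L
    world$trails <- list(
      ids = world$cells$id[tracked],
      trailer_color = if (nt > 0) sample.int(.Machine$integer.max, nt) else integer(0),
      tx = matrix(NA_real_, nt, ncol_tr),
      ty = matrix(NA_real_, nt, ncol_tr)
    )
    if (nt > 0) {
      world$trails$tx[, 1] <- world$cells$x[tracked]
      world$trails$ty[, 1] <- world$cells$y[tracked]
    }
  }
  world
}

#' Seed the monolayer behind the scratch line
#'
#' Places the [cell_capacity()] count of cells on distinct open positions
#' strictly left of the scratch line (one per patch while patches remain,
#' jittered within the patch), each with randomized pathway values within the
#' deviation window and a uniform-random position in the cell cycle, all blue
#' and unreleased.
#'
#' @param world A bare `scratch_world` (no cells).
#' @return World with the initial cell population.
#' @export
populate <- function(world) {
  stopifnot(inherits(world, "scratch_world"), .n_cells(world) == 0)
  p <- world$params
  N <- cell_capacity(p$world_width, p$world_height, p$scratch_line,
                     p$confluent_density)
  if (N == 0) return(world)
  n_cols <- world$scratch_ix - 1L
  pool_ix <- rep(seq_len(n_cols), times = world$ny)
  pool_iy <- rep(seq_len(world$ny), each = n_cols)
  npool <- length(pool_ix)
  if (N <= npool) {
    pick <- sample.int(npool, N)
  } else {
    # more cells than patches: fill every patch once, then double up
    extra <- pmin(N - npool, npool)
    pick <- c(seq_len(npool), sample.int(npool, extra))
    if (N > 2L * npool) {
      warning(sprintf("insufficient space behind the scratch line: placed %d of %d cells",
                      length(pick), N))
      N <- length(pick)
    }
  }
  x <- world$min_x + (pool_ix[pick] - 1L) + stats::runif(N, -0.3, 0.3)
  y <- world$min_y + (pool_iy[pick] - 1L) + stats::runif(N, -0.3, 0.3)
  v <- p$deviation_from_avg
  capA <- world$caps[["A"]]; capB <- world$caps[["B"]]
  A <- stats::runif(N, capA - v, capA + v)
  B <- stats::runif(N, capB - v, capB + v)
  cycle <- as.integer(floor(stats::runif(N, 0, world$schedule$total)))
  world$cells <- list(
    x = x, y = y, A = A, B = B,
    mu = .cell_mu(world, A, B),
    cycle = cycle,
    phase = phase_of(cycle, world$schedule),
    released = rep(FALSE, N),
    color = rep(.COL_BLUE, N),
    tracked = rep(FALSE, N),
    id = seq_len(N),
    disp = numeric(N)
  )
  world
}

#' Mark the scratch-edge cells
#'
#' Cells in the patch column immediately west of the scratch line turn green,
#' are flagged as released (their surface ligand is considered cleaved), and
#' become the tracked cohort whose motility the monitors report.
#'
#' @param world A populated `scratch_world`.
#' @return Updated world.
#' @export
make_scratch <- function(world) {
  stopifnot(inherits(world, "scratch_world"))
  if (.n_cells(world) == 0) return(world)
  edge_ix <- world$scratch_ix - 1L
  if (edge_ix < 1L) return(world)
  sel <- .patch_ix(world, world$cells$x) == edge_ix
  world$cells$color[sel] <- .COL_GREEN
  world$cells$released[sel] <- TRUE
  world$cells$tracked[sel] <- TRUE
  world
}

#' Advance the simulation by one tick
#'
#' The go-loop: refresh the patch density fields; cells update parameters
#' (fluctuation, cycle, mitosis), move, and handle ligand release; if
#' adhesion is enabled the spring network is rebuilt and applied; ligands
#' move; the tick counter advances and halting conditions are checked (time
#' scale reached, a cell reaching the right edge, or an empty world). One
#' tick is one simulated minute.
#'
#' @param world A `scratch_world`.
#' @return The world one tick later; `world$halt` is set when a halting
#'   condition fired.
#' @export
scratch_step <- function(world) {
  stopifnot(inherits(world, "scratch_world"))
  if (.n_cells(world) == 0) {
    world$halt <- "extinction_guard"
    return(world)
  }
  n0 <- .n_cells(world)
  x0 <- world$cells$x
  y0 <- world$cells$y

  world <- update_density(world)
  world <- cells_update_params(world)
  world <- cells_diffuse(world)
  world <- cells_l_production(world)
  if (world$params$cellular_adhesion) {
    world <- apply_springs(world, rebuild_links(world))
  }
  world <- ligands_step(world)

  # net displacement over the whole tick (diffusion + springs)
  world$cells$disp <- numeric(.n_cells(world))
  world$cells$disp[seq_len(n0)] <- sqrt((world$cells$x[seq_len(n0)] - x0)^2 +
                                          (world$cells$y[seq_len(n0)] - y0)^2)

  world$tick <- world$tick + 1L

  if (!is.null(world$trails) && length(world$trails$ids) > 0 &&
      world$tick + 1L <= ncol(world$trails$tx)) {
    tracked <- match(world$trails$ids, world$cells$id)
    world$trails$tx[, world$tick + 1L] <- world$cells$x[tracked]
    world$trails$ty[, world$tick + 1L] <- world$cells$y[tracked]
  }

  if (any(.patch_ix(world, world$cells$x) >= world$nx)) {
    world$halt <- "right_edge_reached"
  } else if (world$tick >= world$params$ticks_planned) {
    world$halt <- "time_scale_reached"
  }
  world
}

#' Run a complete simulation
#'
#' Initializes the world from the parameter set and steps it until a halting
#' condition fires, collecting one monitor frame per tick (including tick 0).
#'
#' @param params A `scratch_params` object (see [scratch_params()]).
#' @return A `scratch_run` object: `frames` (one-row-per-tick data frame of
#'   all monitor quantities), `world` (final state), `trails` (tracked-cell
#'   position history), `halt_reason`, and the resolved `params`.
#' @examples
#' \donttest{
#' run <- run_scratch(scratch_params(time_scale_hours = 1, scratch_line = -20))
#' tail(run$frames[, c("tick", "hours", "cell_count", "avg_motility")])
#' }
#' @export
run_scratch <- function(params) {
  world <- init_world(params)
  nmax <- params$ticks_planned + 1L
  frames <- matrix(NA_real_, nrow = nmax, ncol = length(.FRAME_FIELDS),
                   dimnames = list(NULL, .FRAME_FIELDS))
  frames[1L, ] <- collect_frame(world)
  nframes <- 1L
  if (.n_cells(world) == 0) {
    warning("world initialized with zero cells; halting immediately")
    world$halt <- "extinction_guard"
  }
  while (is.null(world$halt)) {
    world <- scratch_step(world)
    nframes <- nframes + 1L
    frames[nframes, ] <- collect_frame(world)
  }
  structure(list(
    frames = as.data.frame(frames[seq_len(nframes), , drop = FALSE]),
    world = world,
    trails = world$trails,
    halt_reason = world$halt,
    params = params
  ), class = "scratch_run")
}

#' @export
print.scratch_run <- function(x, ...) {
  last <- x$frames[nrow(x$frames), ]
  cat(sprintf("scratch assay run: %d ticks (%.1f h), halted: %s\n",
              x$world$tick, last$hours, x$halt_reason))
  cat(sprintf("  cells %d (cleaved %d), ligands %d\n",
              last$cell_count, last$cleaved, last$ligand_count))
  cat(sprintf("  avg motility %.3f um/min; %%S %.1f (theoretical %.1f)\n",
              last$avg_motility, last$pct_in_S, last$theo_pct_S))
  invisible(x)
}

#' Final eastward displacement of the tracked scratch-edge cohort
#'
#' Mean over the initially green cells of (final x - initial x), in patch
#' units; the quantity the wound-healing experiments track.
#'
#' @param run A `scratch_run`.
#' @return Mean displacement (NA if the cohort is empty).
#' @export
green_displacement <- function(run) {
  stopifnot(inherits(run, "scratch_run"))
  tr <- run$trails
  if (is.null(tr) || length(tr$ids) == 0) return(NA_real_)
  last <- max(which(colSums(!is.na(tr$tx)) > 0))
  mean(tr$tx[, last] - tr$tx[, 1])
}
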