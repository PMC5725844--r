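# Moore neighborhood offsets, anticlockwise from east.
.DIR_DX <- c(1, 1, 0, -1, -1, -1, 0, 1)
.DIR_DY <- c(0, 1, 1, 1, 0, -1, -1, -1)
.DIR_NORM <- sqrt(.DIR_DX^2 + .DIR_DY^2)
.DIR_NAMES <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE")

# Empty cell table (list of parallel vectors).
.empty_cells <- function() {
  list(x = numeric(0), y = numeric(0), A = numeric(0), B = numeric(0),
       mu = numeric(0), cycle = integer(0), phase = integer(0),
       released = logical(0), color = integer(0), tracked = logical(0),
       id = integer(0), disp = numeric(0))
}

.n_cells <- function(world) length(world$cells$x)

# Patch indices (1-based matrix indices) for continuous positions.
.patch_ix <- function(world, x) as.integer(round(x)) - world$min_x + 1L
.patch_iy <- function(world, y) as.integer(round(y)) - world$min_y + 1L

.clamp_x <- function(world, x) pmin(pmax(x, world$min_x - 0.499), world$max_x + 0.499)
.clamp_y <- function(world, y) pmin(pmax(y, world$min_y - 0.499), world$max_y + 0.499)

# Per-position counts in the 8 neighboring patches from a count matrix.
# Out-of-bounds patches report `oob` (walls count as full for cells,
# empty for ligand attraction).
.neighbor_counts <- function(grid, ix, iy, oob) {
  n <- length(ix)
  nx <- nrow(grid)
  ny <- ncol(grid)
  out <- matrix(oob, nrow = n, ncol = 8L)
  for (k in 1:8) {
    jx <- ix + .DIR_DX[k]
    jy <- iy + .DIR_DY[k]
    ok <- jx >= 1L & jx <= nx & jy >= 1L & jy <= ny
    if (any(ok)) out[ok, k] <- grid[cbind(jx[ok], jy[ok])]
  }
  out
}

# Bare world container; cells are added by populate()/make_scratch().
.make_world <- function(params) {
  nx <- params$world_width
  ny <- params$world_height
  min_x <- -((nx - 1L) %/% 2L)
  min_y <- -((ny - 1L) %/% 2L)
  schedule <- phase_boundaries(params)
  caps <- pathway_caps(params)
  structure(list(
    params = params,
    nx = nx, ny = ny,
    min_x = min_x, max_x = min_x + nx - 1L,
    min_y = min_y, max_y = min_y + ny - 1L,
    scratch_ix = params$scratch_line - min_x + 1L,
    caps = caps,
    rate = unname(effective_motility(caps["A"], caps["B"], caps["C"])),
    schedule = schedule,
    theo_pct_S = schedule$pct_S_effective,
    grid_cells = matrix(0L, nx, ny),
    grid_ligands = matrix(0L, nx, ny),
    tick = 0L,
    cells = .empty_cells(),
    ligands = list(x = numeric(0), y = numeric(0)),
    halt = NULL,
    trails = NULL
  ), class = "scratch_world")
}

#' Number of cells needed to fill the monolayer behind the scratch line
#'
#' The monolayer is seeded at a near-confluent density over the patches
#' strictly left of the scratch line.
#'
#' @param world_width,world_height World dimensions in patches.
#' @param scratch_line Scratch x-coordinate (patch units).
#' @param confluent_density Cells per patch (default 0.9, near confluency).
#' @return Integer cell count (0, with a warning, if the scratch line sits at
#'   or beyond the left edge).
#' @examples
#' cell_capacity(65, 33, 0)  # 950
#' @export
cell_capacity <- function(world_width, world_height, scratch_line,
                          confluent_density = 0.9) {
  min_x <- -((as.integer(world_width) - 1L) %/% 2L)
  n_cols <- scratch_line - min_x
  if (n_cols <= 0) {
    warning("scratch line at or beyond the left edge: no room for cells")
    return(0L)
  }
  as.integer(round(confluent_density * n_cols * world_height))
}

#' Refresh per-patch cell and ligand counts
#'
#' Each patch's counts are set to the number of agents whose position rounds
#' into it. Idempotent; the counts are the frozen density field that all agent
#' decisions within the following tick read.
#'
#' @param world A `scratch_world`.
#' @return The world with updated `grid_cells` and `grid_ligands`.
#' @export
update_density <- function(world) {
  nbin <- world$nx * world$ny
  if (.n_cells(world) > 0) {
    idx <- .patch_ix(world, world$cells$x) +
      (.patch_iy(world, world$cells$y) - 1L) * world$nx
    world$grid_cells <- matrix(tabulate(idx, nbins = nbin), world$nx, world$ny)
  } else {
    world$grid_cells <- matrix(0L, world$nx, world$ny)
  }
  if (length(world$ligands$x) > 0) {
    idx <- .patch_ix(world, world$ligands$x) +
      (.patch_iy(world, world$ligands$y) - 1L) * world$nx
    world$grid_ligands <- matrix(tabulate(idx, nbins = nbin), world$nx, world$ny)
  } else {
    world$grid_ligands <- matrix(0L, world$nx, world$ny)
  }
  world
}

#' Assess the open space around a position
#'
#' Reports which of the 8 neighboring patches (and the containing patch) are
#' below the crowding threshold, and the direction of least cell density with
#' ties broken uniformly at random. Out-of-bounds neighbors count as full, so
#' cells cannot be steered through the left/top/bottom walls.
#'
#' @param world A `scratch_world` (with current density fields; see
#'   [update_density()]).
#' @param x,y Position in patch units.
#' @return List with `open` (named logical for the 8 directions),
#'   `here_open` (containing patch below threshold), `surrounded_equally`
#'   (all neighbors open and equally occupied), `stationary` (no open
#'   neighbor), and `direction` (name of the chosen least-density direction,
#'   or NA if stationary).
#' @export
open_space <- function(world, x, y) {
  stopifnot(inherits(world, "scratch_world"))
  thr <- world$params$crowding_threshold
  ix <- .patch_ix(world, x)
  iy <- .patch_iy(world, y)
  nd <- .neighbor_counts(world$grid_cells, ix, iy, oob = Inf)[1, ]
  open <- nd < thr
  names(open) <- .DIR_NAMES
  stationary <- !any(open)
  direction <- NA_character_
  if (!stationary) {
    least <- which(nd == min(nd))
    pick <- if (length(least) > 1) least[sample.int(length(least), 1L)] else least
    direction <- .DIR_NAMES[pick]
  }
  list(open = open,
       here_open = world$grid_cells[ix, iy] < thr,
       surrounded_equally = all(open) && length(unique(nd)) == 1L,
       stationary = stationary,
       direction = direction)
}

#' @export
print.scratch_world <- function(x, ...) {
  cat(sprintf("scratch world: %d x %d patches, tick %d (%.2f h)\n",
              x$nx, x$ny, x$tick, x$tick / 60))
  cat(sprintf("  %d cells (%d released), %d ligands, scratch line at x = %d\n",
              .n_cells(x), sum(x$cells$released), length(x$ligands$x),
              x$params$scratch_line))
  invisible(x)
}
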