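#' Per-tick ligand movement
#'
#' Each released ligand molecule steps a distance `ligand_speed` (patch units
#' per tick): with probability `l_randomness` in a uniformly random direction,
#' otherwise toward the neighboring patch with the highest cell count (ties
#' broken at random), which keeps the molecules concentrated around the cells
#' they stimulate. Positions clamp to the world bounds; ligands never decay.
#'
#' @param world A `scratch_world` with current density fields.
#' @return Updated world.
#' @export
ligands_step <- function(world) {
  n <- length(world$ligands$x)
  if (n == 0) return(world)
  p <- world$params
  s <- p$ligand_speed
  if (s == 0) return(world)
  lx <- world$ligands$x
  ly <- world$ligands$y

  dx <- numeric(n); dy <- numeric(n)
  rnd <- stats::runif(n) < p$l_randomness
  if (any(rnd)) {
    ang <- stats::runif(sum(rnd), 0, 2 * pi)
    dx[rnd] <- s * cos(ang)
    dy[rnd] <- s * sin(ang)
  }
  if (any(!rnd)) {
    ix <- .patch_ix(world, lx[!rnd])
    iy <- .patch_iy(world, ly[!rnd])
    # walls marked below any real count so the drift never targets them
    nd <- .neighbor_counts(world$grid_cells, ix, iy, oob = -1)
    k <- max.col(nd, ties.method = "random")
    dx[!rnd] <- s * .DIR_DX[k] / .DIR_NORM[k]
    dy[!rnd] <- s * .DIR_DY[k] / .DIR_NORM[k]
  }
  world$ligands$x <- .clamp_x(world, lx + dx)
  world$ligands$y <- .clamp_y(world, ly + dy)
  world
}
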