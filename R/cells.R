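# Color classes. Daughters take the lighter variant of the parent's color;
# released cells are always in {green, light_green, red, orange}.
.COL_BLUE <- 1L; .COL_PERIWINKLE <- 2L; .COL_GREEN <- 3L
.COL_LIGHT_GREEN <- 4L; .COL_RED <- 5L; .COL_ORANGE <- 6L
.COLOR_NAMES <- c("blue", "periwinkle", "green", "light_green", "red", "orange")
.DAUGHTER_COLOR <- c(.COL_PERIWINKLE, .COL_PERIWINKLE, .COL_LIGHT_GREEN,
                     .COL_LIGHT_GREEN, .COL_ORANGE, .COL_ORANGE)

# Signaling readout of one cell: the deterministic converged rate plus the
# averaged fluctuation of the two receptor arms. May dip below zero under
# large deviation; the realized agent speed clamps at zero separately.
.cell_mu <- function(world, A, B) {
  world$rate + ((A - world$caps[["A"]]) + (B - world$caps[["B"]])) / 2
}

.step_len <- function(world, mu) {
  sqrt(2) * pmax(mu, 0) * world$params$dt
}

#' Per-tick cell parameter update (fluctuation, cycle advance, mitosis)
#'
#' Each cell's pathway values A and B have a 50% chance of fluctuating by an
#' independent uniform draw within the deviation range, clamped to a
#' symmetric window around the inhibition-determined ceiling; the cycle
#' counter advances one tick; cells completing the cycle attempt mitosis
#' (a daughter appears on an open neighboring patch if there is one, in the
#' lighter parental color, and both restart the cycle); the phase and the
#' effective motility mu are recomputed.
#'
#' @param world A `scratch_world` with current density fields.
#' @return Updated world.
#' @export
cells_update_params <- function(world) {
  n <- .n_cells(world)
  if (n == 0) return(world)
  cl <- world$cells
  v <- world$params$deviation_from_avg
  if (v > 0) {
    fluct <- stats::runif(n) < 0.5
    nf <- sum(fluct)
    if (nf > 0) {
      cl$A[fluct] <- cl$A[fluct] + stats::runif(nf, -v, v)
      cl$B[fluct] <- cl$B[fluct] + stats::runif(nf, -v, v)
      capA <- world$caps[["A"]]; capB <- world$caps[["B"]]
      cl$A <- pmin(pmax(cl$A, capA - v), capA + v)
      cl$B <- pmin(pmax(cl$B, capB - v), capB + v)
    }
  }
  cl$cycle <- cl$cycle + 1L

  total <- world$schedule$total
  dividing <- which(cl$cycle >= total)
  if (length(dividing) > 0) {
    thr <- world$params$crowding_threshold
    gc <- world$grid_cells  # local copy tracks placements made this tick
    d_x <- numeric(0); d_y <- numeric(0); d_A <- numeric(0); d_B <- numeric(0)
    d_color <- integer(0); d_released <- logical(0)
    next_id <- max(cl$id, 0L)
    d_id <- integer(0)
    for (i in dividing) {
      ix <- .patch_ix(world, cl$x[i]); iy <- .patch_iy(world, cl$y[i])
      jx <- ix + .DIR_DX; jy <- iy + .DIR_DY
      ok <- jx >= 1L & jx <= world$nx & jy >= 1L & jy <= world$ny
      ok[ok] <- gc[cbind(jx[ok], jy[ok])] < thr
      if (any(ok)) {
        pick <- which(ok)
        k <- pick[sample.int(length(pick), 1L)]
        px <- world$min_x + (ix + .DIR_DX[k]) - 1L
        py <- world$min_y + (iy + .DIR_DY[k]) - 1L
        d_x <- c(d_x, px + stats::runif(1, -0.3, 0.3))
        d_y <- c(d_y, py + stats::runif(1, -0.3, 0.3))
        d_A <- c(d_A, cl$A[i])  # daughters inherit the parent's pathway rates
        d_B <- c(d_B, cl$B[i])
        d_color <- c(d_color, .DAUGHTER_COLOR[cl$color[i]])
        d_released <- c(d_released, cl$released[i])
        next_id <- next_id + 1L
        d_id <- c(d_id, next_id)
        gc[ix + .DIR_DX[k], iy + .DIR_DY[k]] <- gc[ix + .DIR_DX[k], iy + .DIR_DY[k]] + 1L
      }
      cl$cycle[i] <- 0L  # parent restarts its cycle whether or not it divided
    }
    if (length(d_x) > 0) {
      nd <- length(d_x)
      cl$x <- c(cl$x, d_x); cl$y <- c(cl$y, d_y)
      cl$A <- c(cl$A, d_A); cl$B <- c(cl$B, d_B)
      cl$mu <- c(cl$mu, numeric(nd))
      cl$cycle <- c(cl$cycle, integer(nd))
      cl$phase <- c(cl$phase, integer(nd))
      cl$released <- c(cl$released, d_released)
      cl$color <- c(cl$color, d_color)
      cl$tracked <- c(cl$tracked, logical(nd))  # daughters are never tracked
      cl$id <- c(cl$id, d_id)
      cl$disp <- c(cl$disp, numeric(nd))
    }
  }

  cl$phase <- phase_of(cl$cycle, world$schedule)
  cl$mu <- .cell_mu(world, cl$A, cl$B)
  world$cells <- cl
  world
}

#' Per-tick cell movement
#'
#' In order: a cell whose western (behind) patch holds more than two cells
#' steps east to relieve crowding; otherwise, if no neighboring patch is below
#' the crowding threshold the cell is stationary this tick; otherwise it takes
#' a uniformly random-direction step with probability `randomness` and a step
#' toward the least-dense neighboring patch (ties broken at random) with the
#' complementary probability. The step length is `sqrt(2) * mu * dt` patch
#' units. Decisions are independent per cell and read the density field frozen
#' at the start of the tick; walls are impassable (positions clamp to the
#' world).
#'
#' @param world A `scratch_world`.
#' @return Updated world (positions and per-tick displacements).
#' @export
cells_diffuse <- function(world) {
  n <- .n_cells(world)
  if (n == 0) return(world)
  cl <- world$cells
  p <- world$params
  thr <- p$crowding_threshold
  s <- .step_len(world, cl$mu)
  ix <- .patch_ix(world, cl$x)
  iy <- .patch_iy(world, cl$y)

  behind <- rep(0, n)
  okw <- ix - 1L >= 1L
  behind[okw] <- world$grid_cells[cbind(ix[okw] - 1L, iy[okw])]
  forced <- behind > 2

  nd <- .neighbor_counts(world$grid_cells, ix, iy, oob = Inf)
  open_any <- do.call(pmin, as.data.frame(nd)) < thr

  dx <- numeric(n); dy <- numeric(n)
  # (1) crowded behind: step forward (east)
  if (any(forced)) dx[forced] <- s[forced]
  free <- !forced & open_any
  if (any(free)) {
    rnd <- stats::runif(n) < p$randomness
    rw <- free & rnd
    if (any(rw)) {
      ang <- stats::runif(sum(rw), 0, 2 * pi)
      dx[rw] <- s[rw] * cos(ang)
      dy[rw] <- s[rw] * sin(ang)
    }
    dd <- free & !rnd
    if (any(dd)) {
      k <- max.col(-nd[dd, , drop = FALSE], ties.method = "random")
      dx[dd] <- s[dd] * .DIR_DX[k] / .DIR_NORM[k]
      dy[dd] <- s[dd] * .DIR_DY[k] / .DIR_NORM[k]
    }
  }
  # (3) fully enclosed, not pushed from behind: stationary

  new_x <- .clamp_x(world, cl$x + dx)
  new_y <- .clamp_y(world, cl$y + dy)
  cl$disp <- sqrt((new_x - cl$x)^2 + (new_y - cl$y)^2)
  cl$x <- new_x
  cl$y <- new_y
  world$cells <- cl
  world
}

#' Per-tick ligand release and release-state transitions
#'
#' (a) An unreleased cell strictly past the scratch line with fewer than two
#' cells in the patch ahead cleaves its surface ligand: it turns red (orange
#' for daughters), and hatches exactly four ligand molecules at its position.
#' (b) Every released cell past the line with a clear path ahead has a 5%
#' chance per tick of shedding a uniform-random 1-4 further molecules.
#' (c) With adhesion enabled, a red/orange cell that has moved back into the
#' crowded monolayer behind the line regains its adhesive state and reverts to
#' blue/periwinkle; green-lineage cells never revert and keep releasing.
#'
#' @param world A `scratch_world`.
#' @return Updated world (cell states and new ligands).
#' @export
cells_l_production <- function(world) {
  n <- .n_cells(world)
  if (n == 0) return(world)
  cl <- world$cells
  ix <- .patch_ix(world, cl$x)
  iy <- .patch_iy(world, cl$y)
  past <- ix >= world$scratch_ix

  ahead <- rep(0, n)
  oke <- ix + 1L <= world$nx
  ahead[oke] <- world$grid_cells[cbind(ix[oke] + 1L, iy[oke])]
  clear <- ahead < 2

  new_lx <- numeric(0); new_ly <- numeric(0)

  newly <- !cl$released & past & clear
  if (any(newly)) {
    cl$released[newly] <- TRUE
    cl$color[newly] <- ifelse(cl$color[newly] == .COL_BLUE, .COL_RED, .COL_ORANGE)
    new_lx <- rep(cl$x[newly], each = 4L)
    new_ly <- rep(cl$y[newly], each = 4L)
  }

  producing <- cl$released & past & clear & !newly
  if (any(producing)) {
    idx <- which(producing)
    shed <- idx[stats::runif(length(idx)) < 0.05]
    if (length(shed) > 0) {
      counts <- sample.int(4L, length(shed), replace = TRUE)
      new_lx <- c(new_lx, rep(cl$x[shed], counts))
      new_ly <- c(new_ly, rep(cl$y[shed], counts))
    }
  }

  if (world$params$cellular_adhesion) {
    revert <- cl$released & (cl$color %in% c(.COL_RED, .COL_ORANGE)) &
      ix < world$scratch_ix & ahead >= 2
    if (any(revert)) {
      cl$released[revert] <- FALSE
      cl$color[revert] <- ifelse(cl$color[revert] == .COL_RED,
                                 .COL_BLUE, .COL_PERIWINKLE)
    }
  }

  world$cells <- cl
  if (length(new_lx) > 0) {
    room <- world$params$max_ligands - length(world$ligands$x)
    if (room < length(new_lx)) {
      keep <- max(0, room)
      new_lx <- new_lx[seq_len(keep)]
      new_ly <- new_ly[seq_len(keep)]
    }
    world$ligands$x <- c(world$ligands$x, new_lx)
    world$ligands$y <- c(world$ligands$y, new_ly)
  }
  world
}
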