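test_that("with zero deviation every cell's mu equals the deterministic rate", {
  p <- tiny_params(deviation_from_avg = 0)
  w <- init_world(p)
  for (i in 1:5) w <- scratch_step(w)
  expect_true(all(abs(w$cells$mu - 0.23) < 1e-12))

  p <- tiny_params(deviation_from_avg = 0, inhibition_C = 1)
  w <- init_world(p)
  for (i in 1:5) w <- scratch_step(w)
  expect_true(all(abs(w$cells$mu - 0.13) < 1e-12))
})

test_that("pathway fluctuations stay in the deviation window and are centred", {
  p <- tiny_params(deviation_from_avg = 0.3)
  set.seed(2)
  w <- world_with_cells(p, x = runif(200, -8, -2), y = runif(200, -5, 5))
  capA <- w$caps[["A"]]
  sum_A <- 0; n_obs <- 0
  for (i in 1:300) {
    w <- cells_update_params(w)
    expect_true(all(w$cells$A >= capA - 0.3 - 1e-12))
    expect_true(all(w$cells$A <= capA + 0.3 + 1e-12))
    sum_A <- sum_A + sum(w$cells$A)
    n_obs <- n_obs + length(w$cells$A)
  }
  expect_lt(abs(sum_A / n_obs - capA), 0.02)
})

test_that("cycle threshold crossings move cells into the next phase", {
  p <- tiny_params()
  sch <- phase_boundaries(p)
  b1 <- unname(sch$boundaries[1])
  w <- world_with_cells(p, x = 0, y = 0, cycle = b1 - 1L)
  expect_equal(w$cells$phase, 1L)  # G1, one tick before the S boundary
  w <- cells_update_params(w)
  expect_equal(w$cells$cycle, b1)
  expect_equal(w$cells$phase, 2L)  # S
})

test_that("mitosis spawns a lighter daughter that inherits the released state", {
  p <- tiny_params()
  total <- phase_boundaries(p)$total
  parent_daughter <- list(c(1L, 2L), c(2L, 2L), c(3L, 4L),
                          c(4L, 4L), c(5L, 6L), c(6L, 6L))
  for (pd in parent_daughter) {
    released <- pd[1] >= 3L
    w <- world_with_cells(p, x = 0, y = 0, color = pd[1], released = released,
                          cycle = total - 1L)
    w <- cells_update_params(w)
    expect_equal(length(w$cells$x), 2L)
    expect_equal(w$cells$color[2], pd[2])
    expect_equal(w$cells$released[2], released)
    expect_equal(w$cells$cycle, c(0L, 0L))  # both restart the cycle
  }
})

test_that("mitosis is blocked when no neighboring patch has room", {
  p <- tiny_params()
  total <- phase_boundaries(p)$total
  nb_x <- rep(c(-1, 0, 1), times = 3); nb_y <- rep(c(-1, 0, 1), each = 3)
  ring <- !(nb_x == 0 & nb_y == 0)
  w <- world_with_cells(p,
                        x = c(0, rep(nb_x[ring], each = 2)),
                        y = c(0, rep(nb_y[ring], each = 2)),
                        cycle = c(total - 1L, rep(0L, 16)))
  n0 <- length(w$cells$x)
  w <- cells_update_params(w)
  expect_equal(length(w$cells$x), n0)     # no daughter
  expect_equal(w$cells$cycle[1], 0L)      # parent still restarts
})

test_that("crossing the scratch line releases the cell and hatches four ligands", {
  p <- tiny_params()
  w <- world_with_cells(p, x = p$scratch_line + 1, y = 0)
  w <- cells_l_production(w)
  expect_true(w$cells$released)
  expect_equal(w$cells$color, 5L)  # red
  expect_equal(length(w$ligands$x), 4L)

  # behind the line: nothing happens
  w <- world_with_cells(p, x = p$scratch_line - 2, y = 0)
  w <- cells_l_production(w)
  expect_false(w$cells$released)
  expect_equal(length(w$ligands$x), 0L)

  # released but blocked ahead: the red cell never sheds stochastically.
  # Its path is blocked by two unreleased cells that are themselves blocked;
  # the outermost pair releases deterministically (4 ligands each), so any
  # run yielding more than those 8 would be a stochastic shed by a blocked cell.
  s <- p$scratch_line
  w <- world_with_cells(p,
                        x = c(s + 1, rep(s + 2, 2), rep(s + 3, 2)),
                        y = rep(0, 5),
                        released = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                        color = c(5L, 1L, 1L, 1L, 1L))
  n_lig <- replicate(50, length(cells_l_production(w)$ligands$x))
  expect_true(all(n_lig == 8L))
})

test_that("stochastic ligand shedding matches the 5% up-to-four rule", {
  p <- tiny_params()
  w <- world_with_cells(p, x = p$scratch_line + 3, y = 0,
                        released = TRUE, color = 5L)
  set.seed(99)
  for (i in 1:2000) w <- cells_l_production(w)
  # expectation 2000 * 0.05 * 2.5 = 250, sd ~ 27
  expect_gt(length(w$ligands$x), 160)
  expect_lt(length(w$ligands$x), 340)
})

test_that("red cells re-entering the adherent pack revert to blue; greens never do", {
  p <- tiny_params(cellular_adhesion = TRUE)
  behind <- p$scratch_line - 3
  w <- world_with_cells(p,
                        x = c(behind, rep(behind + 1, 3), behind),
                        y = c(0, 0, 0, 0, 1),
                        released = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                        color = c(5L, 1L, 1L, 1L, 3L))
  w <- cells_l_production(w)
  expect_false(w$cells$released[1])       # red -> blue
  expect_equal(w$cells$color[1], 1L)
  expect_true(w$cells$released[5])        # green keeps releasing
  expect_equal(w$cells$color[5], 3L)

  # without adhesion there is nothing to re-adhere to
  p2 <- tiny_params(cellular_adhesion = FALSE)
  w2 <- world_with_cells(p2,
                         x = c(behind, rep(behind + 1, 3)),
                         y = c(0, 0, 0, 0),
                         released = c(TRUE, FALSE, FALSE, FALSE),
                         color = c(5L, 1L, 1L, 1L))
  w2 <- cells_l_production(w2)
  expect_true(w2$cells$released[1])
})

test_that("movement follows the crowding rules", {
  p <- tiny_params(deviation_from_avg = 0, randomness = 0)
  s <- sqrt(2) * 0.23 * p$dt

  # pushed from behind: more than two cells in the western patch
  w <- world_with_cells(p, x = c(0, -1, -1, -1), y = c(0, 0, 0, 0))
  w2 <- cells_diffuse(w)
  expect_equal(w2$cells$x[1], s, tolerance = 1e-9)
  expect_equal(w2$cells$y[1], 0)

  # fully enclosed (every neighbor at threshold, exactly two behind): stationary
  nb_x <- rep(c(-1, 0, 1), times = 3); nb_y <- rep(c(-1, 0, 1), each = 3)
  full_ring <- !(nb_x == 0 & nb_y == 0)
  w <- world_with_cells(p, x = c(0, rep(nb_x[full_ring], each = 2)),
                        y = c(0, rep(nb_y[full_ring], each = 2)))
  w2 <- cells_diffuse(w)
  expect_equal(w2$cells$x[1], 0)
  expect_equal(w2$cells$y[1], 0)
  ring <- full_ring & !(nb_x == -1 & nb_y == 0)

  # single open neighbor: deterministic step toward it
  w <- world_with_cells(p, x = c(0, rep(nb_x[ring], each = 2)),
                        y = c(0, rep(nb_y[ring], each = 2)))
  w2 <- cells_diffuse(w)
  expect_equal(w2$cells$x[1], -s, tolerance = 1e-9)  # only the west patch is open
  expect_equal(w2$cells$y[1], 0)
})

test_that("pure random walk has isotropic steps of the stated length", {
  p <- tiny_params(randomness = 1, deviation_from_avg = 0)
  s <- sqrt(2) * 0.23 * p$dt
  set.seed(3)
  # sparse lattice (2-patch spacing) so every cell has open space all around
  gx <- seq(-18, 18, by = 2); gy <- seq(-6, 6, by = 2)
  n <- length(gx) * length(gy)
  w <- world_with_cells(p, x = rep(gx, times = length(gy)),
                        y = rep(gy, each = length(gx)))
  w2 <- cells_diffuse(w)
  dx <- w2$cells$x - w$cells$x
  dy <- w2$cells$y - w$cells$y
  expect_equal(sqrt(dx^2 + dy^2), rep(s, n), tolerance = 1e-9)
  expect_lt(abs(mean(dx)), 3 * s / sqrt(n))
  expect_lt(abs(mean(dy)), 3 * s / sqrt(n))
})

test_that("color classes and released flags stay consistent through a run", {
  p <- tiny_params(time_scale_hours = 2, scratch_line = -5)
  run <- run_scratch(p)
  w <- run$world
  expect_true(all(w$cells$released == (w$cells$color %in% 3:6)))
  expect_true(all(diff(run$frames$cell_count) >= 0))  # no cell death
})
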