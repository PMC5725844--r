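# Small, fast parameter sets for unit tests.
tiny_params <- function(...) {
  base <- list(world_width = 41, world_height = 15, scratch_line = -10,
               time_scale_hours = 1)
  do.call(scratch_params, utils::modifyList(base, list(...)))
}

# Bare world with hand-placed cells (bypasses populate/make_scratch so tests
# can set up exact spatial configurations).
world_with_cells <- function(params, x, y, released = FALSE, color = NULL,
                             cycle = 0L, tracked = FALSE) {
  w <- scratchsim:::.make_world(params)
  n <- length(x)
  caps <- w$caps
  A <- rep(caps[["A"]], n)
  B <- rep(caps[["B"]], n)
  released <- rep_len(released, n)
  if (is.null(color)) color <- ifelse(released, 3L, 1L)
  cycle <- as.integer(rep_len(cycle, n))
  w$cells <- list(
    x = as.numeric(x), y = as.numeric(y), A = A, B = B,
    mu = scratchsim:::.cell_mu(w, A, B),
    cycle = cycle,
    phase = scratchsim:::phase_of(cycle, w$schedule),
    released = released,
    color = as.integer(rep_len(color, n)),
    tracked = rep_len(tracked, n),
    id = seq_len(n),
    disp = numeric(n)
  )
  update_density(w)
}

# Ligand-only fixture.
with_ligands <- function(world, x, y) {
  world$ligands <- list(x = as.numeric(x), y = as.numeric(y))
  update_density(world)
}
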