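test_that("pathway_rate interpolates linearly between its endpoints", {
  expect_equal(pathway_rate(0.23, 0.15, 0), 0.23)
  expect_equal(pathway_rate(0.23, 0.15, 1), 0.15)
  expect_equal(pathway_rate(0.23, 0.13, 0.5), 0.18)
  # monotone decreasing in inhibition
  grid <- seq(0, 1, by = 0.05)
  expect_true(all(diff(pathway_rate(0.23, 0.13, grid)) < 0))
})

test_that("pathway ceilings follow the knockout semantics of the base motilities", {
  # base_motility_A is the speed with B knocked out, so inhibiting B lowers
  # ceiling A toward it (and symmetrically for B; C is inhibited directly)
  caps <- pathway_caps(scratch_params(inhibition_B = 1))
  expect_equal(unname(caps), c(0.15, 0.23, 0.23))
  caps <- pathway_caps(scratch_params(inhibition_A = 1))
  expect_equal(unname(caps), c(0.23, 0.13, 0.23))
  caps <- pathway_caps(scratch_params(inhibition_C = 1))
  expect_equal(unname(caps), c(0.23, 0.23, 0.13))
})

test_that("effective motility is the most limited pathway ceiling", {
  expect_equal(effective_motility(0.23, 0.23, 0.23), 0.23)
  # B knocked out: integrin-alone rate dominates
  expect_equal(do.call(effective_motility, as.list(unname(
    pathway_caps(scratch_params(inhibition_B = 1))))), 0.15)
  # convergence fully inhibited: its base rate caps everything
  expect_equal(do.call(effective_motility, as.list(unname(
    pathway_caps(scratch_params(inhibition_C = 1))))), 0.13)
})

test_that("effective motility is non-increasing in each inhibition fraction", {
  grid <- seq(0, 1, by = 0.25)
  for (field in c("inhibition_A", "inhibition_B", "inhibition_C")) {
    mus <- vapply(grid, function(i) {
      args <- stats::setNames(list(i), field)
      caps <- pathway_caps(do.call(scratch_params, args))
      effective_motility(caps[["A"]], caps[["B"]], caps[["C"]])
    }, numeric(1))
    expect_true(all(diff(mus) <= 1e-12), info = field)
  }
})

test_that("avg_inhibition and prolif_factor have the stated endpoints", {
  expect_equal(avg_inhibition(0, 0, 0), 0)
  expect_equal(avg_inhibition(1, 1, 1), 1)
  expect_equal(avg_inhibition(0.3, 0.6, 0), 0.3)
  expect_equal(prolif_factor(0), 1)
  expect_equal(prolif_factor(0.5), 2)
  expect_equal(prolif_factor(1, floor = 0.05), 20)
  expect_true(all(diff(prolif_factor(seq(0, 1, 0.1))) > 0))
})

test_that("theoretical %S is the point-slope line through the two user inputs", {
  expect_equal(theoretical_pct_S(28, 8, 0), 28)
  expect_equal(theoretical_pct_S(28, 8, 1), 8)
  expect_equal(theoretical_pct_S(28, 8, 0.5), 18)
  # linearity: zero second differences on an even grid
  vals <- theoretical_pct_S(28, 8, seq(0, 1, by = 0.1))
  expect_equal(diff(vals, differences = 2), rep(0, length(vals) - 2))
})

test_that("phase schedule matches the baseline and full-inhibition scenarios", {
  sch <- phase_boundaries(scratch_params())
  expect_equal(sch$total, 1440L)
  expect_equal(unname(sch$spans["S"]), 403L)  # 28% of 1440
  expect_equal(unname(sch$spans["M"]), 72L)   # 5% of the uninhibited cycle
  expect_equal(sum(sch$spans), sch$total)

  full <- phase_boundaries(scratch_params(inhibition_A = 1, inhibition_B = 1,
                                          inhibition_C = 1))
  expect_equal(full$prolif_factor, 20)
  expect_equal(full$total, 28800L)
  expect_equal(full$pct_S_effective, 8)
  expect_equal(unname(full$spans["S"]), round(0.08 * 28800))
  expect_equal(sum(full$spans), full$total)
})

test_that("the S-phase change is absorbed by G1 or G2 per the switch, total conserved", {
  on <- phase_boundaries(scratch_params(inhibition_A = 0.5, inhibition_B = 0.5,
                                        inhibition_C = 0.5, s_phase_to_g1 = TRUE))
  off <- phase_boundaries(scratch_params(inhibition_A = 0.5, inhibition_B = 0.5,
                                         inhibition_C = 0.5, s_phase_to_g1 = FALSE))
  expect_equal(on$spans[["S"]], off$spans[["S"]])
  expect_equal(on$total, off$total)
  expect_false(on$spans[["G1"]] == off$spans[["G1"]])
  expect_false(on$spans[["G2"]] == off$spans[["G2"]])
  expect_equal(sum(on$spans), sum(off$spans))
})

test_that("phase durations sum to the cycle total over random valid parameters", {
  set.seed(4711)
  for (rep in 1:200) {
    params <- scratch_params(
      doubling_time_hours = runif(1, 6, 48),
      pct_S_base = runif(1, 5, 60),
      pct_S_max_inhibition = runif(1, 0, 5),
      inhibition_A = runif(1), inhibition_B = runif(1), inhibition_C = runif(1),
      s_phase_to_g1 = sample(c(TRUE, FALSE), 1)
    )
    sch <- phase_boundaries(params)
    expect_equal(sum(sch$spans), sch$total)
    expect_true(all(sch$spans >= 0))
    expect_true(all(diff(c(0, sch$boundaries, sch$total)) >= 0))
  }
})
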