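#' Linearly interpolated pathway transmission rate
#'
#' A pathway transmits the full uninhibited motility when its inhibitor is
#' absent and falls linearly to the corresponding base rate at complete
#' inhibition.
#'
#' @param uninhibited Motility with no inhibition, um/min.
#' @param base Motility at full inhibition of the controlling pathway, um/min
#'   (must be below `uninhibited`).
#' @param inhibition Inhibited fraction in \[0, 1\]. Vectorized.
#' @return Interpolated rate(s), um/min.
#' @examples
#' pathway_rate(0.23, 0.15, 0)    # 0.23
#' pathway_rate(0.23, 0.15, 1)    # 0.15
#' pathway_rate(0.23, 0.13, 0.5)  # 0.18
#' @export
pathway_rate <- function(uninhibited, base, inhibition) {
  stopifnot(all(inhibition >= 0 & inhibition <= 1), all(base < uninhibited))
  uninhibited - inhibition * (uninhibited - base)
}

#' Motility transmitted through the convergence point
#'
#' The downstream convergence (FAK, pathway C) transmits the most limited of
#' the three pathway ceilings: blocking the FGFR arm caps the cell at the
#' integrin-alone rate, blocking integrin caps it at the FGFR-alone rate, and
#' blocking the convergence itself caps everything at its own base rate.
#'
#' A convergence point could alternatively be modeled as a max over the
#' upstream arms; the min over ceilings is the form consistent with the
#' definition of the base motilities (base_motility_A is the speed measured
#' with B knocked out) and with the single-knockout endpoint speeds (0.15 and
#' 0.13 um/min). See the package vignette.
#'
#' @param rate_A,rate_B,cap_C Current pathway ceilings, um/min. Vectorized.
#' @return Effective motility mu, um/min.
#' @seealso [pathway_caps()] for how inhibition fractions produce the ceilings.
#' @export
effective_motility <- function(rate_A, rate_B, cap_C) {
  pmin(rate_A, rate_B, cap_C)
}

#' Deterministic pathway ceilings implied by a parameter set
#'
#' `base_motility_A` is the rate through integrin signaling alone (measured
#' with FGFR fully blocked), so inhibition of B interpolates ceiling A from
#' the uninhibited rate down to it; symmetrically for B; the convergence
#' ceiling C falls with its own inhibition.
#'
#' @param params A `scratch_params` object.
#' @return Named vector `c(A =, B =, C =)` of ceilings, um/min.
#' @export
pathway_caps <- function(params) {
  c(A = pathway_rate(params$uninhibited_motility, params$base_motility_A,
                     params$inhibition_B),
    B = pathway_rate(params$uninhibited_motility, params$base_motility_B,
                     params$inhibition_A),
    C = pathway_rate(params$uninhibited_motility, params$base_motility_C,
                     params$inhibition_C))
}

#' Mean inhibited fraction across the three pathways
#'
#' The average response of the signaling network is `1 - avg_inhibition(...)`;
#' it drives the proliferation scaling.
#'
#' @param iA,iB,iC Inhibited fractions in \[0, 1\].
#' @return Arithmetic mean of the three fractions.
#' @export
avg_inhibition <- function(iA, iB, iC) {
  stopifnot(all(c(iA, iB, iC) >= 0), all(c(iA, iB, iC) <= 1))
  (iA + iB + iC) / 3
}

#' Theoretical percentage of cells in S phase
#'
#' Point-slope interpolation between the user's no-inhibition and
#' full-inhibition S-phase percentages.
#'
#' @param pct_base Percent in S phase with no inhibition.
#' @param pct_max Percent in S phase at maximal inhibition (<= `pct_base`).
#' @param avg_inh Mean inhibited fraction, see [avg_inhibition()].
#' @return Percent in S phase at this inhibition level.
#' @examples
#' theoretical_pct_S(28, 8, 0)    # 28
#' theoretical_pct_S(28, 8, 1)    # 8
#' theoretical_pct_S(28, 8, 0.5)  # 18
#' @export
theoretical_pct_S <- function(pct_base, pct_max, avg_inh) {
  stopifnot(all(pct_max <= pct_base), all(avg_inh >= 0 & avg_inh <= 1))
  pct_base + avg_inh * (pct_max - pct_base)
}

#' Proliferation slow-down factor
#'
#' Reciprocal of the mean pathway response, so the cell cycle stretches as
#' inhibition rises and mitosis is suppressed at full inhibition. A small
#' floor on the response avoids division by zero.
#'
#' @param avg_inh Mean inhibited fraction.
#' @param floor Smallest allowed response (default 0.05, i.e. at most a
#'   20-fold cycle extension).
#' @return Dimensionless factor >= 1.
#' @export
prolif_factor <- function(avg_inh, floor = 0.05) {
  stopifnot(floor > 0, all(avg_inh >= 0 & avg_inh <= 1))
  1 / pmax(1 - avg_inh, floor)
}

#' Cell-cycle phase schedule for a parameter set
#'
#' The total cycle is the doubling time (in ticks) stretched by
#' [prolif_factor()]. S phase occupies the inhibition-interpolated percentage
#' of the stretched cycle; M phase has a fixed duration (a fraction of the
#' uninhibited cycle); the remainder splits equally between G1 and G2 at zero
#' inhibition, and the inhibition-induced change in S is absorbed by G1 when
#' `s_phase_to_g1` is on, else by G2. Boundaries are rounded to whole ticks
#' with the rounding remainder assigned to G1, so spans always sum exactly to
#' the total.
#'
#' @param params A `scratch_params` object.
#' @return A `cycle_schedule` list: `total`, `spans` (named G1/S/G2/M tick
#'   counts), `boundaries` (cumulative G1, G1+S, G1+S+G2), `pct_S_effective`,
#'   `prolif_factor`, `doubling_ticks`.
#' @export
phase_boundaries <- function(params) {
  stopifnot(inherits(params, "scratch_params"))
  avg <- avg_inhibition(params$inhibition_A, params$inhibition_B,
                        params$inhibition_C)
  pf <- prolif_factor(avg, params$prolif_floor)
  D <- params$doubling_ticks
  total <- as.integer(round(D * pf))
  if (total <= 4L) {
    stop("degenerate cell cycle: fewer than 5 ticks; increase doubling_time_hours",
         call. = FALSE)
  }
  pct_eff <- theoretical_pct_S(params$pct_S_base, params$pct_S_max_inhibition, avg)
  M <- as.integer(round(params$m_phase_fraction * D))
  S <- as.integer(round(pct_eff / 100 * total))
  S_ref <- as.integer(round(params$pct_S_base / 100 * total))
  g2_ref <- (total - S_ref - M) / 2
  G2 <- if (params$s_phase_to_g1) {
    as.integer(round(g2_ref))
  } else {
    as.integer(round(g2_ref + (S_ref - S)))
  }
  G1 <- total - S - G2 - M
  spans <- c(G1 = G1, S = S, G2 = G2, M = M)
  if (any(spans < 0L)) {
    stop("degenerate cell cycle: negative phase span; check pct_S_base and m_phase_fraction",
         call. = FALSE)
  }
  structure(list(
    total = total,
    spans = spans,
    boundaries = cumsum(spans)[1:3],
    pct_S_effective = pct_eff,
    prolif_factor = pf,
    doubling_ticks = D
  ), class = "cycle_schedule")
}

# Phase index (1 = G1, 2 = S, 3 = G2, 4 = M) from cycle counters.
phase_of <- function(cycle, schedule) {
  findInterval(cycle, schedule$boundaries) + 1L
}

#' @export
print.cycle_schedule <- function(x, ...) {
  cat(sprintf("cell cycle: %d ticks total (%.2fx doubling time)\n",
              x$total, x$prolif_factor))
  cat(sprintf("  G1 %d | S %d | G2 %d | M %d ticks; %%S effective %.1f\n",
              x$spans["G1"], x$spans["S"], x$spans["G2"], x$spans["M"],
              x$pct_S_effective))
  invisible(x)
}
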