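#' Default simulation parameters
#'
#' The defaults reproduce the baseline uninhibited 24 h T98G scenario:
#' uninhibited motility 0.23 um/min, integrin-alone (pathway A) 0.15 um/min,
#' FGFR-alone (pathway B) 0.13 um/min, 28% of cells in S phase dropping to 8%
#' under maximal inhibition, a 24 h doubling time, ligand speed 0.25
#' patches/tick, movement randomness 0.10 and motility deviation 0.3 um/min.
#'
#' @return Named list of raw default parameter values (not yet validated).
#' @seealso [scratch_params()], [validate_params()], [load_config()]
#' @export
default_params <- function() {
  list(
    # interface controls
    cellular_adhesion    = FALSE,
    time_scale_hours     = 24L,
    randomness           = 0.10,
    l_randomness         = 0.20,
    pct_S_base           = 28,
    pct_S_max_inhibition = 8,
    scratch_line         = 0L,
    ligand_speed         = 0.25,
    doubling_time_hours  = 24,
    base_motility_A      = 0.15,
    base_motility_B      = 0.13,
    base_motility_C      = 0.13,
    uninhibited_motility = 0.23,
    pct_decrease_A       = NULL,
    pct_decrease_B       = NULL,
    pct_decrease_C       = NULL,
    inhibition_A         = 0,
    inhibition_B         = 0,
    inhibition_C         = 0,
    deviation_from_avg   = 0.3,
    motility_check       = FALSE,
    s_phase_to_g1        = TRUE,
    trailers             = TRUE,
    seed                 = 0L,
    # world geometry and model constants
    world_width          = 65L,
    world_height         = 33L,
    patch_scale          = 20,
    confluent_density    = 0.9,
    crowding_threshold   = 2,
    m_phase_fraction     = 0.05,
    prolif_floor         = 0.05,
    rest_length          = 1,
    spring_constant      = 0.2,
    adhesion_radius      = 1.5,
    max_ligands          = Inf,
    dt                   = NULL
  )
}

#' Build and validate a simulation parameter set
#'
#' Named arguments override the defaults of [default_params()]; the merged set
#' is passed through [validate_params()]. Every interface control of the
#' simulator is reachable here; see the package vignette for units and
#' meaning.
#'
#' @param ... named parameter overrides.
#' @return A validated `scratch_params` object.
#' @examples
#' p <- scratch_params(inhibition_C = 1, seed = 7)
#' p$ticks_planned
#' @export
scratch_params <- function(...) {
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  raw <- utils::modifyList(default_params(), over, keep.null = TRUE)
  unknown <- setdiff(names(over), names(default_params()))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  attr(raw, "supplied") <- names(over)
  validate_params(raw)
}

.check_range <- function(value, field, lo, hi) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < lo || value > hi) {
    stop(sprintf("parameter '%s' must be a number in [%s, %s] (got %s)",
                 field, format(lo), format(hi),
                 paste(format(value), collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

.check_flag <- function(value, field) {
  if (!is.logical(value) || length(value) != 1 || is.na(value)) {
    stop(sprintf("parameter '%s' must be TRUE or FALSE", field), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a raw parameter map
#'
#' Fills missing fields with defaults, resolves the alternative
#' `pct_decrease_*` parameterization of the base motilities, checks every
#' invariant (ranges, base motilities below the uninhibited rate, pathway C
#' base not exceeding A or B, S-phase percentages ordered, scratch line within
#' the world) and returns an immutable parameter object. Validation is
#' idempotent: validating a validated set returns an equal set.
#'
#' @param raw Named list of parameter values, or an already validated
#'   `scratch_params` object.
#' @return A `scratch_params` object with derived fields `ticks_planned`,
#'   `doubling_ticks` and resolved `dt`.
#' @export
validate_params <- function(raw) {
  revalidation <- inherits(raw, "scratch_params")
  if (revalidation) {
    raw <- unclass(raw)
    raw$ticks_planned <- NULL
    raw$doubling_ticks <- NULL
  }
  if (!is.list(raw)) stop("'raw' must be a named list", call. = FALSE)
  defaults <- default_params()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  supplied <- attr(raw, "supplied")
  if (revalidation) supplied <- character(0)  # resolved fields are consistent
  if (is.null(supplied)) supplied <- names(raw)
  p <- utils::modifyList(defaults, raw, keep.null = TRUE)

  # Alternative parameterization: %Decrease sliders. Exactly one of the two
  # forms may be active per pathway.
  for (pw in c("A", "B", "C")) {
    dec_f <- paste0("pct_decrease_", pw)
    base_f <- paste0("base_motility_", pw)
    if (!is.null(p[[dec_f]])) {
      if (base_f %in% supplied) {
        stop(sprintf("supply either '%s' or '%s', not both", dec_f, base_f),
             call. = FALSE)
      }
      .check_range(p[[dec_f]], dec_f, 0, 100)
      p[[base_f]] <- p$uninhibited_motility * (1 - p[[dec_f]] / 100)
    }
  }

  .check_flag(p$cellular_adhesion, "cellular_adhesion")
  .check_flag(p$motility_check, "motility_check")
  .check_flag(p$s_phase_to_g1, "s_phase_to_g1")
  .check_flag(p$trailers, "trailers")
  .check_range(p$time_scale_hours, "time_scale_hours", 1, 72)
  if (p$time_scale_hours != round(p$time_scale_hours)) {
    stop("parameter 'time_scale_hours' must be a whole number of hours",
         call. = FALSE)
  }
  for (f in c("randomness", "l_randomness",
              "inhibition_A", "inhibition_B", "inhibition_C")) {
    .check_range(p[[f]], f, 0, 1)
  }
  .check_range(p$pct_S_base, "pct_S_base", 0, 100)
  .check_range(p$pct_S_max_inhibition, "pct_S_max_inhibition", 0, 100)
  if (p$pct_S_max_inhibition > p$pct_S_base) {
    stop("parameter 'pct_S_max_inhibition' must not exceed 'pct_S_base'",
         call. = FALSE)
  }
  .check_range(p$ligand_speed, "ligand_speed", 0, Inf)
  .check_range(p$doubling_time_hours, "doubling_time_hours", 1e-6, Inf)
  .check_range(p$uninhibited_motility, "uninhibited_motility", 1e-9, Inf)
  for (pw in c("A", "B", "C")) {
    f <- paste0("base_motility_", pw)
    .check_range(p[[f]], f, 0, Inf)
    if (p[[f]] >= p$uninhibited_motility) {
      stop(sprintf("parameter '%s' must be set lower than 'uninhibited_motility'", f),
           call. = FALSE)
    }
  }
  if (p$base_motility_C > p$base_motility_A) {
    stop("pathway C base exceeds A: 'base_motility_C' must be <= 'base_motility_A'",
         call. = FALSE)
  }
  if (p$base_motility_C > p$base_motility_B) {
    stop("pathway C base exceeds B: 'base_motility_C' must be <= 'base_motility_B'",
         call. = FALSE)
  }
  .check_range(p$deviation_from_avg, "deviation_from_avg", 0, Inf)
  if (!is.numeric(p$seed) || length(p$seed) != 1 || is.na(p$seed)) {
    stop("parameter 'seed' must be a single integer", call. = FALSE)
  }
  p$seed <- as.integer(p$seed)
  .check_range(p$world_width, "world_width", 3, 10000)
  .check_range(p$world_height, "world_height", 3, 10000)
  p$world_width <- as.integer(p$world_width)
  p$world_height <- as.integer(p$world_height)
  .check_range(p$patch_scale, "patch_scale", 1e-9, Inf)
  .check_range(p$confluent_density, "confluent_density", 0, Inf)
  .check_range(p$crowding_threshold, "crowding_threshold", 1e-9, Inf)
  .check_range(p$m_phase_fraction, "m_phase_fraction", 0, 0.5)
  .check_range(p$prolif_floor, "prolif_floor", 1e-9, 1)
  .check_range(p$rest_length, "rest_length", 1e-9, Inf)
  .check_range(p$spring_constant, "spring_constant", 0, Inf)
  .check_range(p$adhesion_radius, "adhesion_radius", 1e-9, Inf)
  .check_range(p$max_ligands, "max_ligands", 1, Inf)

  min_x <- -((p$world_width - 1L) %/% 2L)
  max_x <- min_x + p$world_width - 1L
  .check_range(p$scratch_line, "scratch_line", min_x, max_x)
  if (p$scratch_line != round(p$scratch_line)) {
    stop("parameter 'scratch_line' must be an integer patch coordinate",
         call. = FALSE)
  }
  p$scratch_line <- as.integer(p$scratch_line)

  # dt translates um/min speeds into patch-unit steps: the per-tick step
  # length sqrt(2)*mu*dt then equals mu (um/min) / patch_scale (um/patch).
  if (is.null(p$dt)) p$dt <- 1 / (sqrt(2) * p$patch_scale)
  .check_range(p$dt, "dt", 1e-12, Inf)

  p$ticks_planned <- as.integer(p$time_scale_hours * 60)
  p$doubling_ticks <- as.integer(round(p$doubling_time_hours * 60))
  attr(p, "supplied") <- NULL
  structure(p, class = "scratch_params")
}

#' Load a parameter set from a YAML config file
#'
#' The file is a flat YAML mapping whose keys are the parameter names of
#' [default_params()] (the simulator's interface controls, normalized to
#' snake_case). Keys not listed there are an error; missing keys take their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `scratch_params` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a YAML mapping: ", path, call. = FALSE)
  unknown <- setdiff(names(raw), names(default_params()))
  if (length(unknown) > 0) {
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  attr(raw, "supplied") <- names(raw)
  validate_params(raw)
}

#' @export
print.scratch_params <- function(x, ...) {
  cat("scratch assay simulation parameters\n")
  cat(sprintf("  world: %d x %d patches (%.0f um/patch), scratch line at x = %d\n",
              x$world_width, x$world_height, x$patch_scale, x$scratch_line))
  cat(sprintf("  time scale: %d h (%d ticks), doubling time %.1f h\n",
              x$time_scale_hours, x$ticks_planned, x$doubling_time_hours))
  cat(sprintf("  motility (um/min): uninhibited %.3f; base A %.3f, B %.3f, C %.3f\n",
              x$uninhibited_motility, x$base_motility_A, x$base_motility_B,
              x$base_motility_C))
  cat(sprintf("  inhibition: A %.2f, B %.2f, C %.2f\n",
              x$inhibition_A, x$inhibition_B, x$inhibition_C))
  cat(sprintf("  %%S: base %.1f, max inhibition %.1f; deviation %.2f; randomness %.2f\n",
              x$pct_S_base, x$pct_S_max_inhibition, x$deviation_from_avg,
              x$randomness))
  cat(sprintf("  adhesion %s; motility check %s; seed %d\n",
              if (x$cellular_adhesion) "on" else "off",
              if (x$motility_check) "on" else "off", x$seed))
  invisible(x)
}
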