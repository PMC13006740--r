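#' Desk-scale tumor state
#'
#' A deterministic micro-tumor for tests: a small domain, hex-packed disk
#' trimmed to exactly `n_cells` cells (nearest the center first), abundant
#' oxygen, no NPs.
#'
#' @param n_cells number of cells, `>= 1`.
#' @param seed RNG seed.
#' @param config optional [sim_config()] to override the default small
#'   domain.
#' @return a [sim_state][initialize_state()].
#' @export
toy_tumor <- function(n_cells = 10, seed = 1L, config = NULL) {
  stopifnot(n_cells >= 1)
  if (is.null(config))
    config <- sim_config(grid = np_grid(200, 200), t_end = 0,
                         dt_diffusion = 0.5, dt_mechanics = 1,
                         initial_radius = 0)
  spacing <- 2 * cell_radius(config$cell_volume)
  # radius generous enough to cover n_cells, then trim nearest-first
  radius <- spacing * (ceiling(sqrt(n_cells)) + 1)
  config$initial_radius <- min(radius,
                               min(config$grid$width,
                                   config$grid$height) / 2 - spacing)
  state <- initialize_state(config, seed)
  d2 <- (state$cells$x - config$grid$width / 2)^2 +
    (state$cells$y - config$grid$height / 2)^2
  keep <- order(d2)[seq_len(min(n_cells, n_cells(state$cells)))]
  state$cells <- cells_subset(state$cells, sort(keep))
  state
}

#' Single cell in a uniform NP bath
#'
#' One cell in a well-mixed NP reservoir: diffusion is disabled (`D = 0`)
#' and the field is refreshed to the bath concentration after every
#' diffusion step, so the local concentration the cell sees is constant and
#' the internalization ODE has the closed form
#' `nI(t) = n_star (1 - exp(-rI V rho t / n_star))`.
#'
#' @param rho bath NP concentration (NPs/um^3), `>= 0`.
#' @param design an [np_design()].
#' @param t_end horizon (min).
#' @param dt_phenotype phenotype step (min).
#' @return the [sim_config()] for the bath scenario.
#' @export
single_cell_bath <- function(rho, design = np_design(), t_end = 1440,
                             dt_phenotype = 6) {
  stopifnot(rho >= 0)
  sim_config(grid = np_grid(100, 100, dx = 20),
             np_D = 0,
             design = design,
             schedule = dose_schedule(times = 0, doses = 1,
                                      clearance_rate = 0,
                                      reference_dose = rho),
             phenotype = oxygen_response(b_bar = 0, rnec_bar = 0),
             apoptosis_base = 0,
             dt_diffusion = dt_phenotype, dt_mechanics = dt_phenotype,
             dt_phenotype = dt_phenotype,
             t_end = t_end, initial_radius = 0, output_every = dt_phenotype,
             bath_refresh = TRUE)
}

#' Cohort of NPs in a single release state
#'
#' `N` NPs placed in state `state_j` of a fresh compartment with zero
#' released drug -- the initial condition used by the linear-cascade oracle
#' tests.
#'
#' @param N NP count, `>= 0`.
#' @param state_j 0-based release state, `0 <= state_j < m`.
#' @param design an [np_design()].
#' @return an [np_compartment()].
#' @export
cohort_release <- function(N, state_j, design = np_design()) {
  stopifnot(N >= 0, state_j >= 0, state_j < design$m)
  n <- numeric(design$m)
  n[state_j + 1L] <- N
  np_compartment(n)
}

#' Desk-scale study configuration
#'
#' The scaled-down condition set used by the package's qualitative
#' experiments (NP design comparisons, dosing schedules, inheritance): a
#' 600 x 600 um domain with 20 um voxels, an initial tumor disk of 60 um
#' (45 cells), a 10-day horizon, quasi-steady oxygen with a drawdown strong
#' enough that growth is oxygen-limited at a few hundred cells, and coarser
#' diffusion/mechanics steps (3 min) appropriate for the unconditionally
#' stable implicit solver at this scale. All other parameters are the
#' package defaults; override via the arguments.
#'
#' @param t_end horizon (min); default 10 days.
#' @param ... further [sim_config()] arguments.
#' @return a [sim_config()].
#' @export
scaled_tumor_config <- function(t_end = 10 * 1440, ...) {
  args <- list(...)
  defaults <- list(grid = np_grid(600, 600, dx = 20),
                   initial_radius = 60,
                   t_end = t_end,
                   oxygen = list(quasi_steady = TRUE,
                                 cell_uptake_rate = 30),
                   design = scaled_np_design(),
                   schedule = scaled_dose_schedule(),
                   dt_diffusion = 3, dt_mechanics = 3, dt_phenotype = 6,
                   output_every = 720)
  do.call(sim_config, modifyList(defaults, args))
}

#' NP design on the desk-scale clock
#'
#' [np_design()] with the slow pharmacokinetic timescales compressed
#' threefold to match the compressed study horizon: intracellular NP decay
#' half-life 5/3 days (the compressed analog of the mid-range 5-day value).
#' Fast processes (release rates, drug decay) keep their values. The
#' saturation count is set to `n_star = 100` so that a single reference
#' dose approximately fills a cell's capacity -- the regime in which the
#' saturable-internalization nonlinearity is active.
#'
#' @param lambda_NP intracellular NP decay rate (1/min).
#' @param n_star per-cell NP saturation count.
#' @param ... further [np_design()] arguments.
#' @return an [np_design()].
#' @export
scaled_np_design <- function(lambda_NP = half_life_to_rate(5 / 3, "days"),
                             n_star = 100, ...) {
  np_design(lambda_NP = lambda_NP, n_star = n_star, ...)
}

#' Dose schedule on the desk-scale clock
#'
#' The scaled experiments compress the study horizon threefold (10 days in
#' place of 30), so schedule timescales compress with it: systemic
#' clearance half-life 4/3 days (in place of 4) and injection times given
#' in compressed days. The reference dose (0.04 NPs/um^3) is set so that a
#' single full dose can overfill a cell's saturation capacity -- the
#' regime in which dose fractionation is a meaningful trade-off.
#'
#' @param times_days injection times, days.
#' @param doses dose multiples.
#' @param reference_dose boundary concentration (NPs/um^3) of a unit dose.
#' @return a [dose_schedule()].
#' @export
scaled_dose_schedule <- function(times_days = 0, doses = 1,
                                 reference_dose = 0.01) {
  dose_schedule(times = times_days * 1440, doses = doses,
                clearance_rate = half_life_to_rate(4 / 3, "days"),
                reference_dose = reference_dose)
}

#' Configurations for the scaled qualitative experiments
#'
#' Named configuration sets for the package's four desk-scale treatment
#' experiments, all built on [scaled_tumor_config()]. Like the full-scale
#' study they emulate, each experiment states its own conditions:
#'
#' * `release`: slow drug release (`gamma1 = 0.02` umol/min) versus
#'   instantaneous release at matched dose, with a cytostatic drug and the
#'   slowest published intracellular decay level (15-day half-life,
#'   compressed to 5 days on the desk-scale clock). Sustained release
#'   contains cycling longer than a burst that decays away.
#' * `decay`: extracellular NP decay (30-day half-life, compressed to 10
#'   days) versus none, immediate release, cytotoxic drug: NPs lost in
#'   transit never deliver drug, so efficacy drops.
#' * `schedule`: one full dose at t = 0 versus two half doses at t = 0 and
#'   day 5 (equal total dose), cytotoxic drug at a doubled reference dose
#'   so a single bolus overfills what cells can absorb before clearance.
#' * `inheritance`: cytotoxic drug (doubled reference dose) at NP
#'   inheritance fractions 0, 0.25, and 0.5.
#'
#' @param which one of `"release"`, `"decay"`, `"schedule"`,
#'   `"inheritance"`.
#' @return named list of [sim_config()] objects.
#' @export
scaled_experiment_arms <- function(which = c("release", "decay", "schedule",
                                             "inheritance")) {
  which <- match.arg(which)
  cytotoxic <- pd_params(mode = "cytotoxic")
  switch(which,
    release = list(
      slow = scaled_tumor_config(design = scaled_np_design(
        gamma1 = 0.02, lambda_NP = half_life_to_rate(5, "days"))),
      instant = scaled_tumor_config(design = scaled_np_design(
        gamma1 = Inf, lambda_NP = half_life_to_rate(5, "days")))),
    decay = list(
      no_decay = scaled_tumor_config(
        design = scaled_np_design(gamma1 = Inf), pd = cytotoxic),
      ext_decay = scaled_tumor_config(
        design = scaled_np_design(
          gamma1 = Inf, lambda_extra = half_life_to_rate(10, "days")),
        pd = cytotoxic)),
    schedule = list(
      one_full = scaled_tumor_config(
        schedule = scaled_dose_schedule(0, 1, reference_dose = 0.02),
        pd = cytotoxic),
      two_half = scaled_tumor_config(
        schedule = scaled_dose_schedule(c(0, 5), c(0.5, 0.5),
                                        reference_dose = 0.02),
        pd = cytotoxic)),
    inheritance = list(
      x0 = scaled_tumor_config(
        schedule = scaled_dose_schedule(reference_dose = 0.02),
        pd = cytotoxic, inheritance_x = 0),
      x25 = scaled_tumor_config(
        schedule = scaled_dose_schedule(reference_dose = 0.02),
        pd = cytotoxic, inheritance_x = 0.25),
      x50 = scaled_tumor_config(
        schedule = scaled_dose_schedule(reference_dose = 0.02),
        pd = cytotoxic, inheritance_x = 0.5)))
}
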