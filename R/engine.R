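#' Simulation configuration
#'
#' Assembles every module's parameter block plus the multi-rate time
#' stepping. Diffusion runs on the fastest clock, mechanics on an
#' intermediate one, and phenotype/NP kinetics on the slowest; each step
#' must divide evenly into the next tier.
#'
#' @param grid an [np_grid()].
#' @param oxygen list with `D` (um^2/min), `lambda` (1/min bulk decay),
#'   `dirichlet` (mmHg boundary value), `cell_uptake_rate` (1/min, per-cell
#'   oxygen consumption coefficient), and optionally `quasi_steady`,
#'   `relax_dt`, `relax_iters`: because oxygen dynamics (fast diffusion,
#'   strong uptake) relax within a fraction of a minute, the engine can
#'   treat the oxygen field as quasi-static, relaxing it by `relax_iters`
#'   diffusion-uptake iterations of step `relax_dt` per phenotype step
#'   instead of integrating it on the diffusion clock. Missing entries take
#'   the defaults.
#' @param np_D NP diffusion coefficient (um^2/min).
#' @param phenotype an [oxygen_response()].
#' @param apoptosis_base baseline apoptosis rate (1/min).
#' @param cell_volume target cell volume (um^3). Daughters are born at half
#'   the parent volume and relax back toward the target exponentially at
#'   `volume_growth_rate` (simplified volume model).
#' @param volume_growth_rate volume relaxation rate (1/min).
#' @param mechanics a [mechanics_params()].
#' @param design an [np_design()].
#' @param pd a [pd_params()].
#' @param cytotoxic_bmax_multiple for cytotoxic mode, the maximally altered
#'   apoptosis rate as a multiple of `apoptosis_base`.
#' @param schedule a [dose_schedule()].
#' @param inheritance_x NP inheritance fraction per daughter, `[0, 0.5]`.
#' @param dt_diffusion,dt_mechanics,dt_phenotype time steps (min).
#' @param t_end simulation horizon (min).
#' @param initial_radius initial tumor disk radius (um).
#' @param output_every time-series cadence (min); multiple of `dt_phenotype`.
#' @param apoptosis_duration minutes an apoptotic cell shrinks before
#'   removal.
#' @param necrosis_lysis minutes a necrotic cell persists before removal.
#' @param max_cells hard cap on agent count (guards runaway configurations).
#' @param bath_refresh if `TRUE`, the NP field is reset to its Dirichlet
#'   value after every diffusion step (ideal well-mixed bath; used by the
#'   [single_cell_bath()] fixture).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid = np_grid(),
                       oxygen = list(D = 1e5, lambda = 0.1, dirichlet = 38,
                                     cell_uptake_rate = 10),
                       np_D = 6,
                       phenotype = oxygen_response(),
                       apoptosis_base = 5.31667e-05,
                       cell_volume = 2494,
                       volume_growth_rate = 0.0045,
                       mechanics = mechanics_params(),
                       design = np_design(),
                       pd = pd_params(),
                       cytotoxic_bmax_multiple = 6,
                       schedule = dose_schedule(),
                       inheritance_x = 0,
                       dt_diffusion = 0.01, dt_mechanics = 0.1,
                       dt_phenotype = 6,
                       t_end = 30 * 1440,
                       initial_radius = 100,
                       output_every = 360,
                       apoptosis_duration = 516,
                       necrosis_lysis = 1440,
                       max_cells = 50000,
                       bath_refresh = FALSE) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  cfg$oxygen <- modifyList(
    list(D = 1e5, lambda = 0.1, dirichlet = 38, cell_uptake_rate = 10,
         quasi_steady = FALSE, relax_dt = 0.05, relax_iters = 40),
    cfg$oxygen)
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every block and reports all violations at once.
#'
#' @param cfg a [sim_config()].
#' @return `cfg`, invisibly, or an error listing every violation.
#' @export
validate_sim_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(inherits(cfg$grid, "np_grid"), "grid must be an np_grid")
  chk(inherits(cfg$phenotype, "oxygen_response"),
      "phenotype must be an oxygen_response")
  chk(inherits(cfg$mechanics, "mechanics_params"),
      "mechanics must be mechanics_params")
  chk(inherits(cfg$design, "np_design"), "design must be an np_design")
  chk(inherits(cfg$pd, "pd_params"), "pd must be pd_params")
  chk(inherits(cfg$schedule, "dose_schedule"),
      "schedule must be a dose_schedule")
  chk(is.numeric(cfg$np_D) && cfg$np_D >= 0, "np_D must be >= 0")
  chk(all(unlist(cfg$oxygen[c("D", "lambda", "dirichlet",
                              "cell_uptake_rate")]) >= 0),
      "oxygen parameters must be >= 0")
  chk(cfg$apoptosis_base >= 0, "apoptosis_base must be >= 0")
  chk(cfg$cell_volume > 0, "cell_volume must be > 0")
  chk(cfg$volume_growth_rate >= 0, "volume_growth_rate must be >= 0")
  chk(cfg$inheritance_x >= 0 && cfg$inheritance_x <= 0.5,
      "inheritance_x must lie in [0, 0.5]")
  chk(cfg$cytotoxic_bmax_multiple >= 1,
      "cytotoxic_bmax_multiple must be >= 1")
  chk(cfg$dt_diffusion > 0 && cfg$dt_mechanics > 0 && cfg$dt_phenotype > 0,
      "time steps must be positive")
  chk(cfg$dt_diffusion <= cfg$dt_mechanics &&
        cfg$dt_mechanics <= cfg$dt_phenotype,
      "need dt_diffusion <= dt_mechanics <= dt_phenotype")
  near_int <- function(z) abs(z - round(z)) < 1e-9
  chk(near_int(cfg$dt_mechanics / cfg$dt_diffusion),
      "dt_diffusion must divide dt_mechanics")
  chk(near_int(cfg$dt_phenotype / cfg$dt_mechanics),
      "dt_mechanics must divide dt_phenotype")
  chk(near_int(cfg$output_every / cfg$dt_phenotype),
      "dt_phenotype must divide output_every")
  chk(cfg$t_end >= 0, "t_end must be >= 0")
  chk(cfg$initial_radius >= 0, "initial_radius must be >= 0")
  chk(2 * cfg$initial_radius < min(cfg$grid$width, cfg$grid$height),
      "initial tumor must fit inside the domain")
  if (length(errs))
    stop(paste(c("invalid configuration:", paste("-", errs)),
               collapse = "\n"), call. = FALSE)
  invisible(cfg)
}

# hexagonal lattice points within a disk of given radius (um) around (0, 0);
# radius 0 degenerates to the single center point
hex_disk <- function(radius, spacing) {
  if (radius <= 0) return(cbind(x = 0, y = 0))
  dy <- spacing * sqrt(3) / 2
  jmax <- ceiling(radius / dy)
  imax <- ceiling(radius / spacing) + 1
  pts <- list()
  for (j in (-jmax):jmax) {
    off <- if (j %% 2 == 0) 0 else spacing / 2
    xs <- ((-imax):imax) * spacing + off
    ys <- rep(j * dy, length(xs))
    keep <- xs^2 + ys^2 <= radius^2
    if (any(keep)) pts[[length(pts) + 1L]] <- cbind(xs[keep], ys[keep])
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y")
  out
}

#' Initialize a simulation state
#'
#' Seeds the RNG, hex-packs cells into a disk of the configured radius at
#' the domain center, sets the oxygen field to its Dirichlet value
#' everywhere, and starts the NP field at zero (injections arrive through
#' the boundary).
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed; one stream per run, consumed in a fixed
#'   order (event draws, then division directions, within each step).
#' @return an object of class `sim_state`.
#' @export
initialize_state <- function(config, seed = 1L) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  g <- config$grid
  spacing <- 2 * cell_radius(config$cell_volume)
  pts <- hex_disk(config$initial_radius, spacing)
  cx <- g$width / 2
  cy <- g$height / 2
  cells <- new_cell_population(pts[, 1] + cx, pts[, 2] + cy,
                               config$cell_volume, config$design$m,
                               config$apoptosis_base)
  oxy <- np_field(g, "oxygen", config$oxygen$D, config$oxygen$lambda,
                  config$oxygen$dirichlet)
  npf <- np_field(g, "np", config$np_D, config$design$lambda_extra,
                  boundary_concentration(0, config$schedule), initial = 0)
  state <- structure(
    list(time = 0, oxygen = oxy, np = npf, cells = cells,
         seed = as.integer(seed),
         ledger = list(internalized = 0, decayed_intra = 0,
                       decayed_extra = 0, cleared_death = 0,
                       lost_division = 0, spent = 0, boundary_net = 0,
                       nE0 = field_total_mass(npf))),
    class = "sim_state")
  state
}

#' Advance one phenotype step
#'
#' One full multi-rate cycle: nested diffusion steps (dosing boundary
#' update, implicit diffusion-decay, per-cell uptake), nested mechanics
#' steps (pairwise velocities, explicit position update), then the
#' phenotype/NP tier: intracellular release kinetics, drug effect,
#' phenotype interpolation, stochastic event sampling, and division/death
#' handling.
#'
#' @param state a [sim_state()].
#' @param config the [sim_config()] used to create it.
#' @return the advanced state.
#' @export
sim_step <- function(state, config) {
  dt_ph <- config$dt_phenotype
  cells <- state$cells
  led <- state$ledger
  design <- config$design
  viable <- which(cells$state == .STATE_VIABLE)
  nv <- length(viable)
  uptake_acc <- numeric(nv)
  nI <- if (nv) rowSums(cells$np[viable, , drop = FALSE]) else numeric(0)

  ## --- diffusion tier -----------------------------------------------------
  n_diff <- as.integer(round(dt_ph / config$dt_diffusion))
  dtd <- config$dt_diffusion
  oxy <- state$oxygen
  npf <- state$np
  ij <- if (nv) .voxel_index(npf, cells$x[viable], cells$y[viable],
                             ids = cells$id[viable])
        else matrix(integer(0), 0, 2)
  # NP field on the diffusion clock, with time-varying dosing boundary
  bvals <- boundary_concentration(state$time + seq_len(n_diff) * dtd,
                                  config$schedule)
  res <- .diffusion_tier_cpp(npf$values, npf$dirichlet_mask, npf$D,
                             npf$lambda, dtd, npf$dx, npf$voxel_volume,
                             bvals, ij[, 1], ij[, 2],
                             numeric(nv), cells$volume[viable], nI,
                             design$rI, design$n_star, TRUE,
                             config$bath_refresh)
  if (anyNA(res$values) || any(res$values < 0))
    stop(sprintf("numerical failure in field 'np' at t = %g min",
                 state$time), call. = FALSE)
  npf$values <- res$values
  npf$dirichlet_value <- bvals[n_diff]
  uptake_acc <- res$uptake
  nI <- nI + uptake_acc
  led$internalized <- led$internalized + sum(uptake_acc)
  led$decayed_extra <- led$decayed_extra + res$decayed
  led$boundary_net <- led$boundary_net + res$boundary
  # oxygen: either on the same clock or relaxed to quasi-steady state
  oxy_uv <- config$oxygen$cell_uptake_rate * cells$volume[viable]
  if (isTRUE(config$oxygen$quasi_steady)) {
    dto <- config$oxygen$relax_dt
    nit <- config$oxygen$relax_iters
  } else {
    dto <- dtd
    nit <- n_diff
  }
  reso <- .diffusion_tier_cpp(oxy$values, oxy$dirichlet_mask, oxy$D,
                              oxy$lambda, dto, oxy$dx, oxy$voxel_volume,
                              rep(oxy$dirichlet_value, nit),
                              ij[, 1], ij[, 2], oxy_uv,
                              cells$volume[viable], numeric(nv),
                              0, 1, FALSE, FALSE)
  if (anyNA(reso$values) || any(reso$values < 0))
    stop(sprintf("numerical failure in field 'oxygen' at t = %g min",
                 state$time), call. = FALSE)
  oxy$values <- reso$values
  state$oxygen <- oxy

  ## --- mechanics tier -----------------------------------------------------
  n_mech <- as.integer(round(dt_ph / config$dt_mechanics))
  if (n_cells(cells) > 1) {
    rad <- cell_radius(cells$volume)
    margin <- config$grid$dx / 2
    for (k in seq_len(n_mech)) {
      v <- pairwise_velocities(cells$x, cells$y, rad, config$mechanics)
      cells$x <- pmin(pmax(cells$x + v[, 1] * config$dt_mechanics, margin),
                      config$grid$width - margin)
      cells$y <- pmin(pmax(cells$y + v[, 2] * config$dt_mechanics, margin),
                      config$grid$height - margin)
    }
  }

  ## --- phenotype / NP tier ------------------------------------------------
  if (nv) {
    # simplified volume model: exponential relaxation to the target volume
    vt <- config$cell_volume
    cells$volume[viable] <- vt + (cells$volume[viable] - vt) *
      exp(-config$volume_growth_rate * dt_ph)
    tab <- release_rate_table(design)
    if (is_immediate_release(design)) {
      # arrivals deliver their full load on arrival and park, spent, in the
      # final state; only decay acts afterwards
      cells$np[viable, design$m] <- cells$np[viable, design$m] + uptake_acc
      cells$C[viable] <- cells$C[viable] + uptake_acc * design$C_star
      influx <- numeric(nv)
    } else influx <- uptake_acc
    # only cells with NP/drug content (or fresh influx) need kinetics
    act <- which(cells$C[viable] != 0 | influx != 0 | nI != 0)
    if (length(act)) {
      va <- viable[act]
      nsub <- .cascade_substeps(design, dt_ph)
      cas <- .cascade_advance_cpp(cells$np[va, , drop = FALSE], influx[act],
                                  cells$C[va], tab$alpha, tab$r,
                                  design$lambda_NP, design$lambda_drug,
                                  dt_ph, nsub)
      cells$np[va, ] <- cas$n
      cells$C[va] <- cas$C
      led$decayed_intra <- led$decayed_intra + cas$decayed
      led$spent <- led$spent + cas$spent
    }
    vols <- cells$volume[viable]
    conc <- cells$C[viable] / vols
    cells$auc[viable] <- cells$auc[viable] + conc * dt_ph

    pd <- config$pd
    E <- if (pd$model == "hill") hill_effect(conc, pd)
         else hill_effect(cells$auc[viable], pd)
    cells$E[viable] <- E

    sigma <- state$oxygen$values[.voxel_index(state$oxygen, cells$x[viable],
                                              cells$y[viable])]
    b_ox <- proliferation_rate(sigma, config$phenotype)
    r_nec <- necrosis_rate(sigma, config$phenotype)
    if (pd$mode == "cytostatic") {
      bmax <- if (is.null(pd$bmax)) 0 else pd$bmax
      b_cur <- b_ox + (bmax - b_ox) * E / pd$Emax
      d_cur <- rep(config$apoptosis_base, nv)
    } else {
      b_cur <- b_ox
      d0 <- config$apoptosis_base
      dmax <- d0 * config$cytotoxic_bmax_multiple
      d_cur <- d0 + (dmax - d0) * E / pd$Emax
    }
    cells$b_cur[viable] <- b_cur
    cells$d_cur[viable] <- d_cur

    ev <- sample_cell_events(b_cur, d_cur, r_nec, dt_ph)

    kill <- viable[ev >= 2L]
    if (length(kill)) {
      led$cleared_death <- led$cleared_death +
        sum(cells$np[kill, , drop = FALSE])
      cells$np[kill, ] <- 0
      nec <- kill[ev[ev >= 2L] == 3L]
      apo <- kill[ev[ev >= 2L] == 2L]
      cells$state[nec] <- .STATE_NECROTIC
      cells$timer[nec] <- config$necrosis_lysis
      cells$state[apo] <- .STATE_APOPTOTIC
      cells$timer[apo] <- config$apoptosis_duration
    }
    for (i in viable[ev == 1L]) {
      dv <- divide_cell(cells, i, config$inheritance_x)
      cells <- dv$cells
      led$lost_division <- led$lost_division + dv$lost
    }
    if (n_cells(cells) > config$max_cells)
      stop(sprintf("cell count exceeded max_cells (%d) at t = %g min",
                   config$max_cells, state$time), call. = FALSE)
  }

  pd_res <- progress_death(cells, dt_ph)
  cells <- pd_res$cells
  if (any(pd_res$remove)) cells <- cells_subset(cells, !pd_res$remove)

  state$np <- npf
  state$cells <- cells
  state$ledger <- led
  state$time <- state$time + dt_ph
  state
}

#' Audit the NP mass ledger
#'
#' Recomputes the extracellular and intracellular NP mass from the current
#' state and compares each against the ledger's flow accounting:
#' `nE = nE0 + boundary - extracellular decay - internalized` and
#' `sum(nI) = internalized - intracellular decay - death clearance -
#' division loss - spent`. Residuals are reported relative to the total NP
#' throughput.
#'
#' @param state a [sim_state()].
#' @return list with absolute and relative residuals for both pools.
#' @export
audit_mass <- function(state) {
  led <- state$ledger
  nE <- field_total_mass(state$np)
  nI <- sum(state$cells$np)
  exp_E <- led$nE0 + led$boundary_net - led$decayed_extra - led$internalized
  exp_I <- led$internalized - led$decayed_intra - led$cleared_death -
    led$lost_division - led$spent
  scale <- max(led$nE0 + abs(led$boundary_net) + led$internalized, 1e-12)
  list(extracellular_residual = nE - exp_E,
       intracellular_residual = nI - exp_I,
       relative = max(abs(nE - exp_E), abs(nI - exp_I)) / scale)
}

# one time-series record
.series_row <- function(state) {
  st <- state$cells$state
  data.frame(time = state$time,
             viable = sum(st == .STATE_VIABLE),
             apoptotic = sum(st == .STATE_APOPTOTIC),
             necrotic = sum(st == .STATE_NECROTIC),
             n_extracellular = field_total_mass(state$np),
             n_intracellular = sum(state$cells$np),
             drug_total = sum(state$cells$C))
}

#' Per-cell snapshot table
#'
#' One row per cell: id, position, volume, state label, current cycling and
#' apoptosis rates, total internalized NPs, released drug, effect, and the
#' m release-state populations (`np_state_0 ...`).
#'
#' @param state a [sim_state()].
#' @return a data.frame.
#' @export
state_snapshot <- function(state) {
  cl <- state$cells
  m <- ncol(cl$np)
  out <- data.frame(id = cl$id, x = cl$x, y = cl$y, volume = cl$volume,
                    state = .state_label(cl$state), b_current = cl$b_cur,
                    apoptosis_current = cl$d_cur,
                    total_np = rowSums(cl$np), C = cl$C, E = cl$E)
  np <- as.data.frame(cl$np)
  names(np) <- paste0("np_state_", seq_len(m) - 1L)
  cbind(out, np)
}

#' Run a simulation
#'
#' Executes the configured run to `t_end`, recording the population and
#' mass time series at the output cadence (including t = 0).
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @param audit_every if `TRUE`, the mass ledger is audited at every output
#'   time and the worst relative residual is returned.
#' @param snapshot_times optional vector of times (min) at which to save
#'   per-cell snapshots.
#' @return an object of class `sim_trajectory`: list with `series`
#'   (data.frame), `final_state`, `snapshots`, `config`, `seed`, and
#'   `max_audit_residual`.
#' @export
run_simulation <- function(config, seed = 1L, audit_every = FALSE,
                           snapshot_times = NULL) {
  state <- initialize_state(config, seed)
  rows <- list(.series_row(state))
  snaps <- list()
  worst <- 0
  record_every <- as.integer(round(config$output_every / config$dt_phenotype))
  nstep <- as.integer(floor(config$t_end / config$dt_phenotype + 1e-9))
  for (s in seq_len(nstep)) {
    state <- sim_step(state, config)
    if (s %% record_every == 0L || s == nstep) {
      rows[[length(rows) + 1L]] <- .series_row(state)
      if (audit_every) worst <- max(worst, audit_mass(state)$relative)
    }
    if (!is.null(snapshot_times) &&
        any(abs(snapshot_times - state$time) < config$dt_phenotype / 2))
      snaps[[sprintf("t%g", state$time)]] <- state_snapshot(state)
  }
  series <- do.call(rbind, rows)
  series <- series[!duplicated(series$time), , drop = FALSE]
  rownames(series) <- NULL
  structure(list(series = series, final_state = state, snapshots = snaps,
                 config = config, seed = as.integer(seed),
                 max_audit_residual = if (audit_every) worst else NA_real_),
            class = "sim_trajectory")
}
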