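# YAML configuration dialect
#
# One block per module; every key is optional and falls back to the package
# default. Keys whose defaults stand in for unpublished values are flagged
# "assumed" in the schema below (see also the package vignette).
.config_schema <- list(
  grid = c("width", "height", "dx", "slab_thickness"),
  oxygen = c("D", "lambda", "dirichlet", "cell_uptake_rate",
             "quasi_steady", "relax_dt", "relax_iters"),
  np_transport = c("D"),
  cell_phenotype = c("b_bar", "sigma1", "sigma2", "rnec_bar", "sigma3",
                     "sigma4", "apoptosis_base", "cell_volume",
                     "volume_growth_rate"),
  mechanics = c("adhesion", "repulsion", "max_adhesion_factor", "drag"),
  np_design = c("rI", "n_star", "lambda_NP", "lambda_extra", "m", "C_star",
                "gamma1", "lambda_drug", "exhausted_removal",
                "midpoint_load"),
  pd = c("model", "Emax", "EC50", "hill_n", "mode",
         "cytotoxic_bmax_multiple"),
  schedule = c("injections", "clearance_half_life_days", "reference_dose"),
  engine = c("dt_diffusion", "dt_mechanics", "dt_phenotype", "t_end_days",
             "initial_radius", "output_every", "inheritance_x",
             "max_cells")
)

#' Load a simulation configuration from YAML
#'
#' Reads the package's YAML configuration dialect (one block per module;
#' any omitted key takes the package default) and returns a validated
#' [sim_config()]. Validation reports every violation, not just the first.
#' Schedule injections are given as `{time_days, dose_multiple}` pairs plus
#' a `clearance_half_life_days`.
#'
#' @param path path to a YAML file.
#' @return a [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  config_from_list(doc)
}

#' Build a configuration from a nested list
#'
#' The list form of the YAML dialect (see [load_config()]).
#'
#' @param doc nested named list.
#' @return a [sim_config()].
#' @export
config_from_list <- function(doc) {
  errs <- character(0)
  for (block in names(doc)) {
    if (!block %in% names(.config_schema)) {
      errs <- c(errs, sprintf("unknown block '%s'", block))
      next
    }
    bad <- setdiff(names(doc[[block]]), .config_schema[[block]])
    if (length(bad))
      errs <- c(errs, sprintf("unknown key(s) in '%s': %s", block,
                              paste(bad, collapse = ", ")))
  }
  g <- function(block, key, default) {
    v <- doc[[block]][[key]]
    if (is.null(v)) default else v
  }
  x_inh <- g("engine", "inheritance_x", 0)
  if (x_inh < 0 || x_inh > 0.5)
    errs <- c(errs, sprintf(
      "engine.inheritance_x = %g outside [0, 0.5]: daughters can inherit at most 50%% each",
      x_inh))
  inj <- g("schedule", "injections", list(list(time_days = 0,
                                               dose_multiple = 1)))
  times <- vapply(inj, function(z) as.numeric(z$time_days), numeric(1)) * 1440
  doses <- vapply(inj, function(z) as.numeric(z$dose_multiple), numeric(1))
  if (length(errs))
    stop(paste(c("invalid configuration:", paste("-", errs)),
               collapse = "\n"), call. = FALSE)
  gamma1 <- g("np_design", "gamma1", 0.1)
  if (identical(gamma1, "immediate")) gamma1 <- Inf
  cfg <- sim_config(
    grid = np_grid(g("grid", "width", 400), g("grid", "height", 400),
                   g("grid", "dx", 20), g("grid", "slab_thickness", 20)),
    oxygen = list(D = g("oxygen", "D", 1e5),
                  lambda = g("oxygen", "lambda", 0.1),
                  dirichlet = g("oxygen", "dirichlet", 38),
                  cell_uptake_rate = g("oxygen", "cell_uptake_rate", 10),
                  quasi_steady = g("oxygen", "quasi_steady", FALSE),
                  relax_dt = g("oxygen", "relax_dt", 0.05),
                  relax_iters = g("oxygen", "relax_iters", 40)),
    np_D = g("np_transport", "D", 6),
    phenotype = oxygen_response(
      b_bar = g("cell_phenotype", "b_bar", 0.00072),
      sigma1 = g("cell_phenotype", "sigma1", 5),
      sigma2 = g("cell_phenotype", "sigma2", 38),
      rnec_bar = g("cell_phenotype", "rnec_bar", 1 / 360),
      sigma3 = g("cell_phenotype", "sigma3", 5),
      sigma4 = g("cell_phenotype", "sigma4", 2.5)),
    apoptosis_base = g("cell_phenotype", "apoptosis_base", 5.31667e-05),
    cell_volume = g("cell_phenotype", "cell_volume", 2494),
    volume_growth_rate = g("cell_phenotype", "volume_growth_rate", 0.0045),
    mechanics = mechanics_params(
      adhesion = g("mechanics", "adhesion", 0.4),
      repulsion = g("mechanics", "repulsion", 10),
      max_adhesion_factor = g("mechanics", "max_adhesion_factor", 1.25),
      drag = g("mechanics", "drag", 1)),
    design = np_design(
      rI = g("np_design", "rI", 0.0058),
      n_star = g("np_design", "n_star", 500),
      lambda_NP = g("np_design", "lambda_NP",
                    half_life_to_rate(5, "days")),
      lambda_extra = g("np_design", "lambda_extra", 0),
      m = g("np_design", "m", 10),
      C_star = g("np_design", "C_star", 10),
      gamma1 = gamma1,
      lambda_drug = g("np_design", "lambda_drug",
                      half_life_to_rate(8, "hours")),
      exhausted_removal = g("np_design", "exhausted_removal", FALSE),
      midpoint_load = g("np_design", "midpoint_load", FALSE)),
    pd = pd_params(model = g("pd", "model", "hill"),
                   Emax = g("pd", "Emax", 1),
                   EC50 = g("pd", "EC50", 0.03),
                   hill_n = g("pd", "hill_n", 2),
                   mode = g("pd", "mode", "cytostatic")),
    cytotoxic_bmax_multiple = g("pd", "cytotoxic_bmax_multiple", 6),
    schedule = dose_schedule(
      times = times, doses = doses,
      clearance_rate = half_life_to_rate(
        g("schedule", "clearance_half_life_days", 4), "days"),
      reference_dose = g("schedule", "reference_dose", 0.01)),
    inheritance_x = x_inh,
    dt_diffusion = g("engine", "dt_diffusion", 0.01),
    dt_mechanics = g("engine", "dt_mechanics", 0.1),
    dt_phenotype = g("engine", "dt_phenotype", 6),
    t_end = g("engine", "t_end_days", 30) * 1440,
    initial_radius = g("engine", "initial_radius", 100),
    output_every = g("engine", "output_every", 360),
    max_cells = g("engine", "max_cells", 50000))
  cfg
}

#' Serialize a configuration to the YAML dialect
#'
#' Writing then re-loading yields an equivalent configuration
#' (round-trip).
#'
#' @param config a [sim_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  d <- config$design
  s <- config$schedule
  p <- config$phenotype
  doc <- list(
    grid = list(width = config$grid$width, height = config$grid$height,
                dx = config$grid$dx,
                slab_thickness = config$grid$slab_thickness),
    oxygen = config$oxygen,
    np_transport = list(D = config$np_D),
    cell_phenotype = list(b_bar = p$b_bar, sigma1 = p$sigma1,
                          sigma2 = p$sigma2, rnec_bar = p$rnec_bar,
                          sigma3 = p$sigma3, sigma4 = p$sigma4,
                          apoptosis_base = config$apoptosis_base,
                          cell_volume = config$cell_volume,
                          volume_growth_rate = config$volume_growth_rate),
    mechanics = unclass(config$mechanics),
    np_design = list(rI = d$rI, n_star = d$n_star, lambda_NP = d$lambda_NP,
                     lambda_extra = d$lambda_extra, m = d$m,
                     C_star = d$C_star,
                     gamma1 = if (is.infinite(d$gamma1)) "immediate"
                              else d$gamma1,
                     lambda_drug = d$lambda_drug,
                     exhausted_removal = d$exhausted_removal,
                     midpoint_load = d$midpoint_load),
    pd = list(model = config$pd$model, Emax = config$pd$Emax,
              EC50 = config$pd$EC50, hill_n = config$pd$hill_n,
              mode = config$pd$mode,
              cytotoxic_bmax_multiple = config$cytotoxic_bmax_multiple),
    schedule = list(
      injections = Map(function(t, dd) list(time_days = t / 1440,
                                            dose_multiple = dd),
                       s$times, s$doses),
      clearance_half_life_days = rate_to_half_life(s$clearance_rate,
                                                   "days"),
      reference_dose = s$reference_dose),
    engine = list(dt_diffusion = config$dt_diffusion,
                  dt_mechanics = config$dt_mechanics,
                  dt_phenotype = config$dt_phenotype,
                  t_end_days = config$t_end / 1440,
                  initial_radius = config$initial_radius,
                  output_every = config$output_every,
                  inheritance_x = config$inheritance_x,
                  max_cells = config$max_cells))
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Write run outputs to a directory
#'
#' Emits the time-series CSV, the final cell snapshot, any requested
#' per-time snapshots, dense CSV matrices of the oxygen and NP fields, and
#' a JSON run manifest (config, seed, package version, config hash) from
#' which the run can be reproduced exactly.
#'
#' @param traj a [run_simulation()] trajectory, or `NULL` for a
#'   manifest-only directory.
#' @param out_dir output directory (created if needed).
#' @param config required when `traj` is `NULL`.
#' @return character vector of files written, invisibly.
#' @export
write_outputs <- function(traj, out_dir, config = traj$config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(f) written <<- c(written, f)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  put(cfg_path)
  manifest <- list(package = "nanoabm",
                   version = as.character(packageVersion("nanoabm")),
                   seed = if (!is.null(traj)) traj$seed else NA,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   files = character(0))
  if (!is.null(traj)) {
    f <- file.path(out_dir, "series.csv")
    write.csv(traj$series, f, row.names = FALSE)
    put(f)
    f <- file.path(out_dir, "cells_final.csv")
    write.csv(state_snapshot(traj$final_state), f, row.names = FALSE)
    put(f)
    for (fieldname in c("oxygen", "np")) {
      f <- file.path(out_dir, paste0("field_", fieldname, ".csv"))
      write.table(traj$final_state[[fieldname]]$values, f, sep = ",",
                  row.names = FALSE, col.names = FALSE)
      put(f)
    }
    for (nm in names(traj$snapshots)) {
      f <- file.path(out_dir, paste0("cells_", nm, ".csv"))
      write.csv(traj$snapshots[[nm]], f, row.names = FALSE)
      put(f)
    }
  }
  manifest$files <- basename(written)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  put(mf)
  invisible(written)
}
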