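#' Regular 2D voxel grid for diffusible substrates
#'
#' The microenvironment is discretized into square voxels of edge `dx`. A 2D
#' simulation carries a slab thickness so that voxel volumes (and therefore
#' NP numbers derived from concentrations) are well defined.
#'
#' @param width,height domain extent (um). Must be integer multiples of `dx`.
#' @param dx voxel edge length (um). Default 20 um (cell-sized voxels).
#' @param slab_thickness out-of-plane thickness (um) used to convert areal
#'   voxels to volumes; default one voxel (20 um).
#' @return an object of class `np_grid`.
#' @export
np_grid <- function(width = 400, height = width, dx = 20, slab_thickness = 20) {
  if (!is.numeric(width) || !is.numeric(height) || !is.numeric(dx) ||
      width <= 0 || height <= 0 || dx <= 0 || slab_thickness <= 0)
    stop("grid dimensions must be positive", call. = FALSE)
  nx <- width / dx
  ny <- height / dx
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("domain extent must be an integer multiple of dx", call. = FALSE)
  structure(
    list(width = width, height = height, dx = dx,
         nx = as.integer(round(nx)), ny = as.integer(round(ny)),
         slab_thickness = slab_thickness,
         voxel_volume = dx * dx * slab_thickness),
    class = "np_grid")
}

#' Create a diffusible substrate field
#'
#' A field holds one scalar concentration per voxel (oxygen in mmHg, NPs in
#' NPs/um^3) together with its diffusion coefficient, bulk decay rate, and
#' Dirichlet boundary data. All four domain edges are flagged Dirichlet,
#' modeling a vascularized far-field that supplies the substrate.
#'
#' @param grid an [np_grid()].
#' @param name field label, e.g. `"oxygen"` or `"np"`.
#' @param D diffusion coefficient (um^2/min), `>= 0`.
#' @param lambda bulk decay rate (1/min), `>= 0`.
#' @param dirichlet_value concentration imposed on boundary voxels.
#' @param initial interior initial value; defaults to `dirichlet_value`
#'   (appropriate for oxygen). Use 0 for a substrate absent at t = 0 (NPs).
#' @return an object of class `np_field`.
#' @export
np_field <- function(grid, name, D, lambda, dirichlet_value,
                     initial = dirichlet_value) {
  stopifnot(inherits(grid, "np_grid"))
  if (D < 0 || lambda < 0)
    stop("diffusion and decay rates must be non-negative", call. = FALSE)
  values <- matrix(initial, grid$nx, grid$ny)
  mask <- matrix(FALSE, grid$nx, grid$ny)
  mask[1, ] <- TRUE; mask[grid$nx, ] <- TRUE
  mask[, 1] <- TRUE; mask[, grid$ny] <- TRUE
  values[mask] <- dirichlet_value
  structure(
    list(name = name, values = values, D = D, lambda = lambda,
         dirichlet_mask = mask, dirichlet_value = dirichlet_value,
         dx = grid$dx, voxel_volume = grid$voxel_volume, grid = grid),
    class = "np_field")
}

#' Total substrate mass on a field
#'
#' For the NP field this is the total number of non-internalized NPs in the
#' domain, `nE = sum(values) * voxel_volume`.
#'
#' @param field an [np_field()].
#' @return total mass (substrate units times um^3, i.e. NP number for NPs).
#' @export
field_total_mass <- function(field) {
  sum(field$values) * field$voxel_volume
}

#' One implicit diffusion-decay step
#'
#' Advances the reaction-diffusion equation `drho/dt = D lap(rho) - lambda rho`
#' by one time step with a dimension-split (locally one-dimensional) backward
#' Euler scheme: tridiagonal solves along x then y, then pointwise implicit
#' decay, then re-pinning of Dirichlet voxels. The scheme is unconditionally
#' stable and first-order accurate in time.
#'
#' The decayed mass for the step is recorded in `attr(field, "decayed_mass")`
#' and the net mass supplied (or absorbed) through the Dirichlet boundary in
#' `attr(field, "boundary_mass")`, for mass-ledger accounting.
#'
#' @param field an [np_field()].
#' @param dt time step (min), `> 0`.
#' @return the updated field.
#' @export
diffuse_decay_step <- function(field, dt) {
  stopifnot(inherits(field, "np_field"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  mass_before <- sum(field$values)
  res <- .lod_diffusion_cpp(field$values, field$dirichlet_mask, field$D,
                            field$lambda, dt, field$dx, field$dirichlet_value)
  vals <- res$values
  if (anyNA(vals) || any(vals < 0))
    stop(sprintf("numerical failure in field '%s' during diffusion step (dt = %g)",
                 field$name, dt), call. = FALSE)
  field$values <- vals
  decayed <- res$decayed * field$voxel_volume
  boundary <- (sum(vals) - mass_before) * field$voxel_volume + decayed
  attr(field, "decayed_mass") <- decayed
  attr(field, "boundary_mass") <- boundary
  field
}

# voxel index (i, j) of a set of points; errors name the offending cell
.voxel_index <- function(field, x, y, ids = NULL) {
  i <- floor(x / field$dx) + 1L
  j <- floor(y / field$dx) + 1L
  bad <- i < 1L | i > field$grid$nx | j < 1L | j > field$grid$ny
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad)[1] else ids[bad][1]
    stop(sprintf("cell %s lies outside the domain", who), call. = FALSE)
  }
  cbind(i, j)
}

#' Apply per-cell uptake sinks to a field
#'
#' Each cell removes substrate from the voxel containing its center. The
#' voxel update is implicit, `rho' = rho / (1 + dt * sum(U_i V_i) / V_voxel)`
#' over the cells sharing the voxel, and each cell's uptaken amount is its
#' share `U_i V_i rho' dt` -- so the mass removed from the field equals the
#' summed uptake exactly (conservative exchange).
#'
#' @param field an [np_field()].
#' @param x,y cell center coordinates (um).
#' @param uv per-cell uptake volume rates `U_i * V_i` (um^3/min).
#' @param dt time step (min).
#' @param ids optional cell ids used in error messages.
#' @return list with elements `field` (updated), `uptake` (per-cell uptaken
#'   mass, NP number for the NP field), and `removed` (total mass removed).
#' @export
apply_cell_uptake <- function(field, x, y, uv, dt, ids = NULL) {
  stopifnot(inherits(field, "np_field"), length(x) == length(y),
            length(uv) == length(x))
  if (length(x) == 0L)
    return(list(field = field, uptake = numeric(0), removed = 0))
  ij <- .voxel_index(field, x, y, ids)
  res <- .cell_uptake_cpp(field$values, ij[, 1], ij[, 2], as.numeric(uv),
                          dt, field$voxel_volume)
  field$values <- res$values
  list(field = field, uptake = res$uptake, removed = res$removed)
}
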