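#' Oxygen response parameters for proliferation and necrosis
#'
#' Live cells divide at an oxygen-modulated birth rate that ramps linearly
#' from 0 at the proliferation threshold `sigma1` to the reference rate
#' `b_bar` at the saturation `sigma2`. Below the necrosis threshold `sigma3`
#' the necrotic death rate ramps linearly up to `rnec_bar`, reached at
#' `sigma4`. Defaults follow common framework conventions for generic tumor
#' cells (reference cycle entry about once per day under full oxygenation;
#' physioxic thresholds in mmHg); they are assumptions, not measured values.
#'
#' @param b_bar reference proliferation rate (1/min).
#' @param sigma1 oxygen proliferation threshold (mmHg).
#' @param sigma2 oxygen proliferation saturation (mmHg).
#' @param rnec_bar maximum necrosis rate (1/min).
#' @param sigma3 oxygen necrosis threshold (mmHg).
#' @param sigma4 oxygen value of maximal necrosis (mmHg).
#' @return an object of class `oxygen_response`.
#' @export
oxygen_response <- function(b_bar = 0.00072, sigma1 = 5, sigma2 = 38,
                            rnec_bar = 1 / 360, sigma3 = 5, sigma4 = 2.5) {
  if (sigma1 >= sigma2) stop("sigma1 must be < sigma2", call. = FALSE)
  if (sigma4 >= sigma3) stop("sigma4 must be < sigma3", call. = FALSE)
  if (b_bar < 0 || rnec_bar < 0) stop("rates must be >= 0", call. = FALSE)
  structure(list(b_bar = b_bar, sigma1 = sigma1, sigma2 = sigma2,
                 rnec_bar = rnec_bar, sigma3 = sigma3, sigma4 = sigma4),
            class = "oxygen_response")
}

#' Oxygen-dependent birth rate
#'
#' `b(sigma) = b_bar * min(1, max((sigma - sigma1)/(sigma2 - sigma1), 0))`.
#'
#' @param sigma local oxygen (mmHg); vectorized.
#' @param p an [oxygen_response()].
#' @return birth rate(s), 1/min.
#' @export
proliferation_rate <- function(sigma, p) {
  p$b_bar * pmin(1, pmax((sigma - p$sigma1) / (p$sigma2 - p$sigma1), 0))
}

#' Oxygen-dependent necrosis rate
#'
#' `rnec(sigma) = rnec_bar * min(1, max((sigma3 - sigma)/(sigma3 - sigma4), 0))`.
#'
#' @inheritParams proliferation_rate
#' @return necrosis rate(s), 1/min.
#' @export
necrosis_rate <- function(sigma, p) {
  p$rnec_bar * pmin(1, pmax((p$sigma3 - sigma) / (p$sigma3 - p$sigma4), 0))
}

#' Cell-cell mechanics parameters
#'
#' Center-based pairwise mechanics with the standard polynomial potential:
#' repulsion with compact support on the summed radii, adhesion with compact
#' support on `max_adhesion_factor` times the summed radii. In the
#' inertialess regime each cell's velocity is the net force divided by the
#' drag coefficient; with `drag = 1` the strengths are effectively in um/min.
#'
#' @param adhesion adhesive force scale.
#' @param repulsion repulsive force scale.
#' @param max_adhesion_factor adhesion interaction range as a multiple of the
#'   summed cell radii.
#' @param drag viscous drag coefficient.
#' @return an object of class `mechanics_params`.
#' @export
mechanics_params <- function(adhesion = 0.4, repulsion = 10,
                             max_adhesion_factor = 1.25, drag = 1) {
  if (any(c(adhesion, repulsion, max_adhesion_factor, drag) < 0) || drag == 0)
    stop("mechanics parameters must be non-negative (drag > 0)", call. = FALSE)
  structure(list(adhesion = adhesion, repulsion = repulsion,
                 max_adhesion_factor = max_adhesion_factor, drag = drag),
            class = "mechanics_params")
}

#' Pairwise cell velocities
#'
#' Computes every cell's velocity from the pairwise adhesion-repulsion
#' forces. Forces are antisymmetric, so total momentum is zero. Coincident
#' centers repel along a random direction drawn from the run's RNG stream.
#'
#' @param x,y cell center coordinates (um).
#' @param radius cell radii (um).
#' @param mech a [mechanics_params()].
#' @return an n x 2 matrix of velocities (um/min).
#' @export
pairwise_velocities <- function(x, y, radius, mech) {
  stopifnot(inherits(mech, "mechanics_params"))
  .pairwise_velocities_cpp(as.numeric(x), as.numeric(y), as.numeric(radius),
                           mech$adhesion, mech$repulsion,
                           mech$max_adhesion_factor, mech$drag)
}

#' Cell radius from volume
#' @param volume cell volume(s), um^3.
#' @return radius (um) of the sphere of that volume.
#' @export
cell_radius <- function(volume) (3 * volume / (4 * pi))^(1 / 3)

#' Sample per-cell stochastic events for one phenotype step
#'
#' Each viable cell carries independent exponential clocks for necrosis,
#' apoptosis, and division; over a step of length `dt` each event fires with
#' probability `1 - exp(-rate * dt)`. Draws are taken in the fixed order
#' necrosis, apoptosis, division, and if several fire in the same step the
#' precedence is necrose > apoptose > divide.
#'
#' @param b division rate(s) (1/min), vectorized over cells.
#' @param d_apop apoptosis rate(s) (1/min).
#' @param d_nec necrosis rate(s) (1/min).
#' @param dt step length (min).
#' @return integer vector of events: 0 none, 1 divide, 2 apoptose, 3 necrose.
#' @export
sample_cell_events <- function(b, d_apop, d_nec, dt) {
  n <- length(b)
  stopifnot(length(d_apop) == n, length(d_nec) == n)
  if (any(c(b, d_apop, d_nec) < 0))
    stop("event rates must be non-negative", call. = FALSE)
  if (n == 0L) return(integer(0))
  u_nec <- runif(n)
  u_apop <- runif(n)
  u_div <- runif(n)
  nec <- u_nec < -expm1(-d_nec * dt)
  apop <- u_apop < -expm1(-d_apop * dt)
  div <- u_div < -expm1(-b * dt)
  ev <- integer(n)
  ev[div] <- 1L
  ev[apop] <- 2L
  ev[nec] <- 3L
  ev
}

# ---- cell population (struct-of-arrays) ------------------------------------

# The engine keeps cells as parallel vectors plus an (n x m) matrix of NP
# release-state populations; this is what makes whole-population updates
# vectorizable.
new_cell_population <- function(x, y, volume, m, base_apoptosis, next_id = 1L) {
  n <- length(x)
  list(
    id = seq.int(next_id, length.out = n),
    x = as.numeric(x), y = as.numeric(y),
    volume = rep_len(as.numeric(volume), n),
    state = rep(.STATE_VIABLE, n),
    timer = numeric(n),
    b_cur = numeric(n),
    d_cur = rep_len(base_apoptosis, n),
    E = numeric(n),
    C = numeric(n),
    auc = numeric(n),
    np = matrix(0, n, m),
    next_id = next_id + n
  )
}

n_cells <- function(cells) length(cells$id)

cells_subset <- function(cells, keep) {
  out <- lapply(cells[setdiff(names(cells), c("np", "next_id"))], `[`, keep)
  out$np <- cells$np[keep, , drop = FALSE]
  out$next_id <- cells$next_id
  out
}

#' Divide one cell of a population
#'
#' The parent is replaced in place by one daughter and the second daughter is
#' appended. Daughters are placed at the parent center plus/minus half the
#' parent radius along a uniformly random direction, each with half the
#' parent volume. The NP compartment is split by [split_on_division()] with
#' inheritance fraction `x_inherit`; released drug and AUC split 50/50.
#'
#' @param cells a cell population (internal struct-of-arrays form).
#' @param i index of the dividing cell.
#' @param x_inherit inheritance fraction per daughter, in `[0, 0.5]`.
#' @return list with the updated population and `lost` (NP number removed
#'   from the system by partial inheritance).
#' @export
divide_cell <- function(cells, i, x_inherit) {
  if (x_inherit < 0 || x_inherit > 0.5)
    stop("inheritance fraction must lie in [0, 0.5]", call. = FALSE)
  theta <- runif(1) * 2 * pi
  r_half <- cell_radius(cells$volume[i]) / 2
  ox <- cos(theta) * r_half
  oy <- sin(theta) * r_half
  sp <- split_on_division(
    np_compartment(cells$np[i, ], C = cells$C[i], auc = cells$auc[i]),
    x_inherit)
  vol2 <- cells$volume[i] / 2
  x1 <- cells$x[i] + ox; y1 <- cells$y[i] + oy
  x2 <- cells$x[i] - ox; y2 <- cells$y[i] - oy
  # first daughter replaces the parent slot
  cells$x[i] <- x1; cells$y[i] <- y1
  cells$volume[i] <- vol2
  cells$np[i, ] <- sp$daughter1$n
  cells$C[i] <- sp$daughter1$C
  cells$auc[i] <- sp$daughter1$auc
  cells$id[i] <- cells$next_id
  # second daughter appended
  k <- n_cells(cells) + 1L
  cells$id[k] <- cells$next_id + 1L
  cells$x[k] <- x2; cells$y[k] <- y2
  cells$volume[k] <- vol2
  cells$state[k] <- .STATE_VIABLE
  cells$timer[k] <- 0
  cells$b_cur[k] <- cells$b_cur[i]
  cells$d_cur[k] <- cells$d_cur[i]
  cells$E[k] <- cells$E[i]
  cells$C[k] <- sp$daughter2$C
  cells$auc[k] <- sp$daughter2$auc
  cells$np <- rbind(cells$np, sp$daughter2$n)
  cells$next_id <- cells$next_id + 2L
  list(cells = cells, lost = sp$lost)
}

#' Progress death processes
#'
#' Apoptotic cells shrink linearly and are removed when their timer expires
#' (default 8.6 h); necrotic cells persist at frozen volume until lysis
#' (default 24 h) and are then removed. Viable cells are untouched.
#'
#' @param cells cell population.
#' @param dt step (min).
#' @return list with updated `cells` and logical `remove` flags.
#' @export
progress_death <- function(cells, dt) {
  dead <- cells$state != .STATE_VIABLE
  remove <- rep(FALSE, n_cells(cells))
  if (any(dead)) {
    apop <- cells$state == .STATE_APOPTOTIC
    if (any(apop)) {
      frac <- pmax(cells$timer[apop] - dt, 0) / pmax(cells$timer[apop], dt)
      cells$volume[apop] <- cells$volume[apop] * frac
    }
    cells$timer[dead] <- cells$timer[dead] - dt
    remove <- dead & cells$timer <= 0
  }
  list(cells = cells, remove = remove)
}
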