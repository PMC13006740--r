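#' Nanoparticle pharmacokinetic design parameters
#'
#' Bundles the NP design: saturable internalization (`rI`, `n_star`),
#' intracellular and extracellular decay, the m-state drug release cascade
#' (`m`, `C_star`, `gamma1`), and released-drug decay. `gamma1 = Inf` selects
#' immediate release: internalized NPs deliver their full load `C_star` to
#' the cytoplasmic drug pool on arrival and sit in the final (empty) release
#' state thereafter.
#'
#' `C_star` and `n_star` are not published quantities; the defaults (10 umol
#' per NP, 500 NPs per cell) are assumed values chosen so that a
#' substantially loaded cell reaches intracellular concentrations of order
#' 1 umol/um^3. Release-state loads use the piecewise-constant approximation
#' `C_j ~ f_j C_star` with `f_j = 1 - j/m`; set `midpoint_load = TRUE` for
#' the midpoint approximation `C_j ~ (f_j + f_{j+1})/2 C_star`.
#'
#' By default the final release state only leaves the system by decay, so a
#' NP parked there keeps releasing at rate `gamma1 / m` indefinitely (the
#' literal cascade). `exhausted_removal = TRUE` instead removes NPs from the
#' final state at the same transition rate as the other states, capping each
#' NP's lifetime release at `C_star`.
#'
#' @param rI base internalization rate (1/min).
#' @param n_star per-cell NP saturation count.
#' @param lambda_NP intracellular NP decay rate (1/min).
#' @param lambda_extra extracellular NP decay rate (1/min); applied on the
#'   NP field.
#' @param m number of release states (integer >= 1).
#' @param C_star drug load per NP (umol).
#' @param gamma1 characteristic release rate (umol/min); `Inf` = immediate.
#' @param lambda_drug released-drug decay rate (1/min).
#' @param exhausted_removal remove fully spent NPs from the final state?
#' @param midpoint_load use the midpoint release-state load approximation?
#' @return an object of class `np_design`.
#' @export
np_design <- function(rI = 0.0058, n_star = 500,
                      lambda_NP = half_life_to_rate(5, "days"),
                      lambda_extra = 0, m = 10, C_star = 10, gamma1 = 0.1,
                      lambda_drug = half_life_to_rate(8, "hours"),
                      exhausted_removal = FALSE, midpoint_load = FALSE) {
  if (m < 1 || m != round(m)) stop("m must be an integer >= 1", call. = FALSE)
  if (n_star <= 0 || C_star <= 0)
    stop("n_star and C_star must be positive", call. = FALSE)
  if (any(c(rI, lambda_NP, lambda_extra, gamma1, lambda_drug) < 0))
    stop("rates must be non-negative", call. = FALSE)
  structure(list(rI = rI, n_star = n_star, lambda_NP = lambda_NP,
                 lambda_extra = lambda_extra, m = as.integer(m),
                 C_star = C_star, gamma1 = gamma1, lambda_drug = lambda_drug,
                 exhausted_removal = isTRUE(exhausted_removal),
                 midpoint_load = isTRUE(midpoint_load)),
            class = "np_design")
}

is_immediate_release <- function(d) is.infinite(d$gamma1)

#' Per-cell NP compartment
#'
#' Holds the release-state populations `n_0 .. n_(m-1)` (continuous,
#' deterministic rate-equation populations), the released intracellular drug
#' `C` (umol), and the accumulated exposure `auc` (umol min / um^3).
#'
#' @param n numeric vector of state populations (length m); use
#'   `numeric(m)` for an empty compartment.
#' @param C released drug (umol).
#' @param auc accumulated exposure.
#' @return an object of class `np_compartment`.
#' @export
np_compartment <- function(n, C = 0, auc = 0) {
  if (any(n < 0) || C < 0 || auc < 0)
    stop("compartment contents must be non-negative", call. = FALSE)
  structure(list(n = as.numeric(n), C = C, auc = auc),
            class = "np_compartment")
}

#' Total internalized NP count of a compartment
#' @param comp an [np_compartment()].
#' @export
total_np <- function(comp) sum(comp$n)

#' Saturable uptake coefficient
#'
#' `U = rI * (1 - nI / n_star)`, clamped at 0 once the cell holds its
#' saturation count. This is the uptake rate that makes the tissue-level
#' sink term match the cell-level internalization ODE, conserving NPs
#' between the extracellular field and the intracellular compartments.
#'
#' @param nI internalized NP count(s); vectorized.
#' @param d an [np_design()].
#' @return uptake coefficient(s), 1/min.
#' @export
uptake_coefficient <- function(nI, d) {
  stopifnot(all(nI >= 0))
  d$rI * pmax(0, 1 - nI / d$n_star)
}

#' Release-state rate table
#'
#' For each state `j` (0-based), the remaining-load fraction
#' `f_j = 1 - j/m`, the per-NP drug release rate `r_j = gamma1 * f_j`
#' (umol/min), and the transition rate to the next state
#' `alpha_j = m * r_j / C_star` (a NP must shed `C_star/m` drug, at rate
#' `r_j`, to advance one state). The final state has no outgoing transition
#' unless exhausted-state removal is enabled.
#'
#' @param d an [np_design()].
#' @return list with numeric vectors `f`, `load_frac`, `r`, `alpha`
#'   (each length `m`; `alpha[m] = 0` in the literal cascade).
#' @export
release_rate_table <- function(d) {
  j <- 0:(d$m - 1)
  f <- 1 - j / d$m
  load <- if (d$midpoint_load) (f + (1 - (j + 1) / d$m)) / 2 else f
  if (is_immediate_release(d)) {
    r <- rep(0, d$m)          # all drug is delivered on arrival
    alpha <- rep(0, d$m)
  } else {
    r <- d$gamma1 * load
    alpha <- d$m * r / d$C_star
    if (!d$exhausted_removal) alpha[d$m] <- 0
  }
  list(f = f, load_frac = load, r = r, alpha = alpha)
}

# number of forward-Euler substeps keeping (rate * h) at or below `target`,
# which bounds the relative trajectory error at about (rate*t)*(rate*h)/2
.cascade_substeps <- function(d, dt, target = 0.005) {
  tab <- release_rate_table(d)
  maxr <- max(tab$alpha + d$lambda_NP, d$lambda_drug, 0)
  max(1L, as.integer(ceiling(dt * maxr / target)))
}

#' Advance one intracellular NP compartment
#'
#' One forward-Euler advance (internally sub-stepped for accuracy) of the
#' linear release cascade: state 0 gains the influx, each state loses
#' transitions out plus intracellular decay, released drug gains
#' `sum(r_j n_j)` and decays at `lambda_drug`, and the AUC accumulator gains
#' `(C / volume) * dt` by the rectangle rule.
#'
#' @param comp an [np_compartment()].
#' @param influx NP number arriving into state 0 over the step.
#' @param dt step length (min).
#' @param d an [np_design()].
#' @param volume cell volume (um^3) used for the concentration in the AUC.
#' @param substeps number of Euler substeps; default chooses enough that the
#'   fastest rate times the substep stays below 0.005. A single substep must
#'   satisfy the stability guard `dt * max(alpha_j + lambda_NP) < 1`.
#' @return the advanced compartment; ledger quantities (`decayed`, `spent`,
#'   `released`, `drug_decayed`) are attached as attributes.
#' @export
advance_intracellular <- function(comp, influx = 0, dt, d, volume = 2494,
                                  substeps = NULL) {
  stopifnot(inherits(comp, "np_compartment"), length(comp$n) == d$m)
  if (influx < 0) stop("negative influx", call. = FALSE)
  tab <- release_rate_table(d)
  nsub <- if (is.null(substeps)) .cascade_substeps(d, dt)
          else as.integer(substeps)
  h <- dt / nsub
  if (h * max(tab$alpha + d$lambda_NP, d$lambda_drug) >= 1)
    stop("explicit-Euler stability guard violated: use a smaller phenotype time step (or more substeps)",
         call. = FALSE)
  res <- .cascade_advance_cpp(matrix(comp$n, 1L), influx, comp$C,
                              tab$alpha, tab$r, d$lambda_NP, d$lambda_drug,
                              dt, nsub)
  out <- np_compartment(drop(res$n), C = res$C[1],
                        auc = comp$auc + res$C[1] / volume * dt)
  attr(out, "decayed") <- res$decayed
  attr(out, "spent") <- res$spent
  attr(out, "released") <- res$released
  attr(out, "drug_decayed") <- res$drug_decayed
  out
}

#' Split a NP compartment at cell division
#'
#' Each daughter receives the fraction `x` of every release-state population
#' (inheritance is independent of release state); the uninherited fraction
#' `1 - 2x` leaves the system and is reported as `lost`. Released drug and
#' accumulated AUC are split 50/50 between the daughters regardless of `x`,
#' conserving drug mass.
#'
#' @param comp parent [np_compartment()].
#' @param x inheritance fraction per daughter, in `[0, 0.5]`.
#' @return list with `daughter1`, `daughter2` (compartments) and `lost`
#'   (NP number removed).
#' @export
split_on_division <- function(comp, x) {
  stopifnot(inherits(comp, "np_compartment"))
  if (!is.numeric(x) || x < 0 || x > 0.5)
    stop("inheritance fraction must lie in [0, 0.5]", call. = FALSE)
  d1 <- np_compartment(comp$n * x, C = comp$C / 2, auc = comp$auc / 2)
  d2 <- np_compartment(comp$n * x, C = comp$C / 2, auc = comp$auc / 2)
  list(daughter1 = d1, daughter2 = d2, lost = (1 - 2 * x) * sum(comp$n))
}

#' Clear a compartment at cell death
#'
#' Internalized NPs are removed from the system when a cell dies; the
#' cleared count feeds the mass-balance ledger.
#'
#' @param comp an [np_compartment()].
#' @return list with the zeroed `comp` and the `cleared` NP count.
#' @export
clear_on_death <- function(comp) {
  cleared <- sum(comp$n)
  comp$n[] <- 0
  list(comp = comp, cleared = cleared)
}
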