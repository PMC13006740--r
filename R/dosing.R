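#' Nanoparticle injection schedule
#'
#' Injections are mapped to the time-varying Dirichlet boundary value of the
#' NP field: each injection contributes its dose, decayed exponentially at
#' the systemic clearance rate, and overlapping injections superpose. This
#' implicitly models systemic (e.g. renal) clearance of circulating NPs:
#' with the default 4-day half-life, more than 87% of a bolus has left the
#' circulation by day 12.
#'
#' @param times injection times (min), non-decreasing.
#' @param doses doses as multiples of `reference_dose`, `>= 0`.
#' @param clearance_rate systemic clearance rate (1/min); default a 4-day
#'   half-life.
#' @param reference_dose the boundary concentration (NPs/um^3) of a unit
#'   dose `C`.
#' @return an object of class `dose_schedule`.
#' @export
dose_schedule <- function(times = 0, doses = 1,
                          clearance_rate = half_life_to_rate(4, "days"),
                          reference_dose = 0.01) {
  stopifnot(length(times) == length(doses))
  if (is.unsorted(times)) stop("injection times must be non-decreasing",
                               call. = FALSE)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  if (clearance_rate < 0 || reference_dose < 0)
    stop("clearance_rate and reference_dose must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times), doses = as.numeric(doses),
                 clearance_rate = clearance_rate,
                 reference_dose = reference_dose),
            class = "dose_schedule")
}

#' Boundary NP concentration at a time
#'
#' Sum over all injections at or before `t` of
#' `dose_k * reference_dose * exp(-clearance_rate * (t - t_k))`.
#'
#' @param t time(s) in min, `>= 0`; vectorized.
#' @param s a [dose_schedule()].
#' @return boundary concentration(s), NPs/um^3.
#' @export
boundary_concentration <- function(t, s) {
  stopifnot(inherits(s, "dose_schedule"), all(t >= 0))
  vapply(t, function(tt) {
    k <- s$times <= tt
    sum(s$doses[k] * exp(-s$clearance_rate * (tt - s$times[k])))
  }, numeric(1)) * s$reference_dose
}

#' Total boundary exposure of a schedule
#'
#' The time integral of the boundary concentration over `[0, Inf)`, which is
#' `sum(doses) * reference_dose / clearance_rate` -- proportional to the
#' total injected dose, so schedules with equal summed dose (e.g. one full
#' dose versus two half doses) have equal total boundary exposure.
#'
#' @param s a [dose_schedule()].
#' @export
total_boundary_exposure <- function(s) {
  if (s$clearance_rate == 0) return(Inf)
  sum(s$doses) * s$reference_dose / s$clearance_rate
}
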