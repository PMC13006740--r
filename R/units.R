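#' Convert a half-life to a first-order decay rate
#'
#' All kinetic rates in the model are expressed in 1/min. Published NP decay
#' parameters are usually quoted as half-lives in days; this converter maps
#' between the two via \eqn{\lambda = \ln 2 / t_{1/2}}.
#'
#' @param half_life half-life, in the units given by `unit`.
#' @param unit one of `"min"`, `"hours"`, `"days"`.
#' @return decay rate in 1/min.
#' @examples
#' half_life_to_rate(5, "days")   # intracellular NP decay, 5-day half-life
#' @export
half_life_to_rate <- function(half_life, unit = c("min", "hours", "days")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(half_life), all(half_life > 0))
  log(2) / (half_life * switch(unit, min = 1, hours = 60, days = 1440))
}

#' @rdname half_life_to_rate
#' @param rate first-order rate in 1/min.
#' @export
rate_to_half_life <- function(rate, unit = c("min", "hours", "days")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(rate), all(rate > 0))
  log(2) / rate / switch(unit, min = 1, hours = 60, days = 1440)
}
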