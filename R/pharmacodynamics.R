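#' Pharmacodynamic response parameters
#'
#' Drug effect is computed from the intracellular released-drug
#' concentration `c = C / volume` with a Hill response, either on the
#' instantaneous concentration (`model = "hill"`) or on the accumulated
#' exposure (`model = "auc"`). The effect then linearly interpolates the
#' targeted phenotype rate between its base value `b0` and the maximally
#' altered value `bmax`. Cytostatic drugs target the cycle-entry rate
#' (`bmax <= b0`, default full arrest `bmax = 0`); cytotoxic drugs target
#' the apoptosis rate (`bmax >= b0`).
#'
#' @param model `"hill"` (instantaneous concentration) or `"auc"`.
#' @param Emax maximal effect (dimensionless), `> 0`.
#' @param EC50 concentration (umol/um^3) or AUC (umol min/um^3) at
#'   half-maximal effect, `> 0`.
#' @param hill_n Hill power, `>= 0`.
#' @param mode `"cytostatic"` or `"cytotoxic"`.
#' @param b0 base value of the targeted rate (1/min); may be `NULL` when the
#'   engine supplies oxygen-dependent base rates per cell.
#' @param bmax maximally altered value of the targeted rate (1/min).
#' @return an object of class `pd_params`.
#' @export
pd_params <- function(model = c("hill", "auc"), Emax = 1, EC50 = 0.03,
                      hill_n = 2, mode = c("cytostatic", "cytotoxic"),
                      b0 = NULL, bmax = NULL) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  if (Emax <= 0 || EC50 <= 0) stop("Emax and EC50 must be > 0", call. = FALSE)
  if (hill_n < 0) stop("hill_n must be >= 0", call. = FALSE)
  if (is.null(bmax)) bmax <- if (mode == "cytostatic") 0 else NULL
  if (!is.null(b0) && !is.null(bmax)) {
    if (mode == "cytostatic" && bmax > b0)
      stop("cytostatic mode requires bmax <= b0", call. = FALSE)
    if (mode == "cytotoxic" && bmax < b0)
      stop("cytotoxic mode requires bmax >= b0", call. = FALSE)
  }
  structure(list(model = model, Emax = Emax, EC50 = EC50, hill_n = hill_n,
                 mode = mode, b0 = b0, bmax = bmax),
            class = "pd_params")
}

#' Hill drug effect
#'
#' `E = Emax * c^n / (EC50^n + c^n)`: zero at `c = 0`, half-maximal at
#' `c = EC50`, saturating below `Emax`.
#'
#' @param conc intracellular drug concentration(s), `>= 0`; vectorized.
#' @param p a [pd_params()].
#' @return effect value(s) in `[0, Emax)`.
#' @export
hill_effect <- function(conc, p) {
  stopifnot(all(conc >= 0))
  cn <- conc^p$hill_n
  p$Emax * cn / (p$EC50^p$hill_n + cn)
}

#' AUC drug effect
#'
#' The Hill form applied to the accumulated exposure
#' `AUC(t) = integral of c dt` instead of the instantaneous concentration;
#' appropriate for drugs whose action tracks total exposure. Since the AUC
#' accumulator never decreases, the effect is non-decreasing over a cell's
#' lifetime.
#'
#' @param auc accumulated exposure(s), or an [np_compartment()] whose `auc`
#'   accumulator is used.
#' @param p a [pd_params()].
#' @return effect value(s) in `[0, Emax)`.
#' @export
auc_effect <- function(auc, p) {
  if (inherits(auc, "np_compartment")) auc <- auc$auc
  hill_effect(auc, p)
}

#' Interpolate a phenotype rate under drug effect
#'
#' `b = b0 + (bmax - b0) * E / Emax`: the targeted rate moves linearly from
#' its base value (no drug) to its maximally altered value (full effect).
#' Effects above `Emax` are clipped with a warning.
#'
#' @param E effect value(s) in `[0, Emax]`.
#' @param p a [pd_params()]; `b0`/`bmax` may be overridden by the arguments.
#' @param b0,bmax base and maximally altered rate (1/min); default from `p`.
#' @return the drug-modulated rate(s), 1/min.
#' @export
interpolate_phenotype <- function(E, p, b0 = p$b0, bmax = p$bmax) {
  if (is.null(b0) || is.null(bmax))
    stop("b0 and bmax must be supplied", call. = FALSE)
  if (any(E < 0)) stop("effect must be non-negative", call. = FALSE)
  if (any(E > p$Emax)) {
    warning("effect above Emax clipped")
    E <- pmin(E, p$Emax)
  }
  b0 + (bmax - b0) * E / p$Emax
}
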