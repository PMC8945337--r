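#' Pharmacokinetic release profile of an oral film
#'
#' Describes the caffeine effect-time course of an oral film as the sum of
#' two first-order absorption/elimination (Bateman) compartments: a fast
#' "free" fraction that dissolves with the film, and a slow "encapsulated"
#' fraction released from microparticles. A placebo film is the same object
#' with both doses equal to zero. Doses are in arbitrary effect units; the
#' downstream simulators interpret the summed profile as a dimensionless
#' autonomic drive.
#'
#' @param dose_free Dose of the free (fast-absorbing) fraction, effect units.
#' @param dose_encapsulated Dose of the microencapsulated (slow) fraction.
#' @param ka_free Absorption rate constant of the free fraction, 1/min.
#' @param ka_encapsulated Absorption rate constant of the encapsulated
#'   fraction, 1/min. Must be smaller than `ka_free`.
#' @param ke Elimination rate constant, 1/min (shared by both fractions).
#' @param lag Absorption lag time, min. The effect is zero before `lag`.
#'
#' @return An object of class `pk_profile`.
#' @examples
#' pk <- pk_profile()
#' plot(seq(0, 50, 0.5), effect_profile(seq(0, 50, 0.5), pk), type = "l")
#' @export
pk_profile <- function(dose_free = 0.6, dose_encapsulated = 0.8,
                       ka_free = 0.2, ka_encapsulated = 0.02,
                       ke = 0.01, lag = 1) {
  stopifnot(is.numeric(dose_free), is.numeric(dose_encapsulated),
            is.numeric(ka_free), is.numeric(ka_encapsulated),
            is.numeric(ke), is.numeric(lag))
  if (dose_free < 0 || dose_encapsulated < 0)
    stop("pk_profile: doses must be nonnegative", call. = FALSE)
  if (ka_free <= 0 || ka_encapsulated <= 0 || ke <= 0)
    stop("pk_profile: rate constants must be strictly positive", call. = FALSE)
  if (ka_free <= ka_encapsulated)
    stop("pk_profile: ka_free must exceed ka_encapsulated ",
         "(the free fraction absorbs faster)", call. = FALSE)
  if (lag < 0)
    stop("pk_profile: lag must be nonnegative", call. = FALSE)
  structure(list(dose_free = dose_free,
                 dose_encapsulated = dose_encapsulated,
                 ka_free = ka_free, ka_encapsulated = ka_encapsulated,
                 ke = ke, lag = lag),
            class = "pk_profile")
}

#' Placebo release profile
#'
#' Convenience constructor for a zero-dose [pk_profile()].
#' @param ... Passed to [pk_profile()] to override rate constants.
#' @return A `pk_profile` with both doses zero.
#' @export
pk_placebo <- function(...) {
  pk_profile(dose_free = 0, dose_encapsulated = 0, ...)
}

#' Bateman absorption-elimination concentration curve
#'
#' Concentration at time `t` after a unit bolus enters a first-order
#' absorption compartment with rate `ka` and is eliminated with rate `ke`:
#' `dose * ka/(ka - ke) * (exp(-ke t) - exp(-ka t))`. When `ka` and `ke`
#' coincide (relative difference below `tol`) the analytic limit
#' `dose * ka * t * exp(-ka t)` is used instead of the numerically unstable
#' quotient.
#'
#' @param t Time since administration, min. Vectorized; all values must be
#'   nonnegative.
#' @param dose Administered dose, arbitrary effect units (nonnegative).
#' @param ka Absorption rate constant, 1/min (> 0).
#' @param ke Elimination rate constant, 1/min (> 0).
#' @param tol Relative `|ka - ke|` threshold below which the equal-rate
#'   limit is evaluated.
#' @return Concentration in the same units as `dose`, nonnegative.
#' @examples
#' bateman_concentration(0:10, dose = 1, ka = 0.2, ke = 0.01)
#' # peak time is ln(ka/ke) / (ka - ke):
#' log(0.2 / 0.01) / (0.2 - 0.01)
#' @export
bateman_concentration <- function(t, dose, ka, ke, tol = 1e-10) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("bateman_concentration: t must be finite and nonnegative",
         call. = FALSE)
  if (!is.finite(dose) || dose < 0)
    stop("bateman_concentration: dose must be nonnegative", call. = FALSE)
  if (!is.finite(ka) || !is.finite(ke) || ka <= 0 || ke <= 0)
    stop("bateman_concentration: rate constants must be strictly positive",
         call. = FALSE)
  if (abs(ka - ke) < tol * max(ka, ke)) {
    conc <- dose * ka * t * exp(-ka * t)
  } else {
    conc <- dose * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
  pmax(conc, 0)
}

#' Time of peak concentration of a Bateman curve
#'
#' Closed form `ln(ka/ke) / (ka - ke)`; for `ka == ke` the limit `1/ka`.
#' @inheritParams bateman_concentration
#' @return Peak time in minutes.
#' @export
bateman_tmax <- function(ka, ke, tol = 1e-10) {
  if (ka <= 0 || ke <= 0)
    stop("bateman_tmax: rate constants must be strictly positive",
         call. = FALSE)
  if (abs(ka - ke) < tol * max(ka, ke)) return(1 / ka)
  log(ka / ke) / (ka - ke)
}

#' Dual-compartment effect profile
#'
#' Evaluates the summed free + encapsulated Bateman curves of a
#' [pk_profile()] on a time grid, shifted by the absorption lag. The effect
#' is zero before `lag` and nonnegative everywhere; a placebo profile
#' (both doses zero) yields an all-zero effect.
#'
#' @param t_grid Nonnegative, nondecreasing time grid in minutes.
#' @param pk A [pk_profile()].
#' @return Numeric vector of dimensionless effect values, one per grid point.
#' @export
effect_profile <- function(t_grid, pk) {
  stopifnot(inherits(pk, "pk_profile"))
  if (any(!is.finite(t_grid)) || any(t_grid < 0))
    stop("effect_profile: t_grid must be finite and nonnegative",
         call. = FALSE)
  if (is.unsorted(t_grid))
    stop("effect_profile: t_grid must be sorted nondecreasing", call. = FALSE)
  ts <- pmax(t_grid - pk$lag, 0)
  eff <- bateman_concentration(ts, pk$dose_free, pk$ka_free, pk$ke) +
    bateman_concentration(ts, pk$dose_encapsulated, pk$ka_encapsulated, pk$ke)
  eff[t_grid < pk$lag] <- 0
  eff
}
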