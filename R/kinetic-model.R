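#' Gas constant times temperature at 25 degrees C
#'
#' `R = 1.987e-3` kcal mol^-1 K^-1 at `T = 298.15` K, the temperature at which
#' stopped-flow (un)folding experiments are typically run. All free energies in
#' the package are in kcal mol^-1, denaturant concentrations in M, rate
#' constants in s^-1.
#'
#' @export
RT_25C <- 1.987e-3 * 298.15

#' Microscopic kinetic parameters of the three-state folding model
#'
#' Container for the parameters of the rate law
#' \deqn{k_{obs} = \frac{k_f^0 e^{-m_f[U]/RT} + k_u^0 e^{+m_u[U]/RT}}
#'                     {1 + K_{part} e^{+m_{part}[U]/RT}}}
#' describing folding through two sequential transition states (TS1, TS2)
#' separated by an on-pathway high-energy intermediate. `Kpart` is the
#' partitioning constant between the early and late transition state and
#' `mpart` its denaturant dependence; `Kpart = 0` collapses the model to the
#' classical two-state chevron.
#'
#' @param kf0 Folding rate constant in water (s^-1, > 0).
#' @param mf Folding kinetic m-value (kcal mol^-1 M^-1, >= 0).
#' @param ku0 Unfolding rate constant in water (s^-1, > 0).
#' @param mu Unfolding kinetic m-value (kcal mol^-1 M^-1, >= 0).
#' @param Kpart Partitioning constant between TS1 and TS2 (dimensionless, >= 0).
#' @param mpart Partitioning m-value (kcal mol^-1 M^-1, >= 0).
#' @param RT Gas constant times temperature (kcal mol^-1), default [RT_25C].
#' @return An object of class `kinetic_params`.
#' @examples
#' wt <- kinetic_params(kf0 = 300, mf = 0.81, ku0 = 0.06, mu = 0.52,
#'                      Kpart = 0.017, mpart = 0.45)
#' three_state_rate(wt, urea = seq(0, 9, 0.5))
#' @export
kinetic_params <- function(kf0, mf, ku0, mu, Kpart = 0, mpart = 0, RT = RT_25C) {
  vals <- c(kf0 = kf0, mf = mf, ku0 = ku0, mu = mu,
            Kpart = Kpart, mpart = mpart, RT = RT)
  if (any(!is.finite(vals)))
    stop("invalid kinetic parameters: all values must be finite numbers",
         call. = FALSE)
  if (kf0 <= 0 || ku0 <= 0)
    stop("invalid kinetic parameters: rate constants must be strictly positive",
         call. = FALSE)
  if (mf < 0 || mu < 0 || mpart < 0)
    stop("invalid kinetic parameters: m-values must be non-negative",
         call. = FALSE)
  if (Kpart < 0)
    stop("invalid kinetic parameters: Kpart must be non-negative", call. = FALSE)
  if (RT <= 0)
    stop("invalid kinetic parameters: RT must be positive", call. = FALSE)
  structure(as.list(vals), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Three-state folding parameters (rates s^-1, m-values kcal mol^-1 M^-1):\n")
  cat(sprintf("  kf0 = %.4g  mf = %.4g\n  ku0 = %.4g  mu = %.4g\n", x$kf0, x$mf,
              x$ku0, x$mu))
  cat(sprintf("  Kpart = %.4g  mpart = %.4g  (RT = %.4f kcal/mol)\n", x$Kpart,
              x$mpart, x$RT))
  invisible(x)
}

check_urea <- function(urea) {
  if (!is.numeric(urea) || any(!is.finite(urea)) || any(urea < 0))
    stop("urea concentrations must be finite and non-negative", call. = FALSE)
  urea
}

#' Observed rate constant of a two-state folder
#'
#' The classical V-shaped chevron:
#' `kobs = kf0 * exp(-mf * urea / RT) + ku0 * exp(mu * urea / RT)`.
#'
#' @param params A [kinetic_params] object (`Kpart`/`mpart` are ignored).
#' @param urea Denaturant concentration(s), M (>= 0). Vectorised.
#' @return Observed rate constant(s), s^-1.
#' @export
two_state_rate <- function(params, urea) {
  stopifnot(inherits(params, "kinetic_params"))
  u <- check_urea(urea)
  params$kf0 * exp(-params$mf * u / params$RT) +
    params$ku0 * exp(params$mu * u / params$RT)
}

#' Observed rate constant with an on-pathway high-energy intermediate
#'
#' Three-state rate law in which the flux partitions between an early (TS1)
#' and a late (TS2) transition state:
#' `kobs = (kf0*exp(-mf*u/RT) + ku0*exp(mu*u/RT)) / (1 + Kpart*exp(mpart*u/RT))`.
#' The denominator produces the characteristic kink (downward curvature) in
#' the unfolding arm of the chevron as the rate-limiting step switches from
#' TS2 to TS1 at high denaturant. With `Kpart = 0` this is exactly
#' [two_state_rate()].
#'
#' @inheritParams two_state_rate
#' @return Observed rate constant(s), s^-1.
#' @export
three_state_rate <- function(params, urea) {
  stopifnot(inherits(params, "kinetic_params"))
  u <- check_urea(urea)
  num <- params$kf0 * exp(-params$mf * u / params$RT) +
    params$ku0 * exp(params$mu * u / params$RT)
  num / (1 + params$Kpart * exp(params$mpart * u / params$RT))
}

#' Kinetically derived stability and equilibrium m-value
#'
#' Folding free energy from the microscopic rates,
#' `dG_DN = RT * ln(kf0 / ku0)`, and the kinetic equilibrium m-value
#' `m_DN = mf + mu`. `dG_DN` depends only on the ratio `kf0/ku0`; it is
#' positive when the native state is more stable than the denatured state.
#'
#' @param params A [kinetic_params] object.
#' @return A list with elements `dG_DN` (kcal mol^-1) and `m_DN`
#'   (kcal mol^-1 M^-1).
#' @export
stability <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  list(dG_DN = params$RT * log(params$kf0 / params$ku0),
       m_DN = params$mf + params$mu)
}

#' Tanford beta values of the early and late transition states
#'
#' Fractional position of each transition state along the denaturant-sensitive
#' reaction coordinate (0 = denatured-like, 1 = native-like compactness):
#' \deqn{\beta_{TS1} = m_{D-TS1}/m_{D-N} = m_f/(m_f + m_u)}
#' \deqn{\beta_{TS2} = 1 - (m_{TS1-N} - m_{part})/m_{D-N}
#'                   = 1 - (m_u - m_{part})/(m_f + m_u)}
#' Values are reported as computed, without clamping to \[0, 1\]; an
#' `out_of_range` flag marks nominally unphysical values so that downstream
#' Hammond-type trend analyses still see the raw numbers.
#'
#' @param params A [kinetic_params] object with `mf + mu > 0`.
#' @return Object of class `tanford_betas`: list with `beta_ts1`, `beta_ts2`,
#'   `out_of_range`.
#' @export
beta_tanford <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  m_DN <- params$mf + params$mu
  if (m_DN <= 0)
    stop("degenerate geometry: m_DN = mf + mu must be positive to place ",
         "transition states on the reaction coordinate", call. = FALSE)
  b1 <- params$mf / m_DN
  b2 <- 1 - (params$mu - params$mpart) / m_DN
  out <- b1 < 0 || b1 > 1 || b2 < 0 || b2 > 1
  if (out)
    warning("Tanford beta outside [0, 1]; reported unclamped", call. = FALSE)
  structure(list(beta_ts1 = b1, beta_ts2 = b2, out_of_range = out),
            class = "tanford_betas")
}

#' @export
print.tanford_betas <- function(x, ...) {
  cat(sprintf("beta_TS1 = %.4f, beta_TS2 = %.4f%s\n", x$beta_ts1, x$beta_ts2,
              if (x$out_of_range) "  [outside [0,1]]" else ""))
  invisible(x)
}
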