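#' Convert an orbital-shaker speed to frequency
#'
#' @param rpm Revolutions per minute, `>= 0`. Vectorized.
#' @return Frequency in Hz (`rpm / 60`).
#' @export
rpm_to_hz <- function(rpm) {
  stopifnot(is.numeric(rpm), all(rpm >= 0))
  rpm / 60
}

#' Average shear rate at the bottom of an orbitally shaken dish
#'
#' Orbital shaking drives a wave that circles the dish and exposes coupons
#' on its bottom to a time-averaged shear rate
#' \deqn{\gamma_\omega = r_{eff} \sqrt{\rho (2\pi f)^3 / \mu},}
#' where \eqn{f} is the orbital frequency, \eqn{\rho} and \eqn{\mu} the
#' fluid density and dynamic viscosity, and \eqn{r_{eff}} an effective
#' orbital length. The shear rate scales as \eqn{f^{3/2}} and as
#' \eqn{\sqrt{\rho/\mu}}.
#'
#' The default `r_eff = 0.0275` m is a lumped coefficient calibrated for
#' 45 mL polypropylene Petri dishes (85 mm internal diameter, 9 mm liquid
#' height) on a shaker with a 3 cm orbit; with water properties it gives
#' 329, 931 and 1712 s^-1 at 50, 100 and 150 rpm. Whether it represents
#' the orbit radius, the dish radius or a mixture cannot be separated in
#' this lumped model, so it is exposed as a plain parameter.
#'
#' @param f Orbital frequency, Hz (use [rpm_to_hz()] for shaker settings).
#'   Vectorized.
#' @param rho Fluid density, kg m^-3 (default water, 1000).
#' @param mu Dynamic viscosity, kg m^-1 s^-1 (default water, 1e-3).
#' @param r_eff Effective orbital length, m.
#' @return Shear rate(s), s^-1.
#' @examples
#' orbital_shear_rate(rpm_to_hz(c(50, 100, 150)))
#' @export
orbital_shear_rate <- function(f, rho = 1000, mu = 1e-3, r_eff = 0.0275) {
  stopifnot(is.numeric(f), all(f >= 0))
  if (any(c(rho, mu, r_eff) <= 0) || any(!is.finite(c(rho, mu, r_eff)))) {
    stop("rho, mu and r_eff must be strictly positive and finite")
  }
  r_eff * sqrt(rho * (2 * pi * f)^3 / mu)
}
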