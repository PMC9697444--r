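#' Water adhesion tension
#'
#' \eqn{\tau_0 = \gamma_w \cos\theta_w}, the driving force for water
#' spreading. It ranges over \eqn{[-\gamma_w, +\gamma_w]} and decreases
#' strictly with the water contact angle; Vogler's criterion calls a
#' surface hydrophilic when \eqn{\tau_0 > 30} mJ m^-2.
#'
#' @param theta_w Water contact angle, degrees in `[0, 180)`. Vectorized.
#' @param water The water [probe_liquid()].
#' @return Numeric vector, mJ m^-2.
#' @examples
#' water_adhesion_tension(c(25, 90, 97)) # ~66.0, 0, ~-8.9
#' @export
water_adhesion_tension <- function(theta_w, water = default_liquids()$water) {
  check_angle(theta_w, "theta_w")
  water$gamma_total * cos_deg(theta_w)
}

#' Zisman critical surface tension
#'
#' Ordinary least-squares fit of \eqn{\cos\theta_i} against the probe
#' liquids' total surface tensions \eqn{\gamma_{L,i}}; the critical
#' surface tension \eqn{\gamma_c} is the liquid tension at which the
#' fitted line reaches \eqn{\cos\theta = 1} (a liquid of that tension
#' would just spread). The fit's \eqn{r^2} is returned so callers can
#' reject degenerate extrapolations: with three chemically disparate probe
#' liquids the Zisman plot is often far from linear (acid-base
#' interactions are liquid-specific), and low-\eqn{r^2} values mean
#' \eqn{\gamma_c} should not be read quantitatively.
#'
#' @param theta Named numeric vector of contact angles (degrees); names
#'   must match entries of `liquids`. At least two liquids with distinct
#'   total surface tension are required.
#' @param liquids Probe-liquid set.
#' @return Named numeric vector `c(gamma_c = , r2 = )`, `gamma_c` in
#'   mJ m^-2.
#' @examples
#' # angles generated from an exact Zisman line are recovered exactly
#' gl <- sapply(default_liquids(), `[[`, "gamma_total")
#' theta <- acos(pmin(1, 1 - 0.02 * (gl - 30))) * 180 / pi
#' critical_surface_tension(theta) # gamma_c = 30, r2 = 1
#' @export
critical_surface_tension <- function(theta, liquids = default_liquids()) {
  stopifnot(is.numeric(theta), !is.null(names(theta)))
  unknown <- setdiff(names(theta), names(liquids))
  if (length(unknown)) {
    stop("no liquid parameters for: ", paste(unknown, collapse = ", "))
  }
  if (length(theta) < 2) stop("Zisman fit needs at least 2 liquids")
  check_angle(theta, "contact angles")
  gl <- vapply(liquids[names(theta)], `[[`, numeric(1), "gamma_total")
  if (length(unique(gl)) < 2) {
    stop("Zisman fit needs at least 2 liquids with distinct surface tension")
  }
  ct <- cos_deg(theta)
  fit <- stats::lm(ct ~ gl)
  slope <- stats::coef(fit)[["gl"]]
  if (!is.finite(slope) || abs(slope) < 1e-12) {
    stop("indeterminate critical tension: Zisman slope is zero ",
         "(all cos(theta) equal across liquids)")
  }
  gamma_c <- (1 - stats::coef(fit)[["(Intercept)"]]) / slope
  # computed directly: summary.lm() warns on exact synthetic-line input
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  c(gamma_c = gamma_c, r2 = r2)
}

#' Vogler hydrophilicity classification
#'
#' Labels a surface `"hydrophilic"` when its water adhesion tension
#' strictly exceeds the threshold (30 mJ m^-2 by default), else
#' `"hydrophobic"`. Hydrophilic surfaces in this sense support a
#' long-range attraction of water and, empirically, heavier protein
#' fouling.
#'
#' @param tau0 Water adhesion tension, mJ m^-2. Vectorized; `NA` in, `NA`
#'   out.
#' @param threshold Classification threshold, mJ m^-2 (strict `>`).
#' @return Character vector in `c("hydrophilic", "hydrophobic")`.
#' @examples
#' classify_vogler(c(66.1, 30, 24.3))
#' @export
classify_vogler <- function(tau0, threshold = 30) {
  ifelse(is.na(tau0), NA_character_,
         ifelse(tau0 > threshold, "hydrophilic", "hydrophobic"))
}

#' Baier minimal-fouling window test
#'
#' The Baier curve relates relative biological adhesion to a material's
#' critical surface tension, with an empirical minimum at low (but not
#' minimal) \eqn{\gamma_c}. This predicate reports whether \eqn{\gamma_c}
#' lies inside the configured closed interval, `[20, 30]` mN m^-1 by
#' default (the window usually quoted for the Baier minimum).
#'
#' @param gamma_c Critical surface tension, mJ m^-2. Vectorized; `NA` in,
#'   `NA` out.
#' @param window Closed interval `c(lo, hi)`.
#' @return Logical vector.
#' @examples
#' baier_zone(c(25, 56.7, 20))
#' @export
baier_zone <- function(gamma_c, window = c(20, 30)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  gamma_c >= window[1] & gamma_c <= window[2]
}
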