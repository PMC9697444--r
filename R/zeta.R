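#' Surface zeta potential from displacement-resolved tracer measurements
#'
#' In a dip-cell surface-zeta measurement the apparent zeta potential of a
#' tracer suspension is recorded at increasing displacements from the
#' wall: electro-osmotic flow dominates near the surface and the tracer's
#' own electrophoresis far from it. The apparent values over the near-wall
#' displacements are regressed linearly on displacement and extrapolated
#' to the wall; the surface zeta potential is
#' \deqn{\zeta_s = -\mathrm{intercept} + \zeta_m,}
#' where \eqn{\zeta_m} is the tracer zeta potential measured in the far
#' field (typically 1000 um), outside the electro-osmotic layer. The
#' far-field value enters only through \eqn{\zeta_m} and is never part of
#' the regression.
#'
#' Signs are the instrument's (mV as reported); no magnitude flipping is
#' applied. Shifting every apparent value and \eqn{\zeta_m} by the same
#' constant leaves \eqn{\zeta_s} unchanged.
#'
#' @param displacement_um Displacements from the wall, um; strictly
#'   positive, strictly increasing, length >= 2.
#' @param zeta_mv Apparent zeta potentials at those displacements, mV.
#' @param zeta_far Tracer (far-field) zeta potential \eqn{\zeta_m}, mV.
#' @return An object of class `"zeta_fit"`: list with `zeta_s`,
#'   `intercept`, `slope` (mV/um), `zeta_far`, `fit` (the underlying
#'   [stats::lm()]), `displacement_um`, `zeta_mv`.
#' @examples
#' d <- c(125, 250, 375, 500, 625)
#' surface_zeta(d, -60 + 0.02 * d, zeta_far = -40) # zeta_s = +20 mV
#' @export
surface_zeta <- function(displacement_um, zeta_mv, zeta_far) {
  stopifnot(is.numeric(displacement_um), is.numeric(zeta_mv),
            is.numeric(zeta_far), length(zeta_far) == 1, is.finite(zeta_far))
  if (length(displacement_um) < 2) {
    stop("surface zeta extrapolation needs at least 2 near-wall displacements")
  }
  if (length(displacement_um) != length(zeta_mv)) {
    stop("displacement_um and zeta_mv must have the same length")
  }
  if (any(displacement_um <= 0) || any(diff(displacement_um) <= 0)) {
    stop("displacements must be strictly positive and strictly increasing")
  }
  fit <- stats::lm(zeta_mv ~ displacement_um)
  intercept <- stats::coef(fit)[["(Intercept)"]]
  slope <- stats::coef(fit)[["displacement_um"]]
  structure(list(zeta_s = -intercept + zeta_far,
                 intercept = intercept, slope = slope, zeta_far = zeta_far,
                 fit = fit, displacement_um = displacement_um,
                 zeta_mv = zeta_mv),
            class = "zeta_fit")
}

#' @export
print.zeta_fit <- function(x, ...) {
  cat(sprintf(
    "Surface zeta extrapolation (%d near-wall points)\n  intercept = %.2f mV, slope = %.4f mV/um, zeta_m = %.2f mV\n  zeta_s = %.2f mV\n",
    length(x$displacement_um), x$intercept, x$slope, x$zeta_far, x$zeta_s))
  invisible(x)
}

#' Surface zeta potentials for a table of displacement profiles
#'
#' Applies [surface_zeta()] per profile (unique combination of
#' `surface_id`, `tracer`, `nacl_mm`) of a long-format measurement table,
#' splitting each profile into its near-wall points and far-field tracer
#' row.
#'
#' @param data data.frame as returned by [read_zeta_table()] or
#'   [synth_zeta_profiles()]: columns `surface_id`, `tracer`, `nacl_mm`,
#'   `displacement_um`, `zeta_mv` and logical `is_far_field` (if absent,
#'   rows with `displacement_um >= 1000` are taken as far field).
#' @return data.frame with one row per profile: the grouping columns plus
#'   `zeta_s`, `intercept`, `slope`, `zeta_far`, `n_points` (near-wall
#'   count).
#' @export
zeta_report <- function(data) {
  need <- c("surface_id", "tracer", "nacl_mm", "displacement_um", "zeta_mv")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("zeta table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(data$is_far_field)) data$is_far_field <- data$displacement_um >= 1000
  key <- interaction(data$surface_id, data$tracer, data$nacl_mm, drop = TRUE)
  out <- lapply(split(data, key), function(g) {
    far <- g[g$is_far_field, , drop = FALSE]
    near <- g[!g$is_far_field, , drop = FALSE]
    if (nrow(far) == 0) {
      stop("profile '", g$surface_id[1], "'/", g$tracer[1],
           ": no far-field (tracer) row")
    }
    near <- near[order(near$displacement_um), , drop = FALSE]
    z <- surface_zeta(near$displacement_um, near$zeta_mv,
                      zeta_far = mean(far$zeta_mv))
    data.frame(surface_id = g$surface_id[1], tracer = g$tracer[1],
               nacl_mm = g$nacl_mm[1], zeta_s = z$zeta_s,
               intercept = z$intercept, slope = z$slope,
               zeta_far = z$zeta_far, n_points = nrow(near))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
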