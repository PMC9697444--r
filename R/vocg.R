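## Three-liquid acid-base (van Oss-Chaudhury-Good) surface-energy inversion.
##
## For probe liquid L on solid s the Young-Dupre equation reads
##   gamma_L (1 + cos theta_L) =
##     2 ( sqrt(gamma_s^LW gamma_L^LW) + sqrt(gamma_s^+ gamma_L^-)
##         + sqrt(gamma_s^- gamma_L^+) ).
## The apolar liquid (gamma_L^+ = gamma_L^- = 0) decouples and yields
## gamma_s^LW in closed form; the two polar liquids then give a 2x2 linear
## system in a = sqrt(gamma_s^+), b = sqrt(gamma_s^-).

cos_deg <- function(theta) cospi(theta / 180)
acos_deg <- function(x) acos(x) * 180 / pi

#' Lifshitz--van der Waals component from the apolar contact angle
#'
#' Closed-form solution of the apolar Young--Dupre equation:
#' \deqn{\gamma_s^{LW} = \gamma_D (1 + \cos\theta_D)^2 / 4,}
#' where \eqn{\gamma_D} is the apolar liquid's surface tension. Complete
#' wetting (\eqn{\theta_D = 0}) returns the liquid's own tension; at
#' \eqn{\theta_D = 180^\circ} the component vanishes.
#'
#' @param theta_d Contact angle of the apolar liquid, degrees in `[0, 180)`.
#'   Vectorized.
#' @param apolar A [probe_liquid()] with `gamma_plus = gamma_minus = 0`.
#' @return Numeric vector, \eqn{\gamma_s^{LW}} in mJ m^-2.
#' @examples
#' gamma_lw_apolar(38) # 40.6 mJ m^-2
#' @export
gamma_lw_apolar <- function(theta_d, apolar = default_liquids()$diiodomethane) {
  if (!is_apolar(apolar)) {
    stop("gamma_lw_apolar() requires an apolar liquid (gamma_plus = gamma_minus = 0); '",
         apolar$name, "' is polar")
  }
  check_angle(theta_d, "theta_d")
  apolar$gamma_total * (1 + cos_deg(theta_d))^2 / 4
}

check_angle <- function(theta, what) {
  bad <- !is.finite(theta) | theta < 0 | theta >= 180
  if (any(bad)) {
    stop(what, " must lie in [0, 180) degrees; offending value(s): ",
         paste(utils::head(theta[bad], 3), collapse = ", "))
  }
  invisible(theta)
}

#' Solve the three-liquid Young--Dupre system for surface-energy components
#'
#' Recovers a solid's vOCG components from its water, formamide and
#' diiodomethane contact angles. \eqn{\gamma_s^{LW}} comes from the apolar
#' equation ([gamma_lw_apolar()]); the water and formamide equations then
#' form a linear system in \eqn{a = \sqrt{\gamma_s^+}},
#' \eqn{b = \sqrt{\gamma_s^-}}.
#'
#' The linear solve can return a negative \eqn{a} or \eqn{b}, which is
#' common for strongly monopolar (electron-donor) polymer surfaces. The
#' magnitudes are carried forward: \eqn{\gamma_s^+ = a^2},
#' \eqn{\gamma_s^- = b^2}, \eqn{\gamma_s^{AB} = 2|a||b|}, and
#' \eqn{\gamma_s = \gamma_s^{LW} + \gamma_s^{AB}}. The columns
#' `root_neg_plus` / `root_neg_minus` record which square roots solved
#' negative so the convention can be audited; the total surface energies
#' reported for such surfaces in the wider materials literature follow the
#' same magnitude convention.
#'
#' @param theta_w,theta_f,theta_d Contact angles in degrees for water,
#'   formamide and diiodomethane. Vectorized (recycled to common length).
#' @param liquids Probe-liquid set containing `water`, `formamide` and
#'   `diiodomethane`; see [default_liquids()].
#' @return A data.frame with one row per angle triple and columns
#'   `gamma_lw`, `gamma_plus`, `gamma_minus`, `gamma_ab`, `gamma_s`
#'   (mJ m^-2), and logical `root_neg_plus`, `root_neg_minus`.
#' @examples
#' # hydrophilic borosilicate glass vs a monopolar polycarbonate
#' solve_components(c(25, 78), c(26, 70), c(38, 26))
#' @seealso [vocg()] for the full fit object, [forward_angles()] for the
#'   inverse map.
#' @export
solve_components <- function(theta_w, theta_f, theta_d,
                             liquids = default_liquids()) {
  liq <- resolve_liquid_roles(liquids)
  n <- max(length(theta_w), length(theta_f), length(theta_d))
  theta_w <- rep_len(theta_w, n); check_angle(theta_w, "theta_w")
  theta_f <- rep_len(theta_f, n); check_angle(theta_f, "theta_f")
  theta_d <- rep_len(theta_d, n); check_angle(theta_d, "theta_d")

  w <- liq$water; f <- liq$formamide
  gamma_lw <- gamma_lw_apolar(theta_d, liq$diiodomethane)

  # rows: water, formamide; unknowns: a = sqrt(g+), b = sqrt(g-)
  A <- rbind(c(sqrt(w$gamma_minus), sqrt(w$gamma_plus)),
             c(sqrt(f$gamma_minus), sqrt(f$gamma_plus)))
  if (abs(det(A)) < 1e-10) {
    stop("polar liquid pair is degenerate: water (",
         w$gamma_plus, ", ", w$gamma_minus, ") and formamide (",
         f$gamma_plus, ", ", f$gamma_minus,
         ") give a singular acid-base system")
  }
  a <- b <- numeric(n)
  for (i in seq_len(n)) {
    rhs <- c(w$gamma_total * (1 + cos_deg(theta_w[i])) / 2 -
               sqrt(gamma_lw[i] * w$gamma_lw),
             f$gamma_total * (1 + cos_deg(theta_f[i])) / 2 -
               sqrt(gamma_lw[i] * f$gamma_lw))
    ab <- solve(A, rhs)
    a[i] <- ab[1]; b[i] <- ab[2]
  }
  gamma_plus <- a^2
  gamma_minus <- b^2
  gamma_ab <- 2 * abs(a) * abs(b)
  data.frame(gamma_lw = gamma_lw,
             gamma_plus = gamma_plus,
             gamma_minus = gamma_minus,
             gamma_ab = gamma_ab,
             gamma_s = gamma_lw + gamma_ab,
             root_neg_plus = a < 0,
             root_neg_minus = b < 0)
}

#' Free energy of cohesion in water
#'
#' The free energy of cohesion \eqn{\Delta G_{coh}} (also written
#' \eqn{\Delta G_{sws}}) of a solid immersed in water is
#' \eqn{-2\gamma_{sw}}, with the solid--water interfacial tension
#' \deqn{\gamma_{sw} = (\sqrt{\gamma_s^{LW}} - \sqrt{\gamma_w^{LW}})^2 +
#'   2(\sqrt{\gamma_s^+\gamma_s^-} + \sqrt{\gamma_w^+\gamma_w^-} -
#'     \sqrt{\gamma_s^+\gamma_w^-} - \sqrt{\gamma_s^-\gamma_w^+}).}
#' Positive values mark hydrophilic surfaces (water molecules prefer the
#' surface to each other), negative values hydrophobic ones. A solid with
#' water's own components gives exactly 0.
#'
#' @param gamma_lw,gamma_plus,gamma_minus Solid surface-energy components,
#'   mJ m^-2, all `>= 0` (magnitude convention; see [solve_components()]).
#'   Vectorized.
#' @param water The water [probe_liquid()].
#' @return Numeric vector, \eqn{\Delta G_{coh}} in mJ m^-2.
#' @examples
#' delta_g_coh(21.8, 25.5, 25.5) # water-like solid: 0
#' @export
delta_g_coh <- function(gamma_lw, gamma_plus, gamma_minus,
                        water = default_liquids()$water) {
  stopifnot(all(gamma_lw >= 0), all(gamma_plus >= 0), all(gamma_minus >= 0))
  w <- water
  gamma_sw <- (sqrt(gamma_lw) - sqrt(w$gamma_lw))^2 +
    2 * (sqrt(gamma_plus * gamma_minus) +
           sqrt(w$gamma_plus * w$gamma_minus) -
           sqrt(gamma_plus * w$gamma_minus) -
           sqrt(gamma_minus * w$gamma_plus))
  -2 * gamma_sw
}

#' Forward Young--Dupre map: contact angles from known components
#'
#' Evaluates the contact angle each probe liquid would show on a solid
#' with the given vOCG components. This is the exact inverse of
#' [solve_components()] whenever both square roots are non-negative, and
#' the forward model behind the synthetic contact-angle generator.
#'
#' @inheritParams delta_g_coh
#' @param liquids Probe-liquid set (any named list of [probe_liquid()]s).
#' @return If the component arguments are scalars, a named numeric vector
#'   of angles (degrees), one per liquid; otherwise a data.frame with one
#'   column per liquid.
#' @examples
#' forward_angles(50.8, 0, 0)["diiodomethane"] # self-wetting: 0
#' @export
forward_angles <- function(gamma_lw, gamma_plus, gamma_minus,
                           liquids = default_liquids()) {
  out <- forward_cos(gamma_lw, gamma_plus, gamma_minus, liquids)
  for (nm in names(out)) {
    ct <- out[[nm]]
    if (anyNA(ct)) {
      bad <- which(is.na(ct))[1]
      stop("unphysical component set for liquid '", nm,
           "': cos(theta) outside [-1, 1] (component row ", bad, ")")
    }
    out[[nm]] <- acos_deg(ct)
  }
  if (nrow(out) == 1L) {
    stats::setNames(as.numeric(out[1L, ]), names(out))
  } else {
    out
  }
}

# Young-Dupre cosines per liquid; values outside [-1,1] (beyond a 1e-9
# floating-point allowance) become NA. data.frame, one column per liquid.
forward_cos <- function(gamma_lw, gamma_plus, gamma_minus, liquids) {
  stopifnot(all(gamma_lw >= 0), all(gamma_plus >= 0), all(gamma_minus >= 0))
  n <- max(length(gamma_lw), length(gamma_plus), length(gamma_minus))
  gamma_lw <- rep_len(gamma_lw, n)
  gamma_plus <- rep_len(gamma_plus, n)
  gamma_minus <- rep_len(gamma_minus, n)
  as.data.frame(lapply(liquids, function(L) {
    ct <- 2 * (sqrt(gamma_lw * L$gamma_lw) +
                 sqrt(gamma_plus * L$gamma_minus) +
                 sqrt(gamma_minus * L$gamma_plus)) / L$gamma_total - 1
    ct[ct > 1 & ct <= 1 + 1e-9] <- 1
    ct[ct < -1 & ct >= -1 - 1e-9] <- -1
    ct[ct > 1 | ct < -1] <- NA_real_
    ct
  }))
}

#' Fit the three-liquid surface-energy model to a table of contact angles
#'
#' The main entry point of the package. Takes one row of mean contact
#' angles per surface, inverts the acid--base Young--Dupre system
#' ([solve_components()]) and derives the full wetting profile: cohesion
#' free energy in water ([delta_g_coh()]), water adhesion tension
#' \eqn{\tau_0 = \gamma_w \cos\theta_w}, Zisman critical surface tension
#' \eqn{\gamma_c} with its fit \eqn{r^2} ([critical_surface_tension()]),
#' the Vogler hydrophilicity label (\eqn{\tau_0 > 30} mJ m^-2 by default)
#' and whether \eqn{\gamma_c} falls in the Baier minimal-fouling window.
#'
#' @param data A data.frame with numeric columns `theta_w`, `theta_f`,
#'   `theta_d` (degrees) and optionally `surface_id` (unique labels) and
#'   `ra_um` (roughness); typically from [read_angle_table()] or
#'   [reference_surfaces()]. Extra columns are ignored.
#' @param liquids Probe-liquid set; see [default_liquids()].
#' @param vogler_threshold Water adhesion tension above which a surface is
#'   labelled hydrophilic, mJ m^-2.
#' @param baier_window Closed interval of \eqn{\gamma_c} (mJ m^-2)
#'   regarded as the minimal-adhesion zone of the Baier curve.
#' @return An object of class `"vocg"`: a list with elements `table` (the
#'   per-surface results, see below), `liquids`, `vogler_threshold`,
#'   `baier_window` and `call`. `table` columns: the input angles plus
#'   `gamma_lw`, `gamma_plus`, `gamma_minus`, `gamma_ab`, `gamma_s`,
#'   `delta_g_coh`, `tau0`, `gamma_c`, `gamma_c_r2`, `vogler_class`,
#'   `baier_in_minimum`, `root_neg_plus`, `root_neg_minus`.
#' @examples
#' fit <- vocg(reference_surfaces())
#' summary(fit)
#' coef(fit)["GS_Normax", ]
#' @seealso [predict.vocg()], [residuals.vocg()], [simulate.vocg()],
#'   [plot.vocg()]
#' @export
vocg <- function(data, liquids = default_liquids(),
                 vogler_threshold = 30, baier_window = c(20, 30)) {
  stopifnot(is.data.frame(data))
  need <- c("theta_w", "theta_f", "theta_d")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("angle table lacks column(s): ", paste(missing, collapse = ", "))
  }
  ids <- if ("surface_id" %in% names(data)) as.character(data$surface_id)
         else sprintf("surface_%d", seq_len(nrow(data)))
  if (anyDuplicated(ids)) stop("surface_id values must be unique")

  comp <- solve_components(data$theta_w, data$theta_f, data$theta_d, liquids)
  dg <- delta_g_coh(comp$gamma_lw, comp$gamma_plus, comp$gamma_minus,
                    liquids$water)
  tau0 <- water_adhesion_tension(data$theta_w, liquids$water)

  gc <- gc_r2 <- rep(NA_real_, nrow(data))
  for (i in seq_len(nrow(data))) {
    z <- tryCatch(
      critical_surface_tension(c(water = data$theta_w[i],
                                 formamide = data$theta_f[i],
                                 diiodomethane = data$theta_d[i]),
                               liquids),
      error = function(e) c(gamma_c = NA_real_, r2 = NA_real_))
    gc[i] <- z[["gamma_c"]]; gc_r2[i] <- z[["r2"]]
  }

  tab <- data.frame(surface_id = ids,
                    theta_w = data$theta_w, theta_f = data$theta_f,
                    theta_d = data$theta_d,
                    comp[c("gamma_lw", "gamma_plus", "gamma_minus",
                           "gamma_ab", "gamma_s")],
                    delta_g_coh = dg, tau0 = tau0,
                    gamma_c = gc, gamma_c_r2 = gc_r2,
                    vogler_class = classify_vogler(tau0, vogler_threshold),
                    baier_in_minimum = baier_zone(gc, baier_window),
                    comp[c("root_neg_plus", "root_neg_minus")],
                    row.names = NULL)
  if ("ra_um" %in% names(data)) tab$ra_um <- data$ra_um
  structure(list(table = tab, liquids = liquids,
                 vogler_threshold = vogler_threshold,
                 baier_window = baier_window, call = match.call()),
            class = "vocg")
}

#' @export
print.vocg <- function(x, digits = 3, ...) {
  cat("Three-liquid acid-base surface-energy fit (", nrow(x$table),
      " surface", if (nrow(x$table) != 1) "s", ")\n", sep = "")
  cols <- c("surface_id", "gamma_s", "delta_g_coh", "tau0", "vogler_class")
  print(format(x$table[cols], digits = digits), row.names = FALSE)
  nneg <- sum(x$table$root_neg_plus | x$table$root_neg_minus)
  if (nneg > 0) {
    cat("Note: ", nneg, " surface(s) solved with a negative acid/base square",
        " root;\nmagnitudes were carried into gamma_ab (see root_neg_* flags).\n",
        sep = "")
  }
  invisible(x)
}

#' Summarize a surface-energy fit
#'
#' @param object A [vocg()] fit.
#' @param ... Unused.
#' @return An object of class `"summary.vocg"` wrapping the full result
#'   table and classification settings.
#' @export
summary.vocg <- function(object, ...) {
  structure(list(table = object$table,
                 vogler_threshold = object$vogler_threshold,
                 baier_window = object$baier_window),
            class = "summary.vocg")
}

#' @export
print.summary.vocg <- function(x, digits = 3, ...) {
  cat("Surface characterization (energies in mJ m^-2, angles in degrees)\n")
  cat(sprintf("Vogler threshold: tau0 > %g; Baier window: [%g, %g]\n\n",
              x$vogler_threshold, x$baier_window[1], x$baier_window[2]))
  cols <- c("surface_id", "theta_w", "theta_f", "theta_d", "gamma_lw",
            "gamma_plus", "gamma_minus", "gamma_s", "delta_g_coh", "tau0",
            "gamma_c", "gamma_c_r2", "vogler_class", "baier_in_minimum")
  print(format(x$table[cols], digits = digits), row.names = FALSE)
  invisible(x)
}

#' Extract fitted surface-energy components
#'
#' @param object A [vocg()] fit.
#' @param ... Unused.
#' @return Numeric matrix (surfaces x components) with columns
#'   `gamma_lw`, `gamma_plus`, `gamma_minus`, `gamma_ab`, `gamma_s`.
#' @export
coef.vocg <- function(object, ...) {
  m <- as.matrix(object$table[c("gamma_lw", "gamma_plus", "gamma_minus",
                                "gamma_ab", "gamma_s")])
  rownames(m) <- object$table$surface_id
  m
}

#' Predict contact angles from a fitted surface-energy model
#'
#' Evaluates the forward Young--Dupre map from the fitted components, for
#' the fitting liquids or any other probe-liquid set. For surfaces whose
#' inversion produced only non-negative square roots this reproduces the
#' observed angles; for negative-root (typically monopolar) surfaces the
#' magnitude convention makes the forward map deviate -- up to predicting
#' complete wetting (`NA` angle, with a warning, when the implied
#' \eqn{\cos\theta} leaves `[-1, 1]`) -- which is exactly the imbalance
#' [residuals.vocg()] quantifies.
#'
#' @param object A [vocg()] fit.
#' @param liquids Probe-liquid set to predict for; defaults to the set the
#'   model was fitted with.
#' @param ... Unused.
#' @return data.frame of predicted angles (degrees), one row per surface,
#'   one column per liquid, with `surface_id` first.
#' @export
predict.vocg <- function(object, liquids = object$liquids, ...) {
  ct <- forward_cos(object$table$gamma_lw, object$table$gamma_plus,
                    object$table$gamma_minus, liquids)
  if (anyNA(ct)) {
    warning("forward map unphysical (cos theta outside [-1, 1]) for ",
            sum(!stats::complete.cases(ct)),
            " surface(s); returning NA angles there")
  }
  ang <- as.data.frame(lapply(ct, acos_deg))
  cbind(data.frame(surface_id = object$table$surface_id), ang)
}

#' Young--Dupre residuals of a surface-energy fit
#'
#' For each surface and fitting liquid, the imbalance
#' \eqn{\gamma_L(1+\cos\theta_L) - 2(\sqrt{\gamma_s^{LW}\gamma_L^{LW}} +
#' \sqrt{\gamma_s^+\gamma_L^-} + \sqrt{\gamma_s^-\gamma_L^+})} in mJ m^-2,
#' computed with the stored (magnitude-convention) components. Residuals
#' are numerically zero whenever both acid-base square roots solved
#' non-negative; non-zero residuals flag monopolar surfaces for which the
#' three equations have no exact non-negative solution.
#'
#' @param object A [vocg()] fit.
#' @param ... Unused.
#' @return Numeric matrix (surfaces x liquids).
#' @export
residuals.vocg <- function(object, ...) {
  tab <- object$table
  liq <- resolve_liquid_roles(object$liquids)
  res <- sapply(liq, function(L) {
    obs <- L$gamma_total * (1 + cos_deg(tab[[paste0("theta_", substr(L$name, 1, 1))]]))
    fit <- 2 * (sqrt(tab$gamma_lw * L$gamma_lw) +
                  sqrt(tab$gamma_plus * L$gamma_minus) +
                  sqrt(tab$gamma_minus * L$gamma_plus))
    obs - fit
  })
  matrix(res, nrow = nrow(tab),
         dimnames = list(tab$surface_id, names(liq)))
}

#' Zisman plot of a surface-energy fit
#'
#' Plots \eqn{\cos\theta} against the probe liquids' total surface
#' tensions with the fitted Zisman line per surface; the critical surface
#' tension \eqn{\gamma_c} is where each line crosses \eqn{\cos\theta = 1}.
#'
#' @param x A [vocg()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.vocg <- function(x, ...) {
  tab <- x$table
  gl <- vapply(x$liquids[c("water", "formamide", "diiodomethane")],
               function(L) L$gamma_total, numeric(1))
  ct <- cbind(cos_deg(tab$theta_w), cos_deg(tab$theta_f), cos_deg(tab$theta_d))
  graphics::plot(NA, xlim = range(c(gl, tab$gamma_c), na.rm = TRUE),
                 ylim = range(c(ct, 1)),
                 xlab = expression(gamma[L] ~ (mJ ~ m^-2)),
                 ylab = expression(cos ~ theta), ...)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  for (i in seq_len(nrow(tab))) {
    graphics::points(gl, ct[i, ], pch = 19, col = i)
    fit <- stats::lm(ct[i, ] ~ gl)
    graphics::abline(fit, col = i, lty = 2)
  }
  graphics::legend("bottomleft", legend = tab$surface_id, col = seq_len(nrow(tab)),
                   pch = 19, cex = 0.7, bty = "n")
  invisible(x)
}

#' Simulate replicate contact-angle measurements from a fitted model
#'
#' Draws synthetic goniometer replicates around each surface's fitted
#' angles (forward Young--Dupre map plus Gaussian measurement noise),
#' matching the triplicate structure of sessile-drop data. A thin wrapper
#' over [synth_contact_angles()].
#'
#' @param object A [vocg()] fit.
#' @param nsim Number of replicates per surface and liquid.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @param angle_sd Measurement SD in degrees.
#' @param ... Unused.
#' @return Long-format data.frame: `surface_id`, `liquid`, `replicate`,
#'   `angle_deg`.
#' @export
simulate.vocg <- function(object, nsim = 3, seed = NULL, angle_sd = 2, ...) {
  truth <- data.frame(surface_id = object$table$surface_id,
                      gamma_lw = object$table$gamma_lw,
                      gamma_plus = object$table$gamma_plus,
                      gamma_minus = object$table$gamma_minus)
  synth_contact_angles(truth, n_replicates = nsim, angle_sd = angle_sd,
                       seed = seed, liquids = object$liquids)
}
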