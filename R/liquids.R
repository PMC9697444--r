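#' Probe-liquid surface-tension parameters
#'
#' A probe liquid is described by its total surface tension and its van
#' Oss--Chaudhury--Good (vOCG) decomposition: a Lifshitz--van der Waals
#' (dispersive) component and the Lewis acid--base electron-acceptor
#' (`gamma_plus`) and electron-donor (`gamma_minus`) parameters. All
#' values are in mJ m^-2 (equivalently mN m^-1) at room temperature.
#'
#' The parameters must satisfy the vOCG consistency identity
#' \deqn{\gamma = \gamma^{LW} + 2\sqrt{\gamma^{+}\gamma^{-}},}
#' which is checked to 0.1 mJ m^-2. An apolar liquid has
#' `gamma_plus = gamma_minus = 0`.
#'
#' @param name Liquid name (e.g. `"water"`).
#' @param gamma_total Total surface tension, mJ m^-2.
#' @param gamma_lw Lifshitz--van der Waals component, mJ m^-2.
#' @param gamma_plus Electron-acceptor parameter, mJ m^-2.
#' @param gamma_minus Electron-donor parameter, mJ m^-2.
#'
#' @return An object of class `"probe_liquid"`: a named list with the
#'   five fields above.
#' @examples
#' probe_liquid("water", 72.8, 21.8, 25.5, 25.5)
#' @export
probe_liquid <- function(name, gamma_total, gamma_lw, gamma_plus, gamma_minus) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(gamma_total = gamma_total, gamma_lw = gamma_lw,
            gamma_plus = gamma_plus, gamma_minus = gamma_minus)
  if (any(!is.finite(vals))) {
    stop("probe liquid '", name, "': all parameters must be finite numbers")
  }
  if (gamma_lw < 0 || gamma_plus < 0 || gamma_minus < 0) {
    stop("probe liquid '", name, "': surface-tension components must be >= 0")
  }
  if (gamma_total < gamma_lw) {
    stop("probe liquid '", name, "': gamma_total must be >= gamma_lw")
  }
  recomposed <- gamma_lw + 2 * sqrt(gamma_plus * gamma_minus)
  if (abs(recomposed - gamma_total) > 0.1) {
    stop(sprintf(
      "probe liquid '%s': gamma_lw + 2*sqrt(gamma_plus*gamma_minus) = %.3f does not match gamma_total = %.3f (tolerance 0.1 mJ m^-2)",
      name, recomposed, gamma_total))
  }
  structure(list(name = name,
                 gamma_total = gamma_total,
                 gamma_lw = gamma_lw,
                 gamma_plus = gamma_plus,
                 gamma_minus = gamma_minus),
            class = "probe_liquid")
}

#' @export
print.probe_liquid <- function(x, ...) {
  cat(sprintf("<probe_liquid> %s: gamma = %.1f (LW %.1f, + %.2f, - %.2f) mJ m^-2\n",
              x$name, x$gamma_total, x$gamma_lw, x$gamma_plus, x$gamma_minus))
  invisible(x)
}

is_apolar <- function(liquid) {
  liquid$gamma_plus == 0 && liquid$gamma_minus == 0
}

#' Default probe-liquid set for three-liquid surface-energy analysis
#'
#' Returns the standard vOCG reference parameters for the two polar probe
#' liquids (water, formamide) and the apolar one (diiodomethane) used in
#' sessile-drop surface characterization. Values in mJ m^-2:
#'
#' | liquid        | total | LW   | acceptor | donor |
#' |---------------|-------|------|----------|-------|
#' | water         | 72.8  | 21.8 | 25.5     | 25.5  |
#' | formamide     | 58.0  | 39.0 | 2.28     | 39.6  |
#' | diiodomethane | 50.8  | 50.8 | 0        | 0     |
#'
#' These are the van Oss reference values (water acid/base parameters set
#' equal by convention). Published liquid parameter sets differ slightly,
#' notably for formamide; this set was validated against the benchmark
#' surface table shipped with the package (see [reference_surfaces()]),
#' which it reproduces. Alternative constants can be supplied through the
#' `liquids:` section of a run configuration (see [liquids_from_config()])
#' rather than by mutating the returned list.
#'
#' @return Named list of [probe_liquid()] objects
#'   (`water`, `formamide`, `diiodomethane`).
#' @examples
#' default_liquids()$water
#' @export
default_liquids <- function() {
  list(
    water         = probe_liquid("water", 72.8, 21.8, 25.5, 25.5),
    formamide     = probe_liquid("formamide", 58.0, 39.0, 2.28, 39.6),
    diiodomethane = probe_liquid("diiodomethane", 50.8, 50.8, 0, 0)
  )
}

#' Build a probe-liquid set from a configuration list or YAML file
#'
#' Reads a `liquids:` mapping of the form
#' ```yaml
#' liquids:
#'   water: {gamma_total: 72.8, gamma_lw: 21.8, gamma_plus: 25.5, gamma_minus: 25.5}
#' ```
#' and merges it over [default_liquids()]: named liquids replace the
#' defaults, unnamed defaults are kept. Each override is validated by
#' [probe_liquid()].
#'
#' @param config Path to a YAML file, or an already-parsed list. A top-level
#'   `liquids` element is used if present, otherwise the list itself is
#'   treated as the mapping.
#' @return Named list of [probe_liquid()] objects.
#' @export
liquids_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  overrides <- if (!is.null(config$liquids)) config$liquids else config
  out <- default_liquids()
  for (nm in names(overrides)) {
    entry <- overrides[[nm]]
    required <- c("gamma_total", "gamma_lw", "gamma_plus", "gamma_minus")
    missing <- setdiff(required, names(entry))
    if (length(missing)) {
      stop("liquid override '", nm, "' is missing field(s): ",
           paste(missing, collapse = ", "))
    }
    out[[nm]] <- probe_liquid(nm, entry$gamma_total, entry$gamma_lw,
                              entry$gamma_plus, entry$gamma_minus)
  }
  out
}

# Check a liquid set contains the three roles the inversion needs and
# return them as list(water=, polar2=, apolar=).
resolve_liquid_roles <- function(liquids) {
  stopifnot(is.list(liquids))
  need <- c("water", "formamide", "diiodomethane")
  missing <- setdiff(need, names(liquids))
  if (length(missing)) {
    stop("liquid set must contain ", paste(need, collapse = ", "),
         "; missing: ", paste(missing, collapse = ", "))
  }
  if (!is_apolar(liquids$diiodomethane)) {
    stop("diiodomethane entry must be apolar (gamma_plus = gamma_minus = 0)")
  }
  liquids[need]
}
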