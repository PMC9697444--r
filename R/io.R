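## CSV readers/writers and the pipeline orchestrator. Dialect: UTF-8,
## comma separator, header row, decimal point.

stop_rows <- function(path, bad, what) {
  # +1: header line
  stop("'", basename(path), "': ", what, " at data row(s) ",
       paste(utils::head(which(bad), 5), collapse = ", "),
       " (file line(s) ",
       paste(utils::head(which(bad) + 1L, 5), collapse = ", "), ")")
}

require_columns <- function(df, need, path) {
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("'", basename(path), "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Read a contact-angle table
#'
#' Accepts either layout:
#' * long: columns `surface_id`, `liquid` (`water`/`formamide`/
#'   `diiodomethane`), `angle_deg`, `replicate` -- replicates are
#'   aggregated to mean and SD per surface and liquid;
#' * wide: columns `surface_id`, `theta_w`, `theta_f`, `theta_d`, with
#'   optional `sd_w`, `sd_f`, `sd_d`, `n_replicates`, `ra_um`.
#'
#' Angles are validated to `[0, 180)` degrees; malformed rows are reported
#' with their file line numbers.
#'
#' @param path CSV file path.
#' @return data.frame with one row per surface: `surface_id`, `theta_w`,
#'   `theta_f`, `theta_d`, `sd_w`, `sd_f`, `sd_d`, `n_replicates`
#'   (plus `ra_um` when present) -- ready for [vocg()].
#' @examples
#' path <- system.file("extdata", "example_angles.csv", package = "pbrsurf")
#' vocg(read_angle_table(path))
#' @export
read_angle_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(data.frame(surface_id = character(0), theta_w = numeric(0),
                      theta_f = numeric(0), theta_d = numeric(0),
                      sd_w = numeric(0), sd_f = numeric(0), sd_d = numeric(0),
                      n_replicates = integer(0)))
  }
  if ("angle_deg" %in% names(df)) {
    require_columns(df, c("surface_id", "liquid", "angle_deg", "replicate"), path)
    if (!is.numeric(df$angle_deg)) {
      stop_rows(path, !grepl("^\\s*-?[0-9.eE+-]+\\s*$", as.character(df$angle_deg)),
                "non-numeric angle")
    }
    bad <- !is.finite(df$angle_deg) | df$angle_deg < 0 | df$angle_deg >= 180
    if (any(bad)) stop_rows(path, bad, "angle outside [0, 180)")
    known <- c("water", "formamide", "diiodomethane")
    if (any(!df$liquid %in% known)) {
      stop_rows(path, !df$liquid %in% known,
                paste("liquid not one of", paste(known, collapse = "/")))
    }
    ids <- unique(df$surface_id)
    if (!all(known %in% unique(df$liquid))) {
      stop("'", basename(path),
           "': every surface needs angles for all three liquids")
    }
    agg_mean <- tapply(df$angle_deg, list(df$surface_id, df$liquid), mean)
    agg_sd <- tapply(df$angle_deg, list(df$surface_id, df$liquid), stats::sd)
    agg_n <- tapply(df$angle_deg, list(df$surface_id, df$liquid), length)
    if (any(is.na(agg_mean[ids, known]))) {
      stop("'", basename(path),
           "': every surface needs angles for all three liquids")
    }
    out <- data.frame(surface_id = ids,
                      theta_w = agg_mean[ids, "water"],
                      theta_f = agg_mean[ids, "formamide"],
                      theta_d = agg_mean[ids, "diiodomethane"],
                      sd_w = agg_sd[ids, "water"],
                      sd_f = agg_sd[ids, "formamide"],
                      sd_d = agg_sd[ids, "diiodomethane"],
                      n_replicates = as.integer(agg_n[ids, "water"]),
                      row.names = NULL)
  } else {
    require_columns(df, c("surface_id", "theta_w", "theta_f", "theta_d"), path)
    for (col in c("theta_w", "theta_f", "theta_d")) {
      v <- df[[col]]
      if (!is.numeric(v)) stop("'", basename(path), "': column ", col,
                               " is not numeric")
      bad <- !is.finite(v) | v < 0 | v >= 180
      if (any(bad)) stop_rows(path, bad, paste(col, "outside [0, 180)"))
    }
    out <- df
    for (col in c("sd_w", "sd_f", "sd_d")) {
      if (is.null(out[[col]])) out[[col]] <- NA_real_
      else if (any(out[[col]] < 0, na.rm = TRUE)) {
        stop_rows(path, !is.na(out[[col]]) & out[[col]] < 0, "negative SD")
      }
    }
    if (is.null(out$n_replicates)) out$n_replicates <- NA_integer_
  }
  if (anyDuplicated(out$surface_id)) {
    stop("'", basename(path), "': duplicated surface_id")
  }
  out
}

#' Read a zeta-potential profile table
#'
#' Long-format CSV with columns `surface_id`, `tracer`, `nacl_mm`,
#' `displacement_um`, `zeta_mv` and optionally logical `is_far_field`;
#' when the flag is absent, rows with `displacement_um >= 1000` are
#' treated as the far-field tracer measurement.
#'
#' @param path CSV file path.
#' @return Validated data.frame (with `is_far_field` filled in), ready for
#'   [zeta_report()].
#' @export
read_zeta_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("surface_id", "tracer", "nacl_mm",
                        "displacement_um", "zeta_mv"), path)
  for (col in c("nacl_mm", "displacement_um", "zeta_mv")) {
    if (!is.numeric(df[[col]])) {
      stop("'", basename(path), "': column ", col, " is not numeric")
    }
  }
  bad <- !is.finite(df$displacement_um) | df$displacement_um <= 0
  if (any(bad)) stop_rows(path, bad, "non-positive displacement")
  if (is.null(df$is_far_field)) df$is_far_field <- df$displacement_um >= 1000
  df$is_far_field <- as.logical(df$is_far_field)
  df
}

#' Read an EPS adhesion table
#'
#' CSV with columns `surface_id`, `material`, `ra_um`, `eps_type`,
#' `mass_ug`, `area_cm2`, `replicate`.
#'
#' @param path CSV file path.
#' @return Validated data.frame, ready for [adhesion_report()].
#' @export
read_adhesion_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("surface_id", "material", "ra_um", "eps_type",
                        "mass_ug", "area_cm2", "replicate"), path)
  for (col in c("ra_um", "mass_ug", "area_cm2")) {
    if (!is.numeric(df[[col]])) {
      stop("'", basename(path), "': column ", col, " is not numeric")
    }
  }
  if (any(df$mass_ug < 0)) stop_rows(path, df$mass_ug < 0, "negative mass")
  if (any(df$area_cm2 <= 0)) stop_rows(path, df$area_cm2 <= 0, "non-positive area")
  if (any(df$ra_um < 0)) stop_rows(path, df$ra_um < 0, "negative roughness")
  df
}

#' Write a report table to CSV
#'
#' Plain UTF-8 comma-separated output with header and no row names; a
#' table written with this function reads back equal (up to column
#' classes) with [utils::read.csv()].
#'
#' @param report data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  utils::write.csv(report, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML with any of the keys: `angles`, `zeta`, `adhesion` (input CSV
#' paths), `output` (report CSV path), `liquids` (parameter overrides, see
#' [liquids_from_config()]), `vogler_threshold`, `baier_window`, `alpha`,
#' `control_surface`, `seed`. Relative input paths are resolved against
#' the config file's directory.
#'
#' @param path YAML file path.
#' @return Config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  base <- dirname(normalizePath(path))
  for (key in c("angles", "zeta", "adhesion", "output")) {
    if (!is.null(cfg[[key]]) && !grepl("^(/|[A-Za-z]:)", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  defaults <- list(vogler_threshold = 30, baier_window = c(20, 30),
                   alpha = 0.05, control_surface = NULL, seed = NULL)
  for (key in names(defaults)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  }
  cfg$liquids <- if (is.null(cfg$liquids)) default_liquids()
                 else liquids_from_config(cfg["liquids"])
  cfg
}

#' Run the full surface-characterization pipeline
#'
#' Orchestrates the whole analysis from a configuration (a YAML path or a
#' list as returned by [read_run_config()]): reads the contact-angle
#' table, fits [vocg()] to obtain surface-energy components, cohesion
#' free energy, water adhesion tension, critical surface tension and
#' Vogler/Baier labels, and -- when the corresponding inputs are
#' configured -- adds surface-zeta extrapolations ([zeta_report()]) and
#' control-normalized adhesion statistics ([adhesion_report()]). Progress
#' is reported per stage via [message()]; a warning is emitted for every
#' surface whose acid-base inversion used a negative square root and for
#' every Zisman fit with \eqn{r^2 < 0.9} (read those critical tensions
#' qualitatively).
#'
#' @param config YAML file path or config list; see [read_run_config()].
#' @return List of class `"pbr_characterization"` with elements
#'   `surfaces` (the [vocg()] result table), `fit` (the full [vocg()]
#'   object), and optionally `zeta` and `adhesion`. An empty angle table
#'   yields an empty report with a warning. If `config$output` is set the
#'   surface table is also written there as CSV.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_report(reference_surfaces(), tmp)
#' res <- run_characterization(list(angles = tmp))
#' head(res$surfaces)
#' @export
run_characterization <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  if (is.null(config$liquids)) config$liquids <- default_liquids()
  if (is.null(config$vogler_threshold)) config$vogler_threshold <- 30
  if (is.null(config$baier_window)) config$baier_window <- c(20, 30)
  if (is.null(config$alpha)) config$alpha <- 0.05
  if (is.null(config$angles)) stop("config must name an 'angles' input")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  message("stage angles: reading ", config$angles)
  angles <- if (is.data.frame(config$angles)) config$angles
            else stage("angles", read_angle_table(config$angles))
  if (nrow(angles) == 0) {
    warning("empty angle table: nothing to characterize")
    return(structure(list(surfaces = data.frame(), fit = NULL),
                     class = "pbr_characterization"))
  }

  message("stage surface_energy: inverting ", nrow(angles), " angle triple(s)")
  fit <- stage("surface_energy",
               vocg(angles, liquids = config$liquids,
                    vogler_threshold = config$vogler_threshold,
                    baier_window = config$baier_window))
  tab <- fit$table
  flagged <- tab$surface_id[tab$root_neg_plus | tab$root_neg_minus]
  if (length(flagged)) {
    warning("negative acid-base square root (magnitude convention applied) for: ",
            paste(flagged, collapse = ", "))
  }
  weak <- tab$surface_id[!is.na(tab$gamma_c_r2) & tab$gamma_c_r2 < 0.9]
  if (length(weak)) {
    warning("Zisman fit r^2 < 0.9 (critical tension unreliable) for: ",
            paste(weak, collapse = ", "))
  }

  out <- list(surfaces = tab, fit = fit)
  if (!is.null(config$zeta)) {
    message("stage zeta: reading ", config$zeta)
    zdf <- if (is.data.frame(config$zeta)) config$zeta
           else stage("zeta", read_zeta_table(config$zeta))
    out$zeta <- stage("zeta", zeta_report(zdf))
  }
  if (!is.null(config$adhesion)) {
    if (is.null(config$control_surface)) {
      stop("[adhesion] config must set 'control_surface' for normalization")
    }
    message("stage adhesion: reading ", config$adhesion)
    adf <- if (is.data.frame(config$adhesion)) config$adhesion
           else stage("adhesion", read_adhesion_table(config$adhesion))
    out$adhesion <- stage("adhesion",
                          adhesion_report(adf, control = config$control_surface,
                                          alpha = config$alpha))
  }
  if (!is.null(config$output) && is.character(config$output)) {
    message("stage output: writing ", config$output)
    write_report(tab, config$output)
  }
  structure(out, class = "pbr_characterization")
}

#' @export
print.pbr_characterization <- function(x, ...) {
  cat("Photobioreactor-surface characterization report\n")
  if (is.null(x$fit)) {
    cat("  (empty)\n")
    return(invisible(x))
  }
  print(x$fit)
  if (!is.null(x$zeta)) {
    cat("\nSurface zeta potentials:\n")
    print(format(x$zeta, digits = 3), row.names = FALSE)
  }
  if (!is.null(x$adhesion)) {
    for (nm in names(x$adhesion)) {
      cat("\nAdhesion (", nm, "):\n", sep = "")
      print(x$adhesion[[nm]])
    }
  }
  invisible(x)
}
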