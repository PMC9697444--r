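## Synthetic-data generators. These emulate the replicate structure of
## the three instrument streams (goniometer angles, dip-cell zeta
## profiles, EPS adhesion masses) so the whole pipeline is testable
## without laboratory data. All are pure functions of (arguments, seed).

# Run code with a temporary RNG state; restores .Random.seed on exit.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Built-in truth library of surface-energy components
#'
#' vOCG components (mJ m^-2) for the six distinct materials of the
#' benchmark set ([reference_surfaces()]), obtained by inverting their
#' benchmark mean contact angles with [solve_components()] under the
#' default liquids. Where the inversion produced a negative acid/base
#' square root the offending parameter is set to zero (the monopolar
#' projection): a truth library must contain physically realizable
#' component sets -- ones whose forward Young--Dupre angles exist -- and
#' the magnitude-convention components of monopolar surfaces are not.
#' Intended as ground truth for the synthetic contact-angle generator, so
#' full-pipeline demonstrations reproduce a benchmark-like
#' characterization end to end.
#'
#' @return data.frame: `surface_id`, `gamma_lw`, `gamma_plus`,
#'   `gamma_minus`.
#' @export
synth_truth_library <- function() {
  ref <- reference_surfaces()
  pick <- c("GS_Normax", "PC_Ferplast", "PE_Ferplast", "PETG_Ferplast",
            "PMMA_transparent_Transglass", "PVC_transparent_Transglass")
  ref <- ref[match(pick, ref$surface_id), ]
  comp <- solve_components(ref$theta_w, ref$theta_f, ref$theta_d)
  data.frame(surface_id = ref$surface_id,
             gamma_lw = comp$gamma_lw,
             gamma_plus = ifelse(comp$root_neg_plus, 0, comp$gamma_plus),
             gamma_minus = ifelse(comp$root_neg_minus, 0, comp$gamma_minus),
             row.names = NULL)
}

#' Generate replicate sessile-drop contact angles
#'
#' Forward model: each material's true angles are computed from its vOCG
#' components via [forward_angles()]; goniometer replicates add
#' independent Gaussian noise (in degrees, matching how replicate SDs are
#' reported for such measurements), clamped to `[0, 180)`.
#'
#' @param truth data.frame with columns `surface_id`, `gamma_lw`,
#'   `gamma_plus`, `gamma_minus`; defaults to [synth_truth_library()].
#' @param n_replicates Replicates per surface and liquid (assay default 3).
#' @param angle_sd Measurement SD in degrees, in `[0, 10]` (replicate SDs
#'   of sessile-drop triplicates are typically 1--5 degrees; default 2).
#' @param seed Optional integer seed; RNG state is restored on exit.
#' @param liquids Probe-liquid set.
#' @return Long-format data.frame: `surface_id`, `liquid`, `replicate`,
#'   `angle_deg` -- the schema [read_angle_table()] accepts.
#' @examples
#' head(synth_contact_angles(seed = 1))
#' @export
synth_contact_angles <- function(truth = synth_truth_library(),
                                 n_replicates = 3, angle_sd = 2,
                                 seed = NULL, liquids = default_liquids()) {
  stopifnot(is.data.frame(truth),
            all(c("surface_id", "gamma_lw", "gamma_plus", "gamma_minus")
                %in% names(truth)),
            all(truth$gamma_lw >= 0), all(truth$gamma_plus >= 0),
            all(truth$gamma_minus >= 0),
            n_replicates >= 2, angle_sd >= 0, angle_sd <= 10)
  true_ang <- forward_angles(truth$gamma_lw, truth$gamma_plus,
                             truth$gamma_minus, liquids)
  if (!is.data.frame(true_ang)) true_ang <- as.data.frame(as.list(true_ang))
  with_seed(seed, {
    out <- expand.grid(replicate = seq_len(n_replicates),
                       liquid = names(liquids),
                       surface_id = truth$surface_id,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- out[c("surface_id", "liquid", "replicate")]
    mu <- mapply(function(s, l) true_ang[match(s, truth$surface_id), l],
                 out$surface_id, out$liquid)
    ang <- mu + stats::rnorm(nrow(out), 0, angle_sd)
    out$angle_deg <- pmin(pmax(ang, 0), 180 - 1e-6)
    rownames(out) <- NULL
    out
  })
}

#' Generate displacement-resolved zeta-potential profiles
#'
#' Emulates dip-cell surface-zeta measurements: apparent zeta is linear in
#' displacement over the near-wall points (125--625 um by default) plus
#' Gaussian instrument noise, with a separate far-field tracer row at
#' 1000 um whose value is the configured \eqn{\zeta_m}. The implied true
#' surface zeta potential is `-intercept + zeta_far`.
#'
#' @param profiles data.frame with one row per profile: columns
#'   `surface_id`, `intercept` (mV), `slope` (mV/um), `zeta_far` (mV) and
#'   optionally `tracer` (default `"standard"`) and `nacl_mm` (default 0).
#' @param displacements Near-wall displacements, um.
#' @param far_displacement Far-field displacement, um.
#' @param noise_sd Gaussian noise SD on the near-wall apparent values, mV
#'   (the far-field row is reported as configured).
#' @param seed Optional integer seed; RNG state is restored on exit.
#' @return Long-format data.frame with the [read_zeta_table()] schema:
#'   `surface_id`, `tracer`, `nacl_mm`, `displacement_um`, `zeta_mv`,
#'   `is_far_field`.
#' @examples
#' p <- data.frame(surface_id = "GS", intercept = -60, slope = 0.02,
#'                 zeta_far = -40)
#' zeta_report(synth_zeta_profiles(p, noise_sd = 0)) # zeta_s = +20
#' @export
synth_zeta_profiles <- function(profiles,
                                displacements = c(125, 250, 375, 500, 625),
                                far_displacement = 1000,
                                noise_sd = 1, seed = NULL) {
  stopifnot(is.data.frame(profiles),
            all(c("surface_id", "intercept", "slope", "zeta_far")
                %in% names(profiles)),
            noise_sd >= 0, all(displacements > 0),
            far_displacement > max(displacements))
  if (is.null(profiles$tracer)) profiles$tracer <- "standard"
  if (is.null(profiles$nacl_mm)) profiles$nacl_mm <- 0
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(profiles)), function(i) {
      p <- profiles[i, ]
      near <- p$intercept + p$slope * displacements +
        stats::rnorm(length(displacements), 0, noise_sd)
      data.frame(surface_id = p$surface_id, tracer = p$tracer,
                 nacl_mm = p$nacl_mm,
                 displacement_um = c(displacements, far_displacement),
                 zeta_mv = c(near, p$zeta_far),
                 is_far_field = c(rep(FALSE, length(displacements)), TRUE))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate replicate EPS adhesion measurements
#'
#' Emulates the triplicate adhesion assay: per material x roughness x EPS
#' type, replicate adhered masses are Gaussian with a coefficient of
#' variation around the configured mean areal density, on a fixed coupon
#' area. The control group's mean density defaults to the glass-control
#' benchmark of 3.0 ug cm^-2 (its own level is expressed as a relative
#' density of 1).
#'
#' @param materials data.frame with one row per material x roughness:
#'   columns `material`, `ra_um` and `rel_density` (mean areal density as
#'   a multiple of `control_density`); optionally `surface_id` (default
#'   `material_ra`).
#' @param eps_types EPS labels to simulate (a protein and a polysaccharide
#'   foulant by default).
#' @param control_density Control areal density, ug cm^-2.
#' @param area_cm2 Coupon area, cm^2 (default the 2.5 x 7.5 cm coupon,
#'   18.75 cm^2).
#' @param cv Coefficient of variation of replicate masses (default 0.03,
#'   matching a 3.0 +/- 0.1 ug cm^-2 control).
#' @param n_replicates Replicates per group (assay default 3).
#' @param seed Optional integer seed; RNG state is restored on exit.
#' @return data.frame with the [read_adhesion_table()] schema:
#'   `surface_id`, `material`, `ra_um`, `eps_type`, `mass_ug`, `area_cm2`,
#'   `replicate`. Masses are truncated at 0.
#' @examples
#' m <- data.frame(material = c("GS", "PC"), ra_um = 0.05,
#'                 rel_density = c(1, 1.5))
#' head(synth_adhesion(m, seed = 1))
#' @export
synth_adhesion <- function(materials, eps_types = c("BSA", "PST"),
                           control_density = 3.0, area_cm2 = 18.75,
                           cv = 0.03, n_replicates = 3, seed = NULL) {
  stopifnot(is.data.frame(materials),
            all(c("material", "ra_um", "rel_density") %in% names(materials)),
            all(materials$rel_density >= 0), all(materials$ra_um >= 0),
            control_density > 0, area_cm2 > 0, cv >= 0, n_replicates >= 2)
  if (is.null(materials$surface_id)) {
    materials$surface_id <- paste(materials$material, materials$ra_um, sep = "_")
  }
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        eps_type = eps_types,
                        row = seq_len(nrow(materials)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- materials$rel_density[grid$row] * control_density * area_cm2
    mass <- stats::rnorm(nrow(grid), mean = mu, sd = cv * mu)
    out <- data.frame(surface_id = materials$surface_id[grid$row],
                      material = materials$material[grid$row],
                      ra_um = materials$ra_um[grid$row],
                      eps_type = grid$eps_type,
                      mass_ug = pmax(mass, 0),
                      area_cm2 = area_cm2,
                      replicate = grid$replicate)
    rownames(out) <- NULL
    out
  })
}
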