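test_that("generators are pure functions of their seed", {
  a <- synth_contact_angles(seed = 123)
  b <- synth_contact_angles(seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, synth_contact_angles(seed = 124)))
  p <- data.frame(surface_id = "GS", intercept = -60, slope = 0.02,
                  zeta_far = -40)
  expect_identical(synth_zeta_profiles(p, seed = 5),
                   synth_zeta_profiles(p, seed = 5))
  mats <- data.frame(material = "GS", ra_um = 0.05, rel_density = 1)
  expect_identical(synth_adhesion(mats, seed = 5), synth_adhesion(mats, seed = 5))
  # the global RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(synth_contact_angles(seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("noise-free angles invert back to the exact truth", {
  truth <- synth_truth_library()
  ang <- synth_contact_angles(truth, angle_sd = 0, seed = 1)
  # aggregate replicates like the reader does, then invert
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_report(ang, path)
  agg <- read_angle_table(path)
  agg <- agg[match(truth$surface_id, agg$surface_id), ]
  comp <- solve_components(agg$theta_w, agg$theta_f, agg$theta_d)
  expect_equal(comp$gamma_lw, truth$gamma_lw, tolerance = 1e-6)
  expect_equal(comp$gamma_plus, truth$gamma_plus, tolerance = 1e-6)
  expect_equal(comp$gamma_minus, truth$gamma_minus, tolerance = 1e-6)
  expect_equal(agg$sd_w, rep(0, nrow(agg)), tolerance = 1e-12)
  expect_equal(agg$n_replicates, rep(3L, nrow(agg)))
})

test_that("replicate noise averages out over many simulated assays", {
  # glass-like truth; 2-degree goniometer noise, triplicates
  truth <- data.frame(surface_id = "GS", gamma_lw = 40.6,
                      gamma_plus = 0.51, gamma_minus = 51.0)
  set.seed(2024)
  gs <- replicate(500, {
    ang <- synth_contact_angles(truth, angle_sd = 2)
    m <- tapply(ang$angle_deg, ang$liquid, mean)
    solve_components(m[["water"]], m[["formamide"]], m[["diiodomethane"]])$gamma_s
  })
  truth_gs <- with(truth, gamma_lw + 2 * sqrt(gamma_plus * gamma_minus))
  expect_lt(abs(mean(gs) - truth_gs), 1)
})

test_that("zeta generator reproduces its configured profile", {
  p <- data.frame(surface_id = c("GS", "PETG"), intercept = c(-60, -75),
                  slope = c(0.02, 0.03), zeta_far = c(-40, -48))
  clean <- synth_zeta_profiles(p, noise_sd = 0, seed = 2)
  rep <- zeta_report(clean)
  expect_equal(rep$intercept[match(c("GS", "PETG"), rep$surface_id)],
               c(-60, -75), tolerance = 1e-9)
  expect_equal(rep$zeta_s[match(c("GS", "PETG"), rep$surface_id)],
               c(20, 27), tolerance = 1e-9)
  expect_identical(sort(unique(clean$displacement_um)),
                   c(125, 250, 375, 500, 625, 1000))
  # an all-negative configuration yields only negative apparent values
  neg <- synth_zeta_profiles(
    data.frame(surface_id = "PC", intercept = -45, slope = 0.002,
               zeta_far = -40), noise_sd = 0.5, seed = 3)
  expect_true(all(neg$zeta_mv < 0))
})

test_that("adhesion generator centred on the control yields a flat assay", {
  mats <- data.frame(material = c("GS", "PC"), ra_um = 0.05, rel_density = 1)
  dat <- synth_adhesion(mats, eps_types = "BSA", cv = 0, seed = 1)
  pct <- relative_adhesion(dat$mass_ug, dat$area_cm2,
                           mean(dat$mass_ug[dat$material == "GS"]), 18.75)
  expect_equal(pct, rep(100, nrow(dat)))
  res <- adhesion_report(dat, control = "GS_0.05")$BSA
  expect_true(res$degenerate)
  expect_identical(unique(res$means$letters), "a")
})

test_that("generated tables round-trip losslessly through the io layer", {
  paths <- replicate(3, tempfile(fileext = ".csv"))
  on.exit(unlink(paths))
  ang <- synth_contact_angles(seed = 6)
  write_report(ang, paths[1])
  expect_equal(utils::read.csv(paths[1]), ang)
  zet <- synth_zeta_profiles(data.frame(surface_id = "GS", intercept = -60,
                                        slope = 0.02, zeta_far = -40), seed = 6)
  write_report(zet, paths[2])
  expect_equal(read_zeta_table(paths[2]), zet)
  adh <- synth_adhesion(data.frame(material = "GS", ra_um = 0.05,
                                   rel_density = 1), seed = 6)
  write_report(adh, paths[3])
  expect_equal(read_adhesion_table(paths[3]), adh)
})
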