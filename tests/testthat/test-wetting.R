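test_that("water adhesion tension follows gamma_w cos(theta)", {
  expect_equal(water_adhesion_tension(25), 66.0, tolerance = 2e-3)
  expect_equal(water_adhesion_tension(90), 0, tolerance = 1e-12)
  expect_equal(water_adhesion_tension(97), -8.87, tolerance = 1e-3)
  # strictly decreasing on [0, 180), bounded by +/- gamma_w
  theta <- seq(0, 179.5, by = 0.5)
  tau <- water_adhesion_tension(theta)
  expect_true(all(diff(tau) < 0))
  expect_true(all(abs(tau) <= 72.8))
})

test_that("Zisman extrapolation recovers a synthetic line exactly", {
  liq <- default_liquids()
  gl <- vapply(liq, `[[`, numeric(1), "gamma_total")
  for (gc_true in c(18, 30, 44)) {
    slope <- -0.015
    ct <- 1 + slope * (gl - gc_true)
    theta <- acos(pmin(ct, 1)) * 180 / pi
    z <- critical_surface_tension(theta, liq)
    expect_equal(unname(z[["gamma_c"]]), gc_true, tolerance = 1e-9)
    expect_equal(unname(z[["r2"]]), 1, tolerance = 1e-9)
  }
})

test_that("Zisman fit guards its degenerate cases", {
  theta <- c(water = 50, formamide = 50, diiodomethane = 50)
  expect_error(critical_surface_tension(theta), "indeterminate")
  expect_error(critical_surface_tension(c(water = 50)), "at least 2")
  liq <- default_liquids()
  liq$formamide <- probe_liquid("formamide", 72.8, 21.8, 25.5, 25.5)
  expect_error(critical_surface_tension(c(water = 40, formamide = 50),
                                        liq), "distinct")
  expect_error(critical_surface_tension(c(water = 40, ethanol = 30)),
               "no liquid parameters")
})

test_that("two-liquid fit passes through both points", {
  # both liquids already wetting (cos = 1): line crosses cos = 1 at the
  # smaller tension
  liq <- default_liquids()
  ct <- c(water = 0.9, diiodomethane = 1)
  theta <- acos(ct) * 180 / pi
  z <- critical_surface_tension(theta, liq)
  expect_equal(unname(z[["gamma_c"]]), 50.8, tolerance = 1e-9)
  expect_equal(unname(z[["r2"]]), 1)
})

test_that("Vogler classification is a strict threshold", {
  expect_identical(classify_vogler(66.1), "hydrophilic")
  expect_identical(classify_vogler(30), "hydrophobic") # boundary excluded
  expect_identical(classify_vogler(24.3), "hydrophobic")
  expect_identical(classify_vogler(c(NA, 31)), c(NA, "hydrophilic"))
  # invariant to any change keeping tau0 on the same side
  expect_identical(classify_vogler(30 + abs(rnorm(20))),
                   rep("hydrophilic", 20))
})

test_that("Baier minimal-fouling window is a closed interval", {
  expect_true(baier_zone(25))
  expect_false(baier_zone(56.7))
  expect_true(baier_zone(20))
  expect_true(baier_zone(30))
  expect_false(baier_zone(19.999))
  expect_identical(baier_zone(c(25, 35), window = c(30, 40)), c(FALSE, TRUE))
})
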