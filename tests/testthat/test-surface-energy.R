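test_that("apolar equation gives the LW component in closed form", {
  expect_equal(gamma_lw_apolar(0), 50.8)           # complete wetting
  expect_equal(gamma_lw_apolar(38), 40.6, tolerance = 1e-3)
  expect_lt(gamma_lw_apolar(179.99), 1e-6)         # (1 + cos 180) -> 0
  expect_error(gamma_lw_apolar(38, default_liquids()$water), "apolar")
  expect_error(gamma_lw_apolar(-3), "\\[0, 180\\)")
})

test_that("inversion reproduces the benchmark glass and polycarbonate rows", {
  # hydrophilic borosilicate glass: both roots non-negative
  gs <- solve_components(25, 26, 38)
  expect_equal(gs$gamma_s, 50.9, tolerance = 0.5 / 50.9)
  expect_false(gs$root_neg_plus)
  expect_false(gs$root_neg_minus)
  expect_equal(delta_g_coh(gs$gamma_lw, gs$gamma_plus, gs$gamma_minus),
               30.4, tolerance = 0.5 / 30.4)
  # monopolar polycarbonate: acid root solves negative, magnitudes carried
  pc <- solve_components(78, 70, 26)
  expect_true(pc$root_neg_plus)
  expect_equal(pc$gamma_s, 57.1, tolerance = 0.5 / 57.1)
  expect_equal(delta_g_coh(pc$gamma_lw, pc$gamma_plus, pc$gamma_minus),
               -24.7, tolerance = 0.5 / 24.7)
})

test_that("result invariants hold on random and benchmark inputs", {
  ref <- reference_surfaces()
  comp <- solve_components(ref$theta_w, ref$theta_f, ref$theta_d)
  expect_true(all(comp$gamma_lw >= 0 & comp$gamma_plus >= 0 &
                    comp$gamma_minus >= 0))
  expect_equal(comp$gamma_ab, 2 * sqrt(comp$gamma_plus * comp$gamma_minus),
               tolerance = 1e-9)
  expect_equal(comp$gamma_s, comp$gamma_lw + comp$gamma_ab, tolerance = 1e-9)
})

test_that("benchmark table rows are reproduced within angle-rounding error", {
  # angles are printed to 1 degree; that rounding propagates to at most
  # ~2.5 mJ m^-2 in Delta G_coh (less in gamma_s and tau0)
  ref <- reference_surfaces()
  fit <- vocg(ref)
  expect_true(all(abs(fit$table$gamma_s - ref$gamma_s_ref) <= 2.5))
  expect_true(all(abs(fit$table$delta_g_coh - ref$dg_coh_ref) <= 2.5))
  expect_true(all(abs(fit$table$tau0 - ref$tau0_ref) <= 2.5))
})

test_that("noise-free forward/inverse round trip is the identity", {
  comp <- random_components(100, seed = 7)
  ang <- forward_angles(comp$gamma_lw, comp$gamma_plus, comp$gamma_minus)
  back <- solve_components(ang$water, ang$formamide, ang$diiodomethane)
  expect_equal(back$gamma_lw, comp$gamma_lw, tolerance = 1e-6)
  expect_equal(back$gamma_plus, comp$gamma_plus, tolerance = 1e-6)
  expect_equal(back$gamma_minus, comp$gamma_minus, tolerance = 1e-6)
  expect_false(any(back$root_neg_plus | back$root_neg_minus))
})

test_that("linear solve agrees with a nonlinear least-squares oracle", {
  skip_if_not_installed("minpack.lm")
  liq <- default_liquids()
  # parameterized by square roots so components stay non-negative without
  # clamping; the exact solution has zero residual
  resid_fun <- function(par, theta) {
    vapply(seq_along(liq), function(i) {
      L <- liq[[i]]
      L$gamma_total * (1 + cospi(theta[i] / 180)) -
        2 * (abs(par[1]) * sqrt(L$gamma_lw) +
               par[2]^2 * sqrt(L$gamma_minus) +
               par[3]^2 * sqrt(L$gamma_plus))
    }, numeric(1))
  }
  set.seed(11)
  comp <- random_components(20, seed = 11)
  ang <- forward_angles(comp$gamma_lw, comp$gamma_plus, comp$gamma_minus)
  for (i in seq_len(nrow(comp))) {
    theta <- c(ang$water[i], ang$formamide[i], ang$diiodomethane[i])
    direct <- solve_components(theta[1], theta[2], theta[3])
    start <- c(6, 1.5, 2) * runif(3, 0.7, 1.3)
    nls <- minpack.lm::nls.lm(
      par = start, fn = resid_fun, theta = theta,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
    expect_lt(sum(nls$fvec^2), 1e-12)
    expect_lt(abs(nls$par[1]^2 - direct$gamma_lw), 1e-4)
    expect_lt(abs(nls$par[2]^4 - direct$gamma_plus), 1e-4)
    expect_lt(abs(nls$par[3]^4 - direct$gamma_minus), 1e-4)
  }
})

test_that("cohesion energy is zero for a water-like solid and monotone in the donor parameter", {
  w <- default_liquids()$water
  expect_equal(delta_g_coh(w$gamma_lw, w$gamma_plus, w$gamma_minus), 0,
               tolerance = 1e-12)
  gm <- seq(60, 0, by = -5)
  dg <- delta_g_coh(40, 1, gm)
  expect_true(all(diff(dg) < 0)) # shrinking electron-donor => more hydrophobic
})

test_that("forward map rejects unphysical component sets", {
  expect_error(forward_angles(50, 200, 200), "unphysical")
  # self-wetting apolar solid and water-like solid wet completely
  expect_equal(unname(forward_angles(50.8, 0, 0)["diiodomethane"]), 0)
  w <- default_liquids()$water
  expect_equal(unname(forward_angles(w$gamma_lw, w$gamma_plus, w$gamma_minus,
                                     liquids = list(water = w))[["water"]]), 0)
})

test_that("vocg fit object exposes the classic modelling surface", {
  ref <- reference_surfaces()[1:4, ]
  fit <- vocg(ref)
  expect_s3_class(fit, "vocg")
  expect_identical(dim(coef(fit)), c(4L, 5L))
  expect_identical(rownames(coef(fit)), ref$surface_id)
  # residuals vanish where no negative root occurred
  res <- residuals(fit)
  clean <- !(fit$table$root_neg_plus | fit$table$root_neg_minus)
  expect_true(all(abs(res[clean, ]) < 1e-9))
  expect_true(all(rowSums(abs(res[!clean, , drop = FALSE]) > 1e-6) > 0))
  # predictions reproduce observed angles for clean surfaces
  pred <- suppressWarnings(predict(fit))
  expect_equal(pred$water[clean], fit$table$theta_w[clean], tolerance = 1e-6)
  expect_output(print(fit), "surface-energy fit")
  expect_output(print(summary(fit)), "Vogler threshold")
  expect_error(vocg(data.frame(theta_w = 10)), "lacks column")
  expect_error(vocg(data.frame(surface_id = c("a", "a"), theta_w = 1,
                               theta_f = 1, theta_d = 1)), "unique")
})

test_that("degenerate polar liquid pair is reported as singular", {
  liq <- default_liquids()
  liq$formamide <- probe_liquid("formamide", 72.8, 21.8, 25.5, 25.5)
  expect_error(solve_components(25, 26, 38, liq), "singular")
})
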