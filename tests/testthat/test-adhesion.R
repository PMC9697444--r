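test_that("control normalization is the ratio of areal densities", {
  expect_equal(relative_adhesion(3.0 * 18.75, 18.75, 3.0 * 18.75, 18.75), 100)
  expect_equal(relative_adhesion(4.5 * 18.75, 18.75, 3.0 * 18.75, 18.75), 150)
  expect_equal(relative_adhesion(0, 18.75, 56.25, 18.75), 0)
  # scale invariance in mass and in area
  set.seed(2)
  m <- runif(10, 10, 90)
  base <- relative_adhesion(m, 18.75, 56.25, 18.75)
  for (k in c(0.5, 3, 10)) {
    expect_equal(relative_adhesion(k * m, 18.75, k * 56.25, 18.75), base)
    expect_equal(relative_adhesion(m, k * 18.75, 56.25, k * 18.75), base)
  }
  expect_error(relative_adhesion(10, 18.75, 0, 18.75), "control")
})

test_that("ANOVA and LSD match the direct sums-of-squares oracle", {
  set.seed(5)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    n <- sample(3:6, 1)
    groups <- setNames(lapply(seq_len(k), function(j) rnorm(n, mean = j)),
                       paste0("T", seq_len(k)))
    res <- anova_lsd(groups)
    orc <- anova_oracle(groups)
    expect_equal(res$f, orc$f, tolerance = 1e-9)
    expect_equal(res$p, orc$p, tolerance = 1e-9)
    expect_equal(res$mse, orc$mse, tolerance = 1e-9)
    expect_equal(res$lsd,
                 qt(0.975, orc$df_error) * sqrt(2 * orc$mse / n),
                 tolerance = 1e-9)
  }
})

test_that("formula and list interfaces agree", {
  df <- data.frame(pct = c(99, 101, 100, 148, 152, 150),
                   surf = rep(c("GS", "PC"), each = 3))
  a <- anova_lsd(pct ~ surf, data = df)
  b <- anova_lsd(list(GS = c(99, 101, 100), PC = c(148, 152, 150)))
  expect_equal(a$f, b$f)
  expect_equal(a$means$letters, b$means$letters)
})

test_that("letter grouping separates what the LSD separates", {
  # identical treatments: F = 0, one shared letter
  same <- anova_lsd(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  expect_equal(same$f, 0)
  expect_identical(same$means$letters, c("a", "a"))
  # huge separation: distinct letters
  far <- anova_lsd(list(A = c(0, 0.1, -0.1), B = c(10, 10.1, 9.9)))
  expect_gt(far$f, 1000)
  expect_identical(far$means$letters, c("a", "b"))
  # A ~ B << C built so |A-B| < LSD < |B-C|
  three <- anova_lsd(list(A = c(-0.2, 0, 0.2), B = c(0.1, 0.3, 0.5),
                          C = c(9.8, 10, 10.2)))
  expect_identical(three$means$letters, c("a", "a", "b"))
})

test_that("letter display is consistent with all-pairs LSD comparisons", {
  set.seed(8)
  for (i in 1:40) {
    k <- sample(3:6, 1)
    groups <- setNames(lapply(seq_len(k), function(j)
      rnorm(4, mean = sample(c(0, 1, 2), 1), sd = 0.5)), paste0("T", seq_len(k)))
    res <- anova_lsd(groups)
    means <- res$means$mean
    lets <- strsplit(res$means$letters, "")
    for (a in seq_len(k - 1)) {
      for (b in seq((a + 1), k)) {
        share <- length(intersect(lets[[a]], lets[[b]])) > 0
        differ <- abs(means[a] - means[b]) >= res$lsd
        # share a letter iff not significantly different
        expect_identical(share, !differ)
      }
    }
  }
})

test_that("unbalanced designs use the harmonic mean group size", {
  groups <- list(A = c(1, 2, 3, 4, 5), B = c(4, 5, 6), C = c(8, 9, 10, 11))
  res <- anova_lsd(groups)
  orc <- anova_oracle(groups)
  n_h <- 3 / (1 / 5 + 1 / 3 + 1 / 4)
  expect_equal(res$lsd, qt(0.975, orc$df_error) * sqrt(2 * orc$mse / n_h),
               tolerance = 1e-9)
})

test_that("degenerate zero-variance input falls back to exact ties", {
  res <- anova_lsd(list(A = c(2, 2, 2), B = c(2, 2, 2), C = c(3, 3, 3)))
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
  expect_identical(res$means$letters, c("a", "a", "b"))
  expect_error(anova_lsd(list(A = 1, B = c(1, 2))), ">= 2 replicates")
  expect_error(anova_lsd(list(A = c(1, 2))), "at least 2 treatments")
})

test_that("adhesion_report normalizes against the configured control", {
  mats <- data.frame(material = c("GS", "PC", "PE"), ra_um = 0.05,
                     rel_density = c(1, 1.5, 0.6))
  dat <- synth_adhesion(mats, eps_types = "BSA", cv = 0.02, seed = 4)
  rep <- adhesion_report(dat, control = "GS_0.05")
  expect_named(rep, "BSA")
  m <- rep$BSA$means
  expect_equal(m$mean[m$treatment == "GS_0.05"], 100, tolerance = 0.05)
  expect_equal(m$mean[m$treatment == "PC_0.05"], 150, tolerance = 0.05)
  expect_false(any(strsplit(m$letters[m$treatment == "PC_0.05"], "")[[1]] %in%
                     strsplit(m$letters[m$treatment == "PE_0.05"], "")[[1]]))
  expect_error(adhesion_report(dat, control = "missing"), "control")
})
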