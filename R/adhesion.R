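#' Control-normalized EPS adhesion
#'
#' Expresses adhered exopolymeric-substance (EPS) mass per unit area as a
#' percentage of a control surface's areal density:
#' \deqn{\%\,\mathrm{adhered} = 100 \cdot
#'   \frac{m / A}{m_{ctrl} / A_{ctrl}}.}
#' In the benchmark assay the control is borosilicate glass with a BSA
#' adsorption capacity of 3.0 ug cm^-2 (defined as 100 %); the control is
#' a parameter here, not hard-coded to glass. The percentage is invariant
#' to rescaling all masses (or all areas) by a common factor.
#'
#' @param mass_ug Adhered mass on the test surface, ug, `>= 0`. Vectorized.
#' @param area_cm2 Test-surface area, cm^2, `> 0`.
#' @param control_mass_ug,control_area_cm2 Same quantities for the control
#'   surface; the control areal density must be strictly positive.
#' @return Percent adhesion relative to the control (100 = control level).
#' @examples
#' relative_adhesion(4.5 * 18.75, 18.75, 3.0 * 18.75, 18.75) # 150 %
#' @export
relative_adhesion <- function(mass_ug, area_cm2,
                              control_mass_ug, control_area_cm2) {
  stopifnot(all(mass_ug >= 0), all(area_cm2 > 0), control_area_cm2 > 0)
  control_density <- control_mass_ug / control_area_cm2
  if (!is.finite(control_density) || control_density <= 0) {
    stop("control areal density must be strictly positive")
  }
  100 * (mass_ug / area_cm2) / control_density
}

#' One-way ANOVA with Fisher-LSD compact-letter grouping
#'
#' Fits a one-way ANOVA (via [stats::aov()]) and groups treatments at the
#' 95 % (by default) level using Fisher's least significant difference:
#' \deqn{LSD = t_{1-\alpha/2,\,df_{err}} \sqrt{2\,MSE/n},}
#' with the harmonic mean of the group sizes standing in for \eqn{n} in
#' unbalanced designs. Treatments whose means differ by less than the LSD
#' share a letter; the compact-letter display is built with the
#' insert-and-absorb algorithm, so shared letters are transitively
#' consistent (overlapping letter sets, never contradictions) and
#' deterministic given the treatment order of the input.
#'
#' When every group has zero internal variance the F statistic is
#' undefined; `p` is returned as `NA`, `degenerate` is set, and letters
#' are assigned by exact equality of means.
#'
#' @param x Either a formula `response ~ treatment` (with `data`), or a
#'   named list of numeric replicate vectors, one per treatment.
#' @param data data.frame for the formula interface.
#' @param alpha Significance level for the LSD (default 0.05).
#' @return An object of class `"anova_lsd"`: list with `means` (data.frame
#'   `treatment`, `n`, `mean`, `sd`, `letters`), `f`, `p`, `df`, `mse`,
#'   `lsd`, `alpha`, `degenerate`.
#' @examples
#' anova_lsd(list(GS = c(99, 101, 100), PC = c(147, 152, 150)))
#' @export
anova_lsd <- function(x, data = NULL, alpha = 0.05) {
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data)
    values <- mf[[1L]]
    treatment <- as.character(mf[[2L]])
  } else if (is.list(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("treatment list must be fully named")
    }
    values <- unlist(x, use.names = FALSE)
    treatment <- rep(names(x), lengths(x))
  } else {
    stop("x must be a formula or a named list of replicate vectors")
  }
  stopifnot(is.numeric(values), alpha > 0, alpha < 1)
  levels_in_order <- unique(treatment)
  if (length(levels_in_order) < 2) stop("need at least 2 treatments")
  n_i <- table(factor(treatment, levels = levels_in_order))
  if (any(n_i < 2)) {
    stop("every treatment needs >= 2 replicates; offending: ",
         paste(names(n_i)[n_i < 2], collapse = ", "))
  }

  g <- factor(treatment, levels = levels_in_order)
  fit <- stats::aov(values ~ g)
  # degenerate (zero-MSE) fits are handled explicitly below; anova.lm's
  # perfect-fit warning is redundant here
  an <- suppressWarnings(stats::anova(fit))
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  means <- tapply(values, g, mean)
  sds <- tapply(values, g, stats::sd)

  degenerate <- mse < .Machine$double.eps^0.75 * max(1, mean(values)^2)
  if (degenerate) {
    f_stat <- if (an["g", "Mean Sq"] < .Machine$double.eps) 0 else Inf
    p_val <- NA_real_
    lsd <- 0
    # letters by exact tie of means
    sig <- outer(means, means, function(a, b) abs(a - b) > 0)
  } else {
    f_stat <- an["g", "F value"]
    p_val <- an["g", "Pr(>F)"]
    n_h <- length(n_i) / sum(1 / as.numeric(n_i)) # harmonic mean group size
    lsd <- stats::qt(1 - alpha / 2, df_err) * sqrt(2 * mse / n_h)
    sig <- outer(means, means, function(a, b) abs(a - b) >= lsd)
  }
  letters_vec <- compact_letters(sig)

  structure(list(
    means = data.frame(treatment = levels_in_order,
                       n = as.integer(n_i),
                       mean = as.numeric(means),
                       sd = as.numeric(sds),
                       letters = letters_vec,
                       row.names = NULL),
    f = unname(f_stat), p = unname(p_val),
    df = c(treatment = unname(an["g", "Df"]), error = df_err),
    mse = mse, lsd = lsd, alpha = alpha, degenerate = degenerate),
    class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA with Fisher LSD grouping (alpha = %g)\n", x$alpha))
  if (x$degenerate) {
    cat("  zero within-group variance: p undefined, letters by exact ties\n")
  } else {
    cat(sprintf("  F(%d, %d) = %.4g, p = %.4g, LSD = %.4g\n",
                x$df[["treatment"]], x$df[["error"]], x$f, x$p, x$lsd))
  }
  print(format(x$means, digits = digits), row.names = FALSE)
  invisible(x)
}

# Compact-letter display by insert-and-absorb from a logical
# "significantly different" matrix (symmetric, FALSE diagonal).
# Deterministic: pairs processed in row-major order, columns labelled in
# order of their first member.
compact_letters <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k)) # start: everyone shares one letter
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!sig[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  out <- vapply(seq_len(k), function(t) {
    paste(letters[which(vapply(cols, function(col) t %in% col, logical(1)))],
          collapse = "")
  }, character(1))
  names(out) <- rownames(sig)
  out
}

#' Adhesion summary: control normalization plus LSD grouping
#'
#' Convenience wrapper for a replicate adhesion table: normalizes every
#' record against the control surface's mean areal density
#' ([relative_adhesion()]) and groups treatments by [anova_lsd()] on the
#' percentages, separately per EPS type.
#'
#' @param data data.frame as from [read_adhesion_table()] or
#'   [synth_adhesion()]: columns `surface_id`, `material`, `ra_um`,
#'   `eps_type`, `mass_ug`, `area_cm2`, `replicate`.
#' @param control Value of `surface_id` identifying the control surface
#'   (normalized to 100 %).
#' @param alpha Significance level passed to [anova_lsd()].
#' @return Named list, one [anova_lsd()] result per `eps_type`, each with
#'   an extra `pct` element (the per-record percentages).
#' @export
adhesion_report <- function(data, control, alpha = 0.05) {
  need <- c("surface_id", "eps_type", "mass_ug", "area_cm2", "replicate")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("adhesion table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!control %in% data$surface_id) {
    stop("control surface '", control, "' not present in the table")
  }
  out <- lapply(split(data, data$eps_type), function(g) {
    ctrl <- g[g$surface_id == control, , drop = FALSE]
    if (nrow(ctrl) == 0) {
      stop("control surface '", control, "' has no rows for eps_type '",
           g$eps_type[1], "'")
    }
    pct <- relative_adhesion(g$mass_ug, g$area_cm2,
                             control_mass_ug = mean(ctrl$mass_ug),
                             control_area_cm2 = mean(ctrl$area_cm2))
    res <- anova_lsd(split(pct, factor(g$surface_id, levels = unique(g$surface_id))),
                     alpha = alpha)
    res$pct <- data.frame(surface_id = g$surface_id,
                          replicate = g$replicate, pct = pct)
    res
  })
  out
}
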