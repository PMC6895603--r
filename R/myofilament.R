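#' Force-pCa dataset for skinned-strip sensitivity analysis
#'
#' Bundles force measurements over a pCa ladder (pCa = -log10 of free
#' [Ca2+]) with the strip geometry used for cross-sectional-area
#' normalization.
#'
#' @param pCa numeric vector of pCa values; at least 4 distinct values
#'   spanning at least 1 pCa unit.
#' @param force_mN nonnegative forces (mN), same length as \code{pCa}.
#' @param radius_mm optional strip radius (mm) for CSA normalization.
#' @param group optional group label.
#' @return Object of class \code{force_pca} (a data frame with
#'   attributes).
#' @export
force_pca_dataset <- function(pCa, force_mN, radius_mm = NULL,
                              group = "strip") {
  stopifnot(is.numeric(pCa), is.numeric(force_mN),
            length(pCa) == length(force_mN))
  if (any(force_mN < 0)) stop("forces must be >= 0", call. = FALSE)
  if (length(unique(pCa)) < 4)
    stop("need at least 4 distinct pCa points", call. = FALSE)
  if (diff(range(pCa)) < 1)
    stop("pCa range must span at least 1 unit", call. = FALSE)
  structure(data.frame(pCa = pCa, force_mN = force_mN),
            class = c("force_pca", "data.frame"),
            radius_mm = radius_mm, group = group)
}

#' Cross-sectional area of a skinned muscle strip
#'
#' The default formula is \code{2 * pi * r^2}, reproducing the published
#' convention this package follows for comparability; \code{"circle"}
#' gives the plain circle area \code{pi * r^2} (exactly half). The
#' factor-of-two discrepancy between the two is intentional and
#' documented: choose \code{"circle"} for a geometrically conventional
#' area.
#'
#' @param radius_mm strip radius (mm), positive.
#' @param formula \code{"paper_2pir2"} (default) or \code{"circle_pir2"}.
#' @return CSA in mm^2.
#' @examples
#' csa_area(0.2)            # 2*pi*0.04 = 0.2513
#' csa_area(0.2, "circle_pir2")  # half of that
#' @export
csa_area <- function(radius_mm, formula = c("paper_2pir2",
                                            "circle_pir2")) {
  formula <- match.arg(formula)
  if (any(!is.finite(radius_mm)) || any(radius_mm <= 0))
    stop("radius must be > 0", call. = FALSE)
  switch(formula,
         paper_2pir2 = 2 * pi * radius_mm^2,
         circle_pir2 = pi * radius_mm^2)
}

#' Normalize force by cross-sectional area
#'
#' @param force_mN force (mN).
#' @param radius_mm strip radius (mm).
#' @inheritParams csa_area
#' @return Stress (mN/mm^2).
#' @export
normalize_force_csa <- function(force_mN, radius_mm,
                                formula = c("paper_2pir2",
                                            "circle_pir2")) {
  force_mN / csa_area(radius_mm, match.arg(formula))
}

# Hill model in pCa space: F = Fmax / (1 + 10^(nH * (pCa - pCa50))).
# Identical to Fmax * C^nH / (C^nH + C50^nH) with C = 10^(-pCa).
.hill_pca <- function(pCa, Fmax, pCa50, nH) {
  Fmax / (1 + 10^(nH * (pCa - pCa50)))
}

# Deterministic multi-start least-squares fit of the Hill model.
# start grid: pCa50 in {5.0, 5.5, 6.0} x nH in {1, 2, 4}; Fmax = max(F).
.hill_fit_engine <- function(pCa, force, fix = NULL) {
  best <- NULL
  f0 <- max(force)
  dat <- data.frame(pCa = pCa, force = force)
  for (p50 in c(5.0, 5.5, 6.0)) {
    for (nh in c(1, 2, 4)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          force ~ Fmax / (1 + 10^(nH * (pCa - pCa50))),
          data = dat,
          start = list(Fmax = f0, pCa50 = p50, nH = nh),
          lower = c(Fmax = 1e-12, pCa50 = min(pCa) - 2, nH = 0.05),
          upper = c(Fmax = 100 * f0 + 1, pCa50 = max(pCa) + 2, nH = 25),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best))
    stop("Hill fit did not converge from any start", call. = FALSE)
  best
}

#' Fit a Hill equation to force-pCa data
#'
#' Least-squares fit of \eqn{F = Fmax \cdot C^{nH} / (C^{nH} +
#' C_{50}^{nH})} with \eqn{C = 10^{-pCa}}, parameterized by the maximal
#' force \code{Fmax}, the myofilament Ca2+ sensitivity \code{pCa50} (pCa
#' at half-maximal force) and the Hill coefficient \code{nH}
#' (cooperativity). Initialization uses a deterministic multi-start grid
#' to avoid local minima.
#'
#' @param data a \code{\link{force_pca_dataset}}, or a data frame with
#'   columns \code{pCa} and \code{force_mN} (or \code{force}).
#' @return Object of class \code{hill_fit}: list with \code{Fmax},
#'   \code{pCa50}, \code{nH}, \code{rss}, \code{df_residual},
#'   \code{fitted}, \code{data}.
#' @examples
#' d <- gen_force_pca(pca_config(noise_sd = 0))
#' coef(hill_fit(d$data))
#' @export
hill_fit <- function(data) {
  force <- if (!is.null(data$force_mN)) data$force_mN else data$force
  pCa <- data$pCa
  stopifnot(is.numeric(pCa), is.numeric(force))
  best <- .hill_fit_engine(pCa, force)
  cf <- stats::coef(best$fit)
  structure(list(Fmax = unname(cf["Fmax"]), pCa50 = unname(cf["pCa50"]),
                 nH = unname(cf["nH"]), rss = best$rss,
                 df_residual = length(force) - 3L,
                 fitted = stats::fitted(best$fit),
                 data = data.frame(pCa = pCa, force = force)),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(Fmax = object$Fmax, pCa50 = object$pCa50, nH = object$nH)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> force-pCa Hill equation\n")
  cat(sprintf("  Fmax %.4g  pCa50 %.4f  nH %.3f  (RSS %.4g, df %d)\n",
              x$Fmax, x$pCa50, x$nH, x$rss, x$df_residual))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  pCa <- if (is.null(newdata)) object$data$pCa else newdata$pCa
  .hill_pca(pCa, object$Fmax, object$pCa50, object$nH)
}

#' @export
plot.hill_fit <- function(x, ...) {
  ord <- order(x$data$pCa, decreasing = TRUE)
  graphics::plot(x$data$pCa[ord], x$data$force[ord], xlim =
                   rev(range(x$data$pCa)), xlab = "pCa",
                 ylab = "force", ...)
  pp <- seq(max(x$data$pCa), min(x$data$pCa), length.out = 200)
  graphics::lines(pp, .hill_pca(pp, x$Fmax, x$pCa50, x$nH))
  invisible(x)
}

# Joint fit under the null: shared (pCa50, nH), group-specific Fmax.
.hill_fit_shared <- function(pCaA, forceA, pCaB, forceB) {
  dat <- data.frame(pCa = c(pCaA, pCaB),
                    force = c(forceA, forceB),
                    gB = rep(c(0, 1), c(length(pCaA), length(pCaB))))
  best <- NULL
  fA0 <- max(forceA); fB0 <- max(forceB)
  for (p50 in c(5.0, 5.5, 6.0)) {
    for (nh in c(1, 2, 4)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          force ~ (FmaxA * (1 - gB) + FmaxB * gB) /
            (1 + 10^(nH * (pCa - pCa50))),
          data = dat,
          start = list(FmaxA = fA0, FmaxB = fB0, pCa50 = p50, nH = nh),
          lower = c(1e-12, 1e-12, min(dat$pCa) - 2, 0.05),
          upper = c(100 * fA0 + 1, 100 * fB0 + 1, max(dat$pCa) + 2, 25),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best))
    stop("shared Hill fit did not converge", call. = FALSE)
  best
}

# Fully shared null (one Fmax, pCa50, nH for both groups).
.hill_fit_pooled <- function(pCa, force) {
  .hill_fit_engine(pCa, force)
}

#' Compare two force-pCa curves by extra sum-of-squares F-test
#'
#' Tests whether two groups share the same myofilament Ca2+ sensitivity.
#' Under the default null model (\code{null = "sensitivity"}), the groups
#' share (pCa50, nH) but keep separate maximal forces, so the test is
#' specific to a sensitivity shift; \code{null = "all"} shares all three
#' parameters. The alternative fits each group separately. The statistic
#' is \eqn{F = ((SS_0 - SS_1)/(df_0 - df_1)) / (SS_1/df_1)} with the
#' p-value from the F distribution.
#'
#' @param groupA,groupB \code{\link{force_pca_dataset}}s or data frames
#'   with \code{pCa} and \code{force_mN}/\code{force} columns.
#' @param null which parameters are shared under the null:
#'   \code{"sensitivity"} (shared pCa50 and nH) or \code{"all"}.
#' @return Object of class \code{force_pca_test}: list with \code{F},
#'   \code{df1}, \code{df2}, \code{p_value}, \code{fitA}, \code{fitB},
#'   \code{rss_null}, \code{rss_alt}, \code{null}.
#' @export
compare_curves_f_test <- function(groupA, groupB,
                                  null = c("sensitivity", "all")) {
  null <- match.arg(null)
  fA <- if (!is.null(groupA$force_mN)) groupA$force_mN else groupA$force
  fB <- if (!is.null(groupB$force_mN)) groupB$force_mN else groupB$force
  pA <- groupA$pCa; pB <- groupB$pCa

  fitA <- hill_fit(data.frame(pCa = pA, force = fA))
  fitB <- hill_fit(data.frame(pCa = pB, force = fB))
  rss_alt <- fitA$rss + fitB$rss
  n <- length(fA) + length(fB)
  df_alt <- n - 6L

  if (null == "sensitivity") {
    nullfit <- .hill_fit_shared(pA, fA, pB, fB)
    df_null <- n - 4L
  } else {
    nullfit <- .hill_fit_pooled(c(pA, pB), c(fA, fB))
    df_null <- n - 3L
  }
  rss_null <- nullfit$rss
  if (rss_alt > rss_null) {
    # separate fits must do at least as well; keep the better of the two
    rss_alt <- min(rss_alt, rss_null)
  }
  df1 <- df_null - df_alt
  Fstat <- ((rss_null - rss_alt) / df1) / (rss_alt / df_alt)
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, df1, df_alt, lower.tail = FALSE)
  structure(list(F = Fstat, df1 = df1, df2 = df_alt, p_value = p,
                 fitA = fitA, fitB = fitB, rss_null = rss_null,
                 rss_alt = rss_alt, null = null),
            class = "force_pca_test")
}

#' @export
print.force_pca_test <- function(x, ...) {
  cat("<force_pca_test> extra sum-of-squares F-test (null:", x$null,
      ")\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df1, x$df2, x$F,
              x$p_value))
  cat(sprintf("  pCa50: %.4f vs %.4f   nH: %.3f vs %.3f\n",
              x$fitA$pCa50, x$fitB$pCa50, x$fitA$nH, x$fitB$nH))
  invisible(x)
}
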