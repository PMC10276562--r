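#' Predict the density surface on a regular grid
#'
#' Evaluates the fitted density surface model on square cells (default
#' 200 m) laid over the region bounding box from its south-west corner,
#' keeping cells whose centre falls inside the region.  Density is
#' reported in birds per hectare (offset excluded: prediction per unit
#' area); the SE is by the delta method,
#' \eqn{\mathrm{SE} = \hat D \sqrt{x^T V_\beta x}}.
#'
#' @param fit a [fit_dsm()] result.
#' @param region a [region()] (defaults to the soap smoother's region).
#' @param cell cell side, metres.
#' @return A data.frame of class `prediction_grid` with columns `x`, `y`,
#'   `density_ha`, `se_ha`; attributes `cell` (m), `cell_area_ha`,
#'   `n_outside` (count of candidate cells dropped), `region`.
#' @export
predict_surface <- function(fit, region = NULL, cell = 200) {
  stopifnot(inherits(fit, "dsm"), cell > 0)
  if (is.null(region)) region <- fit$smoother$region
  if (!inherits(region, "region"))
    stop("a region is required (tprs fits do not carry one)")
  bb <- apply(region$outer, 2, range)
  cx <- seq(bb[1, 1] + cell / 2, bb[2, 1], by = cell)
  cy <- seq(bb[1, 2] + cell / 2, bb[2, 2], by = cell)
  g <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  ins <- point_in_region(region, g$x, g$y)
  n_outside <- sum(!ins)
  g <- g[ins, , drop = FALSE]
  pr <- predict(fit, newdata = g, type = "density", se.fit = TRUE)
  keep <- is.finite(pr$fit)
  dropped_na <- sum(!keep)  # soap: inside per our convention but outside mgcv's PDE grid
  out <- data.frame(x = g$x[keep], y = g$y[keep],
                    density_ha = pr$fit[keep], se_ha = pr$se.fit[keep])
  rownames(out) <- NULL
  structure(out, cell = cell, cell_area_ha = cell^2 / 1e4,
            n_outside = n_outside, n_na = dropped_na, region = region,
            class = c("prediction_grid", "data.frame"))
}

#' @export
plot.prediction_grid <- function(x, what = c("density", "se"), ...) {
  what <- match.arg(what)
  z <- if (what == "density") x$density_ha else x$se_ha
  pal <- grDevices::hcl.colors(64, "viridis")
  zi <- cut(z, breaks = 64, labels = FALSE, include.lowest = TRUE)
  cell <- attr(x, "cell")
  graphics::plot(x$x, x$y, asp = 1, pch = 15, col = pal[zi],
                 cex = 0.6, xlab = "easting (m)", ylab = "northing (m)",
                 main = paste0(what, " (birds/ha)"), ...)
  region <- attr(x, "region")
  if (!is.null(region)) {
    o <- region$outer
    graphics::polygon(o[, 1], o[, 2], border = "black")
  }
  invisible(x)
}

#' Predicted density along the region boundary
#'
#' Evaluates the fitted model at `m` even arc-length positions along the
#' outer boundary.  For the soap smoother the interior film is zero on
#' the boundary by construction, so the profile is the cyclic boundary
#' smooth (plus intercept) alone; for TPRS the full smooth is evaluated
#' at the boundary coordinates.  Evaluation uses points nudged a small
#' distance inside the region so the soap PDE grid has support.
#'
#' @param fit a `dsm` fit.
#' @param region region whose boundary to profile (defaults to the soap
#'   region).
#' @param m number of profile positions.
#' @return data.frame of class `boundary_profile` with columns `s`
#'   (arc-length, metres), `x`, `y`, `density_ha`; attribute `L`.
#' @export
boundary_profile <- function(fit, region = NULL, m = 200) {
  stopifnot(inherits(fit, "dsm"))
  if (is.null(region)) region <- fit$smoother$region
  if (!inherits(region, "region")) stop("a region is required")
  path <- parameterize_boundary(region, m)
  pts <- nudge_inward(region, path[, c("x", "y")])
  pts$off <- 0
  if (fit$smoother$type == "soap") {
    X <- stats::predict(fit$engine, newdata = pts, type = "lpmatrix")
    ## zero the film columns: on the boundary the film is exactly 0
    film <- which(vapply(fit$engine$smooth, function(sm) grepl("^sw", class(sm)[1]), TRUE))
    for (i in film) {
      sm <- fit$engine$smooth[[i]]
      X[, sm$first.para:sm$last.para] <- 0
    }
    eta <- drop(X %*% stats::coef(fit$engine))
  } else {
    eta <- predict(fit, newdata = pts, type = "link")
  }
  out <- data.frame(s = path$s, x = path$x, y = path$y,
                    density_ha = exp(eta) * 1e4)
  structure(out, L = attr(path, "L"),
            class = c("boundary_profile", "data.frame"))
}

#' Roughness of a boundary profile
#'
#' Sum of squared successive differences of the profile densities,
#' treated cyclically.  Leakage by a boundary-ignorant smoother shows up
#' as a rougher profile.
#'
#' @param profile a [boundary_profile()] result.
#' @export
profile_roughness <- function(profile) {
  d <- profile$density_ha
  sum(diff(c(d, d[1]))^2)
}

#' Posterior-simulation abundance from a density surface model
#'
#' Draws `n_sims` coefficient vectors from the Gaussian posterior
#' \eqn{N(\hat\beta, V_\beta)}, computes abundance
#' \eqn{N^{(s)} = \sum_{cells} \exp(x_{cell}^T \beta^{(s)})\,a_{cell}}
#' for each, and reports the mean, SD, and 2.5/97.5 percentile interval.
#' Detection-function uncertainty is not propagated by default (the
#' detection probability carries no spatial variability); set
#' `propagate_detection_cv` to add a detection CV in quadrature to the
#' interval on the log scale.
#'
#' @param fit a `dsm` fit.
#' @param grid a [predict_surface()] grid.
#' @param n_sims number of posterior draws (>= 100).
#' @param seed integer seed for reproducibility.
#' @param propagate_detection_cv optional CV of the detection probability
#'   to fold into the interval (default `NULL`, off).
#' @return An [abundance_estimate()] with `method` `"soap"` or `"tprs"`.
#' @export
posterior_abundance <- function(fit, grid, n_sims = 10000, seed = NULL,
                                propagate_detection_cv = NULL) {
  stopifnot(inherits(fit, "dsm"), inherits(grid, "prediction_grid"), n_sims >= 100)
  if (!is.null(seed)) set.seed(seed)
  cell_area_ha <- attr(grid, "cell_area_ha")
  nd <- data.frame(x = grid$x, y = grid$y, off = 0)
  X <- stats::predict(fit$engine, newdata = nd, type = "lpmatrix")
  beta <- stats::coef(fit$engine)
  V <- fit$engine$Vp
  B <- draw_mvn(n_sims, beta, V)
  ## per-draw abundance: sum over cells of density * area
  eta <- X %*% t(B)                      # cells x sims
  Ns <- colSums(exp(eta) * 1e4) * cell_area_ha
  N <- mean(Ns)
  se <- stats::sd(Ns)
  ci <- stats::quantile(Ns, c(0.025, 0.975), names = FALSE)
  if (!is.null(propagate_detection_cv)) {
    cv <- sqrt((se / N)^2 + propagate_detection_cv^2)
    se <- cv * N
    C <- exp(1.96 * sqrt(log(1 + cv^2)))
    ci <- c(N / C, N * C)
  }
  abundance_estimate(method = switch(fit$smoother$type, soap = "soap",
                                     tprs = "tprs", "model"),
                     N = N, se = se, lcl = ci[1], ucl = ci[2],
                     n_sims = n_sims, seed = seed)
}

#' Plug-in abundance from a prediction grid
#'
#' The degenerate (zero-covariance) path: abundance is the sum of cell
#' density times cell area, exactly conserving the predicted surface.
#'
#' @param grid a [predict_surface()] grid.
#' @return Abundance in birds.
#' @export
plugin_abundance <- function(grid) {
  stopifnot(inherits(grid, "prediction_grid"))
  sum(grid$density_ha) * attr(grid, "cell_area_ha")
}

#' Design-based (conventional distance sampling) abundance
#'
#' Encounter-rate estimator for point transects:
#' \eqn{\hat D = \sum_k n_k / (K \hat\nu)} (converted to birds per
#' hectare), \eqn{\hat N = \hat D \times A}.  The abundance CV combines
#' the empirical between-point encounter-rate variance with the detection
#' probability CV in quadrature, and the 95% CI is lognormal,
#' \eqn{\hat N \cdot C^{\pm 1}} with
#' \eqn{C = \exp(1.96 \sqrt{\ln(1 + CV^2)})}.
#'
#' @param counts per-point counts within the truncation distance (length
#'   K >= 2), e.g. from [counts_per_point()].
#' @param detfun a [fit_detection()] result (supplies `nu`, `p_a`,
#'   `se_p_a`).
#' @param area_ha region area in hectares.
#' @return An [abundance_estimate()] with `method = "distance"` and an
#'   extra `density_ha` element.
#' @export
design_based_abundance <- function(counts, detfun, area_ha) {
  stopifnot(inherits(detfun, "detfun"), length(counts) >= 2, area_ha > 0)
  if (detfun$nu <= 0) stop("effective area must be positive")
  K <- length(counts)
  nbar <- mean(counts)
  D <- nbar / detfun$nu * 1e4            # birds per ha
  N <- D * area_ha
  cv2_er <- if (nbar > 0) stats::var(counts) / K / nbar^2 else 0
  cv2_p <- if (is.finite(detfun$se_p_a)) (detfun$se_p_a / detfun$p_a)^2 else 0
  cv <- sqrt(cv2_er + cv2_p)
  if (cv > 0) {
    C <- exp(1.96 * sqrt(log(1 + cv^2)))
    lcl <- N / C; ucl <- N * C
  } else {
    lcl <- ucl <- N
  }
  est <- abundance_estimate(method = "distance", N = N, se = cv * N,
                            lcl = lcl, ucl = ucl)
  est$density_ha <- D
  est
}

#' Abundance estimate container
#'
#' @param method `"soap"`, `"tprs"` or `"distance"`.
#' @param N point estimate (birds).
#' @param se standard error (birds).
#' @param lcl,ucl 95% confidence limits (birds).
#' @param n_sims,seed posterior-simulation bookkeeping (model-based only).
#' @return A list of class `abundance_estimate` with `cv = se / N`.
#' @export
abundance_estimate <- function(method, N, se, lcl, ucl, n_sims = NULL, seed = NULL) {
  stopifnot(N >= 0, se >= 0, lcl <= N + 1e-9, N <= ucl + 1e-9)
  structure(list(method = method, N = N, se = se,
                 cv = if (N > 0) se / N else NA_real_,
                 lcl = lcl, ucl = ucl, n_sims = n_sims, seed = seed),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("%-8s N = %s  SE = %.2f  CV = %.3f  95%% CI (%s, %s)\n",
              x$method,
              format(round(x$N), big.mark = ","), x$se, x$cv,
              format(round(x$lcl), big.mark = ","),
              format(round(x$ucl), big.mark = ",")))
  invisible(x)
}

#' Coefficient of variation of an abundance estimate
#'
#' @param estimate an [abundance_estimate()].
#' @return `se / N`.
#' @export
cv_of <- function(estimate) {
  stopifnot(inherits(estimate, "abundance_estimate"))
  if (estimate$N == 0) stop("N is zero; CV undefined")
  estimate$se / estimate$N
}

#' Percentage change in confidence-interval width
#'
#' \eqn{(\mathrm{CIW}_b / \mathrm{CIW}_a - 1) \times 100}, with `a` the
#' reference estimator (the soap model in the headline comparison): a
#' negative value means `b`'s interval is narrower than the reference's.
#'
#' @param a reference [abundance_estimate()].
#' @param b comparison [abundance_estimate()].
#' @return List of class `ciw_comparison`: `ciw_change_pct`, `pair`.
#' @export
ciw_change <- function(a, b) {
  stopifnot(inherits(a, "abundance_estimate"), inherits(b, "abundance_estimate"))
  wa <- a$ucl - a$lcl
  wb <- b$ucl - b$lcl
  if (!(wa > 0)) stop("reference interval has zero width")
  structure(list(ciw_change_pct = (wb / wa - 1) * 100,
                 pair = c(a$method, b$method)),
            class = "ciw_comparison")
}

#' @export
print.ciw_comparison <- function(x, ...) {
  cat(sprintf("CIW change %s -> %s: %+.1f%%\n",
              x$pair[1], x$pair[2], x$ciw_change_pct))
  invisible(x)
}
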