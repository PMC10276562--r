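#' Fit a density surface model to point-transect counts
#'
#' Fits the stage-two count model
#' \deqn{\log E(n_k) = f(x_k, y_k) + \log \hat\nu_k}
#' where \eqn{n_k} is the bird count at point \eqn{k}, \eqn{f} is a
#' spatial smooth (soap film or thin plate regression spline, see
#' [smoother_spec()]) and \eqn{\hat\nu_k} is the effective area searched
#' (square metres) from the stage-one detection function, entering as an
#' offset.  The response is Poisson or negative binomial
#' (\eqn{Var = \mu + \mu^2/\theta}) with a log link; smoothing parameters
#' (and the NB dispersion \eqn{\theta}) are estimated by restricted
#' maximum likelihood via a penalized IRLS inner loop and a Laplace
#' restricted-marginal-likelihood outer loop.
#'
#' The returned object carries the coefficient vector, the Bayesian
#' posterior covariance of the coefficients (used for posterior simulation
#' of abundance), per-term effective degrees of freedom and the deviance
#' explained.
#'
#' @param counts non-negative integer counts, one per survey point.
#' @param coords data.frame with columns `x`, `y` (metres), one row per
#'   point.
#' @param nu effective area per point in square metres (scalar or vector),
#'   e.g. `fit$nu` from [fit_detection()].
#' @param smoother a [smoother_spec()], or `NULL` for an intercept-only
#'   model (no spatial smooth; useful as a null/reference fit).
#' @param family `"nb"` (negative binomial, dispersion estimated) or
#'   `"poisson"`.
#' @param sp optional fixed smoothing parameters (one per penalty; `NULL`
#'   to estimate by REML).
#' @param theta optional fixed NB dispersion (bypasses estimation).
#' @return An object of class `dsm`: list with the fitted `gam` engine
#'   object, `smoother`, `family`, `theta`, `edf` (per term), `counts`,
#'   `coords`, `nu`.
#' @seealso [predict_surface()], [posterior_abundance()],
#'   [deviance_explained()], [residual_refit_check()],
#'   [basis_adequacy_index()]
#' @export
fit_dsm <- function(counts, coords, nu, smoother, family = c("nb", "poisson"),
                    sp = NULL, theta = NULL) {
  family <- match.arg(family)
  if (!is.null(smoother)) stopifnot(inherits(smoother, "smoother_spec"))
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y") %in% names(coords)), nrow(coords) == length(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (all(counts == 0)) stop("all counts are zero: degenerate model")
  if (nrow(unique(coords[, c("x", "y")])) < 2)
    stop("need at least 2 distinct point locations")
  nu <- rep_len(nu, length(counts))
  if (any(nu <= 0)) stop("effective areas must be positive")

  dat <- data.frame(count = as.integer(counts), x = coords$x, y = coords$y,
                    off = log(nu))
  fam <- if (family == "poisson") stats::poisson(link = "log")
         else if (!is.null(theta)) mgcv::negbin(theta = theta, link = "log")
         else mgcv::nb(link = "log")

  spec <- if (is.null(smoother)) structure(list(type = "none"), class = "smoother_spec")
          else smoother
  knots <- NULL
  if (spec$type == "none") {
    fml <- count ~ 1 + offset(off)
  } else if (spec$type == "soap") {
    bad <- !point_in_region(spec$region, dat$x, dat$y)
    if (any(bad))
      stop("survey points outside the region: rows ",
           paste(utils::head(which(bad), 10), collapse = ", "))
    spec_xt <- soap_xt(spec)
    knots <- prune_soap_knots(spec, dat)
    fml <- count ~ s(x, y, bs = "sf", k = KB, xt = XT) +
      s(x, y, bs = "sw", xt = XT) + offset(off)
    fml <- eval(call("substitute", fml,
                     list(KB = spec$k_boundary, XT = quote(spec_xt))))
  } else {
    fml <- count ~ s(x, y, bs = "tp", k = KK) + offset(off)
    fml <- eval(call("substitute", fml, list(KK = spec$k)))
  }
  environment(fml) <- environment()

  g <- mgcv::gam(fml, data = dat, knots = knots, family = fam,
                 method = "REML", sp = sp)

  theta_hat <- if (family == "nb" && is.null(theta)) g$family$getTheta(TRUE)
               else theta
  edf <- per_term_edf(g)
  out <- list(
    engine = g, smoother = spec, family = family, theta = theta_hat,
    edf = edf, counts = dat$count, coords = dat[, c("x", "y")], nu = nu,
    knots = knots
  )
  class(out) <- "dsm"
  out
}

per_term_edf <- function(g) {
  if (!length(g$smooth)) return(numeric(0))
  e <- vapply(g$smooth, function(sm) sum(g$edf[sm$first.para:sm$last.para]), 0)
  lab <- vapply(g$smooth, function(sm) {
    cls <- class(sm)[1]
    if (grepl("^sf", cls)) "boundary"
    else if (grepl("^sw", cls)) "film"
    else if (grepl("tprs", cls)) "tprs"
    else sm$label
  }, "")
  names(e) <- make.unique(lab)
  e
}

#' @export
print.dsm <- function(x, ...) {
  cat("Density surface model (",
      switch(x$smoother$type, soap = "soap film smoother",
             tprs = "TPRS smoother", "intercept only"),
      "), family: ",
      if (x$family == "nb") sprintf("negative binomial (theta = %.2f)", x$theta)
      else "Poisson", "\n", sep = "")
  cat("  n points:", length(x$counts),
      " total count:", sum(x$counts), "\n")
  free <- vapply(x$engine$smooth, function(sm) as.integer(sm$last.para - sm$first.para + 1), 0L)
  for (i in seq_along(x$edf))
    cat(sprintf("  %-9s EDF %6.2f of %d\n", names(x$edf)[i], x$edf[i], free[i]))
  cat(sprintf("  deviance explained: %.1f%%\n", 100 * deviance_explained(x)))
  invisible(x)
}

#' @export
summary.dsm <- function(object, ...) {
  s <- summary(object$engine)
  out <- list(dsm = object, engine_summary = s,
              deviance_explained = deviance_explained(object),
              k_index = basis_adequacy_index(object))
  class(out) <- "summary.dsm"
  out
}

#' @export
print.summary.dsm <- function(x, ...) {
  print(x$dsm)
  cat(sprintf("  basis adequacy index: %.2f\n", x$k_index))
  invisible(x)
}

#' @export
coef.dsm <- function(object, ...) stats::coef(object$engine)

#' Bayesian posterior covariance of the DSM coefficients
#'
#' The inverse of the penalized information at convergence, i.e. the
#' covariance of the Gaussian posterior approximation used for
#' posterior-simulation abundance intervals.
#'
#' @param object a `dsm` fit.
#' @param ... unused.
#' @export
vcov.dsm <- function(object, ...) object$engine$Vp

#' @export
logLik.dsm <- function(object, ...) stats::logLik(object$engine)

#' @export
AIC.dsm <- function(object, ..., k = 2) stats::AIC(object$engine, k = k)

#' @export
residuals.dsm <- function(object, type = "deviance", ...) {
  stats::residuals(object$engine, type = type)
}

#' @export
fitted.dsm <- function(object, ...) stats::fitted(object$engine)

#' Predict from a density surface model
#'
#' Link-scale or response-scale prediction at new locations.  With
#' `type = "density"` the offset is excluded and the prediction is
#' converted to birds per hectare.  Soap-film predictions outside the
#' region are `NA`.
#'
#' @param object a `dsm` fit.
#' @param newdata data.frame with columns `x`, `y`.
#' @param type `"density"` (birds per hectare, no offset), `"link"`
#'   (linear predictor without offset), or `"lpmatrix"`.
#' @param se.fit also return standard errors (delta method on the density
#'   scale).
#' @param ... unused.
#' @export
predict.dsm <- function(object, newdata, type = c("density", "link", "lpmatrix"),
                        se.fit = FALSE, ...) {
  type <- match.arg(type)
  nd <- as.data.frame(newdata)
  nd$off <- 0
  if (type == "lpmatrix")
    return(stats::predict(object$engine, newdata = nd, type = "lpmatrix"))
  eta <- stats::predict(object$engine, newdata = nd, type = "link")
  if (type == "link") return(drop(eta))
  dens <- exp(drop(eta)) * 1e4   # birds m^-2 -> birds ha^-1
  if (!se.fit) return(dens)
  X <- stats::predict(object$engine, newdata = nd, type = "lpmatrix")
  se_link <- sqrt(pmax(0, rowSums((X %*% object$engine$Vp) * X)))
  list(fit = dens, se.fit = dens * se_link)
}

#' @export
plot.dsm <- function(x, cell = 200, ...) {
  if (x$smoother$type == "soap") {
    grid <- predict_surface(x, region = x$smoother$region, cell = cell)
  } else {
    stop("plot.dsm requires a region; use predict_surface() + your own plotting for tprs")
  }
  plot(grid, ...)
  invisible(x)
}

#' Simulate from the coefficient posterior of a DSM
#'
#' Draws coefficient vectors from the multivariate normal posterior
#' approximation \eqn{N(\hat\beta, V_\beta)}.
#'
#' @param object a `dsm` fit.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return `nsim` x `p` matrix of coefficient draws.
#' @export
simulate.dsm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  beta <- stats::coef(object$engine)
  V <- object$engine$Vp
  draw_mvn(nsim, beta, V)
}

## MVN draws via pivoted Cholesky (tolerates a PSD, rank-deficient V)
draw_mvn <- function(n, mu, V) {
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values)))
    stop("posterior covariance is not positive semi-definite")
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  Z <- matrix(stats::rnorm(n * length(mu)), n, length(mu))
  sweep(Z %*% A, 2, mu, "+")
}

#' Proportion of deviance explained by a DSM
#'
#' `1 - deviance(model) / deviance(null model)`, the null model being the
#' intercept-plus-offset fit with the same family and dispersion.
#'
#' @param fit a `dsm` object.
#' @return Proportion in `[0, 1]`.
#' @export
deviance_explained <- function(fit) {
  stopifnot(inherits(fit, "dsm"))
  nulldev <- fit$engine$null.deviance
  if (!is.finite(nulldev) || nulldev <= 0) stop("null deviance is zero")
  max(0, min(1, 1 - stats::deviance(fit$engine) / nulldev))
}

#' Residual-refit model check
#'
#' Refits the smoother (with intercept, Gaussian family) to the deviance
#' residuals of the model.  If no spatial pattern remains, the refitted
#' effective degrees of freedom should be near zero for each term.
#'
#' @param fit a `dsm` object.
#' @param threshold per-term EDF below which the check passes.
#' @param residuals optional residual vector to refit in place of the
#'   model's own deviance residuals (used for calibration checks).
#' @return List with `refit_edf` (named per term), `pass`.
#' @details The refit uses `select = TRUE`, which also penalizes each
#'   term's penalty null space, so that structureless residuals can drive
#'   every term's EDF to zero (the thin-plate null space would otherwise
#'   retain two unpenalized degrees of freedom).
#' @export
residual_refit_check <- function(fit, threshold = 1.0, residuals = NULL) {
  stopifnot(inherits(fit, "dsm"))
  r <- if (is.null(residuals)) stats::residuals(fit$engine, type = "deviance")
       else residuals
  spec <- fit$smoother
  if (stats::sd(r) == 0) {
    ## degenerate: nothing to fit, every term has no effective freedom
    nt <- length(fit$engine$smooth)
    edf <- stats::setNames(rep(0, nt), names(per_term_edf(fit$engine)))
    return(list(refit_edf = edf, pass = TRUE))
  }
  dat <- data.frame(r = r, x = fit$coords$x, y = fit$coords$y, off = 0)
  if (spec$type == "soap") {
    spec_xt <- soap_xt(spec)
    fml <- r ~ s(x, y, bs = "sf", k = KB, xt = XT) + s(x, y, bs = "sw", xt = XT)
    fml <- eval(call("substitute", fml,
                     list(KB = spec$k_boundary, XT = quote(spec_xt))))
  } else {
    fml <- eval(call("substitute", r ~ s(x, y, bs = "tp", k = KK),
                     list(KK = spec$k)))
  }
  environment(fml) <- environment()
  g <- mgcv::gam(fml, data = dat, knots = fit$knots, family = stats::gaussian(),
                 method = "REML", select = TRUE)
  edf <- per_term_edf(g)
  list(refit_edf = edf, pass = all(edf < threshold))
}

#' Basis adequacy index for residual fine-scale structure
#'
#' The ratio of the mean squared difference of deviance residuals between
#' spatial nearest-neighbour point pairs to twice the overall residual
#' variance.  For exchangeable residuals the expectation is 1; values
#' clearly below 1 indicate unmodelled fine-scale spatial structure
#' (neighbouring residuals more alike than chance), which suggests the
#' basis dimension is too small.  This nearest-neighbour convention is
#' this package's own definition of the index.
#'
#' @param fit a `dsm` object (or a list with `residuals` and `coords`).
#' @return The index (scalar); 0 with a warning for constant residuals.
#' @export
basis_adequacy_index <- function(fit) {
  if (inherits(fit, "dsm")) {
    r <- stats::residuals(fit$engine, type = "deviance")
    xy <- fit$coords
  } else {
    r <- fit$residuals
    xy <- fit$coords
  }
  n <- length(r)
  if (n < 20) stop("need at least 20 residuals")
  v <- mean((r - mean(r))^2)
  if (v == 0) {
    warning("constant residuals: degenerate index 0")
    return(0)
  }
  nn <- nearest_neighbour(xy$x, xy$y)
  mean((r - r[nn])^2) / (2 * v)
}

nearest_neighbour <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf
    which.min(d2)
  }, 0L)
}
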