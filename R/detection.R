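#' Detection function key evaluation
#'
#' Evaluates the half-normal key \eqn{g(r) = \exp(-r^2 / (2\sigma^2))} or
#' the hazard-rate key \eqn{g(r) = 1 - \exp(-(r/\sigma)^{-b})} at radial
#' distance `r` metres.  Both keys satisfy \eqn{g(0) = 1} (the hazard-rate
#' in the limit) and are monotone non-increasing in `r`.
#'
#' @param key `"hn"` (half-normal) or `"hr"` (hazard-rate).
#' @param r distances, metres, non-negative.
#' @param sigma scale parameter, metres, positive.
#' @param b hazard-rate shape, required for `key = "hr"`; larger values
#'   give a wider shoulder and a sharper fall-off.
#' @return Detection probabilities in `[0, 1]`.
#' @examples
#' key_g("hn", 30, sigma = 30)       # exp(-0.5)
#' key_g("hr", 20, sigma = 20, b = 3) # 1 - exp(-1)
#' @export
key_g <- function(key = c("hn", "hr"), r, sigma, b = NULL) {
  key <- match.arg(key)
  if (any(r < 0)) stop("negative distances are not allowed")
  stopifnot(sigma > 0)
  if (key == "hn") return(exp(-r^2 / (2 * sigma^2)))
  if (is.null(b) || b <= 0) stop("hazard-rate key requires shape b > 0")
  out <- 1 - exp(-(r / sigma)^(-b))
  out[r == 0] <- 1
  out
}

## integral of t g(t) dt over (0, w); closed form for HN, quadrature for HR
int_rg <- function(key, sigma, b, w) {
  if (key == "hn") {
    return(sigma^2 * (1 - exp(-w^2 / (2 * sigma^2))))
  }
  stats::integrate(function(t) t * key_g("hr", t, sigma, b), 0, w,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

#' Average detection probability within the truncation radius
#'
#' \eqn{P_a = (2 / w^2) \int_0^w r\,g(r)\,dr}, the probability that an
#' animal present in the disk of radius `w` is detected.  Computed by
#' adaptive quadrature; for the half-normal key the closed form
#' \eqn{P_a = (2\sigma^2 / w^2)(1 - e^{-w^2/(2\sigma^2)})} is available via
#' `method = "closed"` as a cross-check.
#'
#' @inheritParams key_g
#' @param w truncation distance, metres.
#' @param method `"quadrature"` (default) or, for the half-normal key,
#'   `"closed"`.
#' @return Probability in `(0, 1]`.
#' @export
average_detection_probability <- function(key = c("hn", "hr"), sigma, b = NULL, w,
                                          method = c("quadrature", "closed")) {
  key <- match.arg(key)
  method <- match.arg(method)
  stopifnot(w > 0, sigma > 0)
  if (method == "closed") {
    if (key != "hn") stop("closed form is available for the half-normal key only")
    return(2 * sigma^2 / w^2 * (1 - exp(-w^2 / (2 * sigma^2))))
  }
  2 / w^2 * stats::integrate(function(t) t * key_g(key, t, sigma, b), 0, w,
                             rel.tol = 1e-10, subdivisions = 500L)$value
}

#' Effective area searched per point
#'
#' \eqn{\hat\nu = P_a \pi w^2} in square metres: the area of a disk that,
#' searched perfectly, would yield the same expected count as the radius-`w`
#' disk searched with detection probability `g(r)`.  It enters the density
#' surface model as a per-point offset on the log scale.
#'
#' @param p_a average detection probability in `(0, 1]`.
#' @param w truncation distance, metres.
#' @return Effective area, square metres.
#' @examples
#' effective_area(0.631, 58)  # 6668.6 m^2
#' @export
effective_area <- function(p_a, w) {
  stopifnot(p_a > 0, p_a <= 1, w >= 0)
  p_a * pi * w^2
}

## negative log-likelihood of truncated point-transect distances,
## f(r) = r g(r) / int_0^w t g(t) dt
ptds_nll <- function(par, key, r, w) {
  sigma <- exp(par[1])
  b <- if (key == "hr") 1 + exp(par[2]) else NULL
  denom <- int_rg(key, sigma, b, w)
  if (!is.finite(denom) || denom <= 0) return(1e10)
  ll <- sum(log(r) + log(pmax(key_g(key, r, sigma, b), 1e-300))) - length(r) * log(denom)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a point-transect detection function by maximum likelihood
#'
#' Maximizes the truncated point-transect likelihood with density
#' \eqn{f(r) = r\,g(r) / \int_0^w t\,g(t)\,dt} on `[0, w]` for the
#' half-normal or hazard-rate key without adjustment terms or covariates.
#' Optimization is on `log(sigma)` (and `log(b - 1)` for the hazard rate,
#' which enforces a shoulder, `b > 1`, and a strictly monotone decline)
#' with jittered restarts.  Standard errors come from the observed
#' information; `se(P_a)` by the delta method.
#'
#' @param distances numeric vector of radial distances (metres), or a
#'   data.frame with a `distance_m` column as returned by
#'   [read_distances()].
#' @param key `"hn"` or `"hr"`.
#' @param truncation truncation distance `w` in metres; distances beyond
#'   `w` are discarded before fitting.
#' @param min_n minimum number of retained distances (guards against a
#'   degenerate likelihood).
#' @param restarts number of jittered optimizer restarts.
#' @return An object of class `detfun`: a list with `key`, `sigma`, `b`,
#'   `w`, `loglik`, `aic`, `p_a`, `se_p_a`, `nu` (effective area, m^2),
#'   `n_used`, `vcov` (parameter covariance on the optimization scale),
#'   and the retained `distances`.
#' @examples
#' set.seed(1)
#' r <- sim_distances(500, key = "hn", sigma = 30, w = 58)
#' fit <- fit_detection(r, key = "hn", truncation = 58)
#' fit$p_a
#' @export
fit_detection <- function(distances, key = c("hn", "hr"), truncation,
                          min_n = 10, restarts = 5) {
  key <- match.arg(key)
  if (is.data.frame(distances)) distances <- distances$distance_m
  stopifnot(is.numeric(distances), truncation > 0)
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and non-negative")
  r <- distances[distances <= truncation]
  if (length(r) < min_n)
    stop(sprintf("only %d distances within truncation %.1f m (minimum %d)",
                 length(r), truncation, min_n))
  if (diff(range(r)) == 0)
    stop("all retained distances are equal: degenerate likelihood")
  w <- truncation

  init <- if (key == "hn") log(sqrt(mean(r^2) / 2)) else c(log(stats::median(r)), log(2))
  best <- NULL
  trace <- character(0)
  set_jitter <- function(k) if (k == 1) 0 else stats::rnorm(length(init), 0, 0.4)
  for (k in seq_len(max(1, restarts))) {
    p0 <- init + set_jitter(k)
    op <- tryCatch(
      stats::optim(p0, ptds_nll, key = key, r = r, w = w,
                   method = if (key == "hn") "Brent" else "Nelder-Mead",
                   lower = if (key == "hn") log(w) - 8 else -Inf,
                   upper = if (key == "hn") log(w) + 8 else Inf,
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(op)) { trace <- c(trace, sprintf("restart %d: error", k)); next }
    trace <- c(trace, sprintf("restart %d: nll %.6f conv %d", k, op$value, op$convergence))
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best) || best$value >= 1e10)
    stop("detection function optimization failed to converge:\n  ",
         paste(trace, collapse = "\n  "))

  par <- best$par
  sigma <- exp(par[1])
  b <- if (key == "hr") 1 + exp(par[2]) else NULL
  ll <- -best$value
  npar <- if (key == "hn") 1L else 2L

  H <- tryCatch(stats::optimHess(par, ptds_nll, key = key, r = r, w = w),
                error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(V)) V <- matrix(NA_real_, npar, npar)

  p_a <- average_detection_probability(key, sigma, b, w)
  ## delta method on the optimization scale
  grad <- numeric(npar)
  eps <- 1e-5
  for (j in seq_len(npar)) {
    pp <- par; pm <- par
    pp[j] <- pp[j] + eps; pm[j] <- pm[j] - eps
    f <- function(p) {
      s <- exp(p[1]); bb <- if (key == "hr") 1 + exp(p[2]) else NULL
      average_detection_probability(key, s, bb, w)
    }
    grad[j] <- (f(pp) - f(pm)) / (2 * eps)
  }
  se_p_a <- if (all(is.finite(V))) sqrt(max(0, drop(t(grad) %*% V %*% grad))) else NA_real_

  out <- list(
    key = key, sigma = sigma, b = b, w = w,
    loglik = ll, aic = -2 * ll + 2 * npar, npar = npar,
    p_a = p_a, se_p_a = se_p_a, nu = effective_area(p_a, w),
    n_used = length(r), vcov = V, distances = r,
    optim_trace = trace
  )
  class(out) <- "detfun"
  out
}

#' @export
print.detfun <- function(x, ...) {
  cat(sprintf("%s detection function (point transect), w = %.1f m, n = %d\n",
              if (x$key == "hn") "Half-normal" else "Hazard-rate", x$w, x$n_used))
  cat(sprintf("  sigma = %.3f m%s\n", x$sigma,
              if (x$key == "hr") sprintf(", b = %.3f", x$b) else ""))
  cat(sprintf("  P_a = %.3f (SE %.3f);  effective area = %.1f m^2\n",
              x$p_a, x$se_p_a, x$nu))
  cat(sprintf("  logLik = %.3f,  AIC = %.3f\n", x$loglik, x$aic))
  invisible(x)
}

#' @export
coef.detfun <- function(object, ...) {
  if (object$key == "hn") c(sigma = object$sigma)
  else c(sigma = object$sigma, b = object$b)
}

#' @export
logLik.detfun <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' @export
summary.detfun <- function(object, ...) object

#' Predict detection probability from a fitted detection function
#'
#' @param object a `detfun` fit.
#' @param r distances (metres) at which to evaluate `g`.
#' @param ... unused.
#' @export
predict.detfun <- function(object, r, ...) {
  key_g(object$key, r, object$sigma, object$b)
}

#' @export
plot.detfun <- function(x, breaks = 12, ...) {
  ## distance histogram rescaled against the fitted pdf of detected distances
  h <- graphics::hist(x$distances, breaks = breaks, plot = FALSE)
  rr <- seq(0, x$w, length.out = 200)
  dens <- rr * predict(x, rr) / int_rg(x$key, x$sigma, x$b, x$w)
  graphics::plot(h, freq = FALSE, main = "Detected distances", xlab = "distance (m)", ...)
  graphics::lines(rr, dens, col = 2, lwd = 2)
  invisible(x)
}

#' Simulate detected distances from a fitted or specified detection model
#'
#' Draws radial distances with density \eqn{f(r) \propto r\,g(r)} on
#' `[0, w]` by rejection from the triangular density \eqn{2r/w^2}.
#'
#' @param n number of distances.
#' @param key,sigma,b key function and parameters.
#' @param w truncation distance (metres).
#' @return Numeric vector of length `n`.
#' @export
sim_distances <- function(n, key = c("hn", "hr"), sigma, b = NULL, w) {
  key <- match.arg(key)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 2.5))
    r <- w * sqrt(stats::runif(m))          # triangular 2r/w^2
    keep <- stats::runif(m) < key_g(key, r, sigma, b)
    out <- c(out, r[keep])
  }
  out[seq_len(n)]
}

#' Choose the truncation distance from a preliminary fit
#'
#' Fits a preliminary detection function truncated at the maximum observed
#' distance and returns the smallest distance at which the estimated
#' detection probability falls to `target_g` (default 0.1), rounded to the
#' nearest metre.  Both keys are monotone, so the crossing is unique.
#'
#' @inheritParams fit_detection
#' @param target_g detection probability defining the truncation point,
#'   in (0, 1).
#' @param round_to rounding granularity in metres (default 1).
#' @return Truncation distance in metres.  If `g` never falls to
#'   `target_g` within the observed range, the maximum observed distance
#'   is returned with a warning.
#' @export
select_truncation <- function(distances, key = c("hn", "hr"), target_g = 0.1,
                              round_to = 1) {
  key <- match.arg(key)
  if (is.data.frame(distances)) distances <- distances$distance_m
  stopifnot(target_g > 0, target_g < 1)
  wmax <- max(distances)
  fit <- fit_detection(distances, key = key, truncation = wmax)
  if (key_g(key, wmax, fit$sigma, fit$b) > target_g) {
    warning("estimated g never falls to ", target_g,
            " within the observed range; returning the maximum observed distance")
    return(wmax)
  }
  w <- stats::uniroot(function(r) key_g(key, r, fit$sigma, fit$b) - target_g,
                      c(1e-8, wmax), tol = 1e-8)$root
  round(w / round_to) * round_to
}

#' Rank fitted detection functions by AIC
#'
#' @param models list of `detfun` fits on the same truncated data.
#' @return data.frame with one row per model: key, npar, aic, delta_aic,
#'   p_a, se_p_a, ascending in `delta_aic` (ties broken by fewer
#'   parameters).
#' @export
rank_by_aic <- function(models) {
  stopifnot(length(models) >= 1, all(vapply(models, inherits, TRUE, "detfun")))
  n_used <- vapply(models, `[[`, 0, "n_used")
  if (length(unique(n_used)) > 1)
    stop("models were fitted on different numbers of distances; AICs are not comparable")
  tab <- data.frame(
    key = vapply(models, `[[`, "", "key"),
    npar = vapply(models, `[[`, 0L, "npar"),
    aic = vapply(models, `[[`, 0, "aic"),
    p_a = vapply(models, `[[`, 0, "p_a"),
    se_p_a = vapply(models, `[[`, 0, "se_p_a")
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab <- tab[order(tab$delta_aic, tab$npar), ]
  rownames(tab) <- NULL
  tab[, c("key", "npar", "aic", "delta_aic", "p_a", "se_p_a")]
}

## limiting distribution of the Cramer-von Mises statistic
## P(W^2 <= x) via the classical Bessel-K series
pcvm_asymptotic <- function(x, terms = 12) {
  vapply(x, function(xx) {
    if (!is.finite(xx) || xx <= 0) return(0)
    if (xx > 20) return(1)
    j <- 0:(terms - 1)
    a <- exp(lgamma(j + 0.5) - lgamma(0.5) - lfactorial(j))
    z <- (4 * j + 1)^2 / (16 * xx)
    ## exp(-z) K_{1/4}(z) computed with the scaled Bessel to avoid underflow
    s <- a * sqrt(4 * j + 1) * exp(-2 * z) * besselK(z, 0.25, expon.scaled = TRUE)
    min(1, max(0, sum(s) / (pi * sqrt(xx))))
  }, 0)
}

#' Cramer-von Mises goodness-of-fit test for a detection function
#'
#' Computes the unweighted Cramer-von Mises statistic
#' \eqn{W^2 = \sum_i [\hat F(r_{(i)}) - (2i-1)/(2n)]^2 + 1/(12n)} where
#' \eqn{\hat F} is the fitted CDF of detected distances on `[0, w]`, with a
#' p-value from the asymptotic Cramer-von Mises distribution.  No
#' correction is made for estimated parameters (the unweighted convention);
#' the p-value is therefore approximate and mildly conservative.
#'
#' @param fit a `detfun` object.
#' @param distances optional distances to test; defaults to the distances
#'   the model was fitted to.
#' @return list with `statistic` (W^2) and `p_value`.
#' @export
cvm_test <- function(fit, distances = NULL) {
  stopifnot(inherits(fit, "detfun"))
  r <- if (is.null(distances)) fit$distances else distances[distances <= fit$w]
  n <- length(r)
  if (n == 0) stop("no distances to test")
  denom <- int_rg(fit$key, fit$sigma, fit$b, fit$w)
  Fhat <- vapply(sort(r), function(u) int_rg(fit$key, fit$sigma, fit$b, u), 0) / denom
  i <- seq_len(n)
  W2 <- sum((Fhat - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n)
  list(statistic = W2, p_value = 1 - pcvm_asymptotic(W2))
}

#' Per-point counts of detections within the truncation distance
#'
#' @param records data.frame with columns `point_id` and `distance_m`.
#' @param points data.frame of survey points with a `point_id` column.
#' @param w truncation distance, metres.
#' @return Integer vector of counts, one per row of `points` (0 for points
#'   without records), named by `point_id`.
#' @export
counts_per_point <- function(records, points, w) {
  stopifnot(all(c("point_id", "distance_m") %in% names(records)),
            "point_id" %in% names(points))
  orphans <- setdiff(unique(records$point_id), points$point_id)
  if (length(orphans))
    stop("detection records reference unknown point_id(s): ",
         paste(utils::head(orphans, 10), collapse = ", "))
  kept <- records[records$distance_m <= w, ]
  tab <- table(factor(kept$point_id, levels = points$point_id))
  stats::setNames(as.integer(tab), points$point_id)
}
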