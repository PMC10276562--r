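#' Gaussian-bump intensity surface over a region
#'
#' Defines a true density surface as a non-negative baseline plus a sum
#' of anisotropic Gaussian bumps, in birds per hectare.  The true total
#' abundance is the numerical integral of the surface over the region
#' (computed on a raster and stored with the surface).
#'
#' @param region a [region()] object.
#' @param components list of bumps; each a list with `amplitude`
#'   (birds/ha), `centre` (length-2, metres), `sd` (length-2 metres, axis
#'   aligned spreads).
#' @param baseline constant background density, birds/ha.
#' @param h raster cell size (metres) for the abundance integral.
#' @return Object of class `intensity_surface` with `density(x, y)`
#'   evaluation via [surface_density()], `N_true`, `region`.
#' @export
intensity_surface <- function(region, components, baseline = 0, h = 100) {
  stopifnot(inherits(region, "region"), baseline >= 0)
  for (cmp in components) {
    stopifnot(cmp$amplitude >= 0, length(cmp$centre) == 2, all(cmp$sd > 0))
  }
  surf <- structure(list(region = region, components = components,
                         baseline = baseline),
                    class = "intensity_surface")
  msk <- rasterize_region(region, h)
  bb <- apply(region$outer, 2, range)
  idx <- which(msk$inside, arr.ind = TRUE)
  cx <- bb[1, 1] + (idx[, 2] - 0.5) * h
  cy <- bb[1, 2] + (idx[, 1] - 0.5) * h
  dens <- surface_density(surf, cx, cy)
  surf$N_true <- sum(dens) * h^2 / 1e4
  surf
}

#' Evaluate a true intensity surface
#'
#' @param surface an [intensity_surface()].
#' @param x,y coordinates, metres.
#' @return Density in birds per hectare (no region masking).
#' @export
surface_density <- function(surface, x, y) {
  d <- rep(surface$baseline, length(x))
  for (cmp in surface$components) {
    d <- d + cmp$amplitude *
      exp(-0.5 * (((x - cmp$centre[1]) / cmp$sd[1])^2 +
                    ((y - cmp$centre[2]) / cmp$sd[2])^2))
  }
  d
}

#' @export
print.intensity_surface <- function(x, ...) {
  cat("Intensity surface:", length(x$components), "component(s), baseline",
      x$baseline, "birds/ha; true abundance",
      format(round(x$N_true), big.mark = ","), "birds\n")
  invisible(x)
}

#' Systematic point-transect survey design
#'
#' Places parallel east-west transects at given northings and survey
#' points every `point_spacing` metres along each transect, keeping
#' points inside the region.  Points are ordered transect by transect,
#' west to east; if `n_points` is given the trailing points are dropped
#' (deterministically) to reach exactly that count.
#'
#' @param region a [region()] object.
#' @param transect_y northings of the transects (metres).
#' @param point_spacing spacing along transects, metres.
#' @param x_start,x_end optional easting limits, recycled per transect
#'   (default: the region bounding box).  Varying `x_start` lets parts
#'   of the region go unsampled, as in surveys whose sampling frame is
#'   narrower than the prediction region.
#' @param n_points optional exact number of points to return.
#' @return data.frame with columns `point_id`, `transect`, `x`, `y`.
#' @export
survey_design <- function(region, transect_y, point_spacing = 150,
                          x_start = NULL, x_end = NULL, n_points = NULL) {
  stopifnot(inherits(region, "region"), point_spacing > 0)
  bb <- apply(region$outer, 2, range)
  if (is.null(x_start)) x_start <- bb[1, 1]
  if (is.null(x_end)) x_end <- bb[2, 1]
  x_start <- rep_len(x_start, length(transect_y))
  x_end <- rep_len(x_end, length(transect_y))
  pts <- do.call(rbind, lapply(seq_along(transect_y), function(t) {
    xs <- seq(x_start[t], x_end[t], by = point_spacing)
    keep <- point_in_region(region, xs, rep(transect_y[t], length(xs)))
    if (!any(keep)) return(NULL)
    data.frame(transect = t, x = xs[keep], y = transect_y[t])
  }))
  if (is.null(pts) || nrow(pts) == 0) stop("no survey points fall inside the region")
  if (!is.null(n_points)) {
    if (nrow(pts) < n_points)
      stop(sprintf("design yields %d points, fewer than the requested %d",
                   nrow(pts), n_points))
    ## drop the easternmost point of the currently longest transect until
    ## the requested count is reached (deterministic; keeps every transect)
    while (nrow(pts) > n_points) {
      sizes <- table(pts$transect)
      longest <- as.integer(names(sizes)[which.max(sizes)])
      drop <- max(which(pts$transect == longest))
      pts <- pts[-drop, , drop = FALSE]
    }
  }
  pts$point_id <- sprintf("p%03d", seq_len(nrow(pts)))
  rownames(pts) <- NULL
  pts[, c("point_id", "transect", "x", "y")]
}

#' Simulate a point-transect survey with known truth
#'
#' For each survey point the number of birds present in the disk of
#' radius `w_max` is drawn with mean \eqn{D(s_k)\,\pi\,w_{max}^2}
#' (negative binomial with dispersion `theta`, or Poisson when
#' `theta = Inf`).  Each bird receives a radial distance with density
#' \eqn{2r/w_{max}^2} (uniform position in the disk) and is detected
#' with probability `g(r)`; detected birds become detection records.
#' Birds are placed independently per point disk: at typical designs
#' (150 m point spacing, detection radii under 100 m) disks barely
#' overlap, so no shared population is simulated.
#'
#' @param surface an [intensity_surface()].
#' @param design a [survey_design()] data.frame (columns `point_id`,
#'   `x`, `y`).
#' @param detection list with `key` (`"hn"`/`"hr"`), `sigma`, and `b`
#'   (hazard-rate only).
#' @param w_max generation radius, metres.
#' @param theta negative binomial dispersion (`Inf` for Poisson counts).
#' @param seed integer master seed; all randomness derives from it.
#' @return Object of class `synthetic_survey`: list with `points`
#'   (the design), `records` (data.frame `point_id`, `distance_m`),
#'   `truth` (surface, `N_true`, detection parameters, `theta`, `w_max`,
#'   `seed`), and `region`.
#' @export
simulate_survey <- function(surface, design, detection, w_max, theta = Inf,
                            seed = 1) {
  stopifnot(inherits(surface, "intensity_surface"),
            all(c("point_id", "x", "y") %in% names(design)),
            w_max > 0, theta > 0)
  set.seed(as.integer(seed))
  dens <- surface_density(surface, design$x, design$y)   # birds/ha
  mu <- dens / 1e4 * pi * w_max^2                        # birds per disk
  n_present <- if (is.finite(theta)) {
    stats::rnbinom(length(mu), size = theta, mu = mu)
  } else {
    stats::rpois(length(mu), mu)
  }
  recs <- vector("list", length(mu))
  for (k in seq_along(mu)) {
    if (n_present[k] == 0) next
    r <- w_max * sqrt(stats::runif(n_present[k]))
    det <- stats::runif(n_present[k]) <
      key_g(detection$key, r, detection$sigma, detection$b)
    if (any(det))
      recs[[k]] <- data.frame(point_id = design$point_id[k],
                              distance_m = r[det])
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(point_id = character(0), distance_m = numeric(0))
  rownames(records) <- NULL
  structure(list(
    points = design, records = records,
    truth = list(surface = surface, N_true = surface$N_true,
                 detection = detection, theta = theta, w_max = w_max,
                 seed = as.integer(seed)),
    region = surface$region
  ), class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat("Synthetic point-transect survey:", nrow(x$points), "points,",
      nrow(x$records), "detections at",
      length(unique(x$records$point_id)), "points\n")
  cat("  truth: N =", format(round(x$truth$N_true), big.mark = ","),
      "birds; detection", x$truth$detection$key,
      "sigma", round(x$truth$detection$sigma, 1),
      if (!is.null(x$truth$detection$b)) paste("b", round(x$truth$detection$b, 2)) else "",
      "; theta", x$truth$theta, "\n")
  invisible(x)
}

## Hakalau-like study region: ~5,671.8 ha, irregular western (pasture-
## forest) edge, squared-off north/east/south edges; first vertex is the
## south-west corner so arc length 0 starts there.  Purely synthetic --
## the real boundary coordinates are not published.
hakalau_region_raw <- function() {
  ys <- seq(0, 10500, length.out = 40)
  ## wiggly pasture-forest west edge
  xw <- 950 + 420 * sin(2 * pi * ys / 4600) + 250 * sin(2 * pi * ys / 1600 + 1) +
    150 * cos(2 * pi * ys / 750)
  east <- 5600
  outer <- rbind(
    cbind(xw[1], 0),
    cbind(east, 0),
    cbind(east, 10500),
    cbind(rev(xw[-1]), rev(ys[-1]))
  )
  region(outer)
}

#' Hakalau-like synthetic study region
#'
#' A synthetic stand-in for the 2002 study-area boundary: an irregular
#' western edge with squared-off north, east and south sides, scaled so
#' the area is exactly 5,671.8 ha.  The first outer vertex (arc-length
#' origin) is the south-west corner.
#'
#' @return A [region()] object.
#' @export
hakalau_region <- function() {
  r0 <- hakalau_region_raw()
  sc <- sqrt(5671.8 / r0$area_ha)
  region(r0$outer * sc)
}

#' Hakalau-like synthetic survey fixture
#'
#' Generates a survey emulating the 2002 study conditions: a region of
#' 5,671.8 ha with an irregular west edge; 14 east-west transects with
#' alternating 500 m / 1,000 m spacing and points every 150 m (exactly
#' 289 points); a density surface with a strong southern hotspot, a
#' moderate central hotspot, and near-zero density in the north; a
#' hazard-rate detection function calibrated so the average detection
#' probability within 58 m is 0.631; and negative binomial counts with
#' dispersion 10.  The surface amplitude is calibrated so the expected
#' number of detections is close to the 276 recorded in 2002.
#'
#' @param seed integer master seed.
#' @return A [simulate_survey()] object; `truth` additionally records
#'   `w = 58` (the analysis truncation distance).
#' @export
hakalau_like_fixture <- function(seed = 1) {
  reg <- hakalau_region()
  sc <- sqrt(5671.8 / hakalau_region_raw()$area_ha)
  ## 14 east-west transects, gaps alternating 500/1000 m (pre-scaling);
  ## the six northern transects are east-anchored, leaving the low-density
  ## north-west corner unsampled, as in the 2002 sampling frame
  gaps <- rep(c(500, 1000), length.out = 13)
  ty <- 500 + cumsum(c(0, gaps))
  xs <- ifelse(ty > 6000, 3400, 150)
  design <- survey_design(reg, transect_y = ty * sc,
                          point_spacing = 150 * sc,
                          x_start = xs * sc, x_end = 5450 * sc,
                          n_points = 289)
  surface <- intensity_surface(
    reg,
    components = list(
      list(amplitude = 3.96, centre = c(2300, 1700) * sc, sd = c(1300, 1100) * sc),
      list(amplitude = 2.16, centre = c(3900, 4700) * sc, sd = c(950, 850) * sc)
    ),
    baseline = 0.036
  )
  detection <- list(key = "hr", sigma = 39.837, b = 3.5)  # P_a(58 m) = 0.631
  out <- simulate_survey(surface, design, detection, w_max = 90,
                         theta = 10, seed = seed)
  out$truth$w <- 58
  out
}

#' Truth-versus-estimate recovery scorecard
#'
#' Compares pipeline outputs against the stored truth of a synthetic
#' survey: detection scale sigma, average detection probability, NB
#' dispersion, total abundance, and (if a prediction grid is supplied)
#' the cell-wise correlation between true and estimated density
#' (Pearson and Spearman).
#'
#' @param survey a [simulate_survey()] object.
#' @param detfit a [fit_detection()] result (optional).
#' @param dsm_fit a [fit_dsm()] result (optional).
#' @param abundance an [abundance_estimate()] (optional).
#' @param grid a [predict_surface()] grid (optional).
#' @return data.frame with columns `parameter`, `truth`, `estimate`,
#'   `rel_error`, `ci_covered`.
#' @export
recovery_report <- function(survey, detfit = NULL, dsm_fit = NULL,
                            abundance = NULL, grid = NULL) {
  stopifnot(inherits(survey, "synthetic_survey"))
  tr <- survey$truth
  rows <- list()
  add <- function(parameter, truth, estimate, ci = c(NA, NA)) {
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = parameter, truth = truth, estimate = estimate,
      rel_error = if (is.finite(truth) && truth != 0) (estimate - truth) / truth else NA_real_,
      ci_covered = if (all(is.finite(ci))) (truth >= ci[1] & truth <= ci[2]) else NA)
  }
  if (!is.null(detfit)) {
    add("sigma", tr$detection$sigma, detfit$sigma)
    p_true <- average_detection_probability(tr$detection$key, tr$detection$sigma,
                                            tr$detection$b, detfit$w)
    ci <- detfit$p_a + c(-1.96, 1.96) * detfit$se_p_a
    add("p_a", p_true, detfit$p_a, ci)
  }
  if (!is.null(dsm_fit) && dsm_fit$family == "nb")
    add("theta", tr$theta, dsm_fit$theta)
  if (!is.null(abundance))
    add("N", tr$N_true, abundance$N, c(abundance$lcl, abundance$ucl))
  if (!is.null(grid)) {
    d_true <- surface_density(tr$surface, grid$x, grid$y)
    add("surface_cor_pearson", 1, stats::cor(d_true, grid$density_ha))
    add("surface_cor_spearman", 1,
        stats::cor(d_true, grid$density_ha, method = "spearman"))
  }
  do.call(rbind, rows)
}
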