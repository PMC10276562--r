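#' Specify a spatial smoother for the density surface model
#'
#' Two smoother families are supported.  `"tprs"` is an isotropic thin
#' plate regression spline over (easting, northing) that ignores the
#' region boundary.  `"soap"` is a soap-film smoother: a cyclic boundary
#' smooth in arc length around the region edge plus an interior "film"
#' that is exactly zero on the boundary, so the fitted surface can never
#' leak across the study-region edge.
#'
#' For the soap smoother the boundary smooth has basis dimension
#' `k_boundary` (cyclicity and model-level centering each absorb one
#' degree of freedom, leaving `k_boundary - 2` free coefficients) and the
#' interior film has one basis function per interior knot.  Basis
#' functions are defined as solutions of Laplace/Poisson problems on the
#' region, solved numerically on a grid with at most `nmax` cells along
#' the longest side.
#'
#' @param type `"tprs"` or `"soap"`.
#' @param k basis dimension for the TPRS smoother (default 127; one degree
#'   of freedom is absorbed by the identifiability constraint).
#' @param region a [region()] object (required for soap).
#' @param knots interior knot locations for the soap film, e.g. from
#'   [make_knot_grid()] (required for soap).
#' @param k_boundary cyclic boundary-smooth basis dimension (default 20).
#' @param nmax PDE solution grid dimension (cells along the longest side).
#' @return An object of class `smoother_spec`.
#' @export
smoother_spec <- function(type = c("soap", "tprs"), k = 127, region = NULL,
                          knots = NULL, k_boundary = 20, nmax = 200) {
  type <- match.arg(type)
  if (type == "soap") {
    if (!inherits(region, "region")) stop("soap smoother requires a region")
    if (is.null(knots) || nrow(knots) < 1) stop("soap smoother requires interior knots")
    if (!all(point_in_region(region, knots$x, knots$y)))
      stop("all soap knots must lie inside the region")
    if (k_boundary < 4) stop("k_boundary must be at least 4")
  } else {
    if (k < 3) stop("tprs requires k >= 3")
  }
  structure(list(type = type, k = k, region = region, knots = knots,
                 k_boundary = k_boundary, nmax = nmax),
            class = "smoother_spec")
}

#' @export
print.smoother_spec <- function(x, ...) {
  if (x$type == "tprs") {
    cat("Thin plate regression spline smoother, k =", x$k, "\n")
  } else {
    cat("Soap-film smoother: boundary basis", x$k_boundary,
        "(", x$k_boundary - 2, "free ),", nrow(x$knots), "interior knots\n")
  }
  invisible(x)
}

## mgcv smooth term definitions for a spec; soap is entered as two terms
## (boundary film "sf" + zero-boundary interior film "sw") so that each
## component gets its own penalty, smoothing parameter and EDF
smoother_formula_terms <- function(spec) {
  if (spec$type == "tprs") return("s(x, y, bs = \"tp\", k = spec$k)")
  c("s(x, y, bs = \"sf\", k = spec$k_boundary, xt = spec_xt)",
    "s(x, y, bs = \"sw\", xt = spec_xt)")
}

soap_xt <- function(spec) {
  list(bnd = as_soap_boundary(spec$region), nmax = spec$nmax)
}

## mgcv's soap constructor rejects knots that fall on/outside the PDE grid
## boundary cells; prune them (deterministically) and retry
prune_soap_knots <- function(spec, data, max_drop = 25) {
  knots <- spec$knots[, c("x", "y")]
  xt <- soap_xt(spec)
  for (i in seq_len(max_drop)) {
    ok <- tryCatch({
      mgcv::smoothCon(mgcv::s(x, y, bs = "sw", xt = xt),
                      data = data, knots = knots, absorb.cons = TRUE)
      TRUE
    }, error = function(e) e)
    if (isTRUE(ok)) return(knots)
    msg <- conditionMessage(ok)
    m <- regmatches(msg, regexec("knot ([0-9]+) is on or outside boundary", msg))[[1]]
    if (length(m) < 2) stop("soap basis construction failed: ", msg)
    drop <- as.integer(m[2])
    knots <- knots[-drop, , drop = FALSE]
    if (nrow(knots) < 1) stop("all soap knots rejected by the PDE grid")
  }
  stop("soap knot pruning did not converge after ", max_drop, " drops")
}

#' Build design and penalty matrices for a smoother
#'
#' Evaluates the smoother's basis at the supplied data locations and
#' returns the constrained design matrix and penalty matrices, as used
#' inside [fit_dsm()].  For the soap smoother the result has two
#' components, the cyclic boundary smooth and the interior film (zero on
#' the boundary); for TPRS a single component.
#'
#' @param spec a [smoother_spec()].
#' @param data data.frame with columns `x`, `y` (metres); for soap, all
#'   points must be inside the region.
#' @return An object of class `smoother_basis`: list with `spec`,
#'   `terms` (a list per component with `label`, `design`, `penalty`,
#'   `smooth` (the underlying constructor object)), and `design` (the
#'   column-bound full design matrix, no intercept).
#' @export
build_smoother <- function(spec, data) {
  stopifnot(inherits(spec, "smoother_spec"),
            all(c("x", "y") %in% names(data)))
  data <- as.data.frame(data)[, c("x", "y")]
  if (spec$type == "soap") {
    bad <- !point_in_region(spec$region, data$x, data$y)
    if (any(bad))
      stop("data points outside the region: rows ",
           paste(utils::head(which(bad), 10), collapse = ", "))
    xt <- soap_xt(spec)
    knots <- prune_soap_knots(spec, data)
    scb <- mgcv::smoothCon(mgcv::s(x, y, bs = "sf", k = spec$k_boundary, xt = xt),
                           data = data, knots = knots, absorb.cons = TRUE)[[1]]
    scf <- mgcv::smoothCon(mgcv::s(x, y, bs = "sw", xt = xt),
                           data = data, knots = knots, absorb.cons = TRUE)[[1]]
    terms <- list(
      boundary = list(label = "boundary", design = scb$X,
                      penalty = scb$S[[1]], smooth = scb),
      film = list(label = "film", design = scf$X,
                  penalty = scf$S[[1]], smooth = scf)
    )
  } else {
    n_distinct <- nrow(unique(data))
    if (n_distinct < 2) stop("need at least 2 distinct locations")
    if (spec$k > n_distinct)
      stop("tprs basis dimension k exceeds the number of distinct locations")
    sct <- mgcv::smoothCon(mgcv::s(x, y, bs = "tp", k = spec$k),
                           data = data, absorb.cons = TRUE)[[1]]
    terms <- list(
      tprs = list(label = "tprs", design = sct$X,
                  penalty = sct$S[[1]], smooth = sct)
    )
  }
  structure(list(spec = spec, terms = terms,
                 design = do.call(cbind, lapply(terms, `[[`, "design"))),
            class = "smoother_basis")
}

#' Evaluate a smoother basis at new locations
#'
#' Computes the linear combination of basis columns at arbitrary
#' locations.  For the soap smoother, locations outside the region give
#' `NA` (never an extrapolated value), and locations on the boundary
#' (within `boundary_tol` metres) evaluate the film component to exactly
#' zero, its Dirichlet boundary condition.
#'
#' @param basis a [build_smoother()] result.
#' @param coefficients numeric vector matching `ncol(basis$design)`.
#' @param locations data.frame with columns `x`, `y`.
#' @param strict if `TRUE`, outside locations raise an error instead of
#'   returning `NA`.
#' @param boundary_tol snap tolerance (metres) for the on-boundary film
#'   condition.
#' @return Numeric vector of smoother values (no intercept).
#' @export
evaluate_smoother <- function(basis, coefficients, locations, strict = FALSE,
                              boundary_tol = 1e-6) {
  stopifnot(inherits(basis, "smoother_basis"))
  X <- smoother_predict_matrix(basis, locations, boundary_tol = boundary_tol)
  if (length(coefficients) != ncol(X))
    stop("coefficient length ", length(coefficients), " does not match basis dimension ", ncol(X))
  if (strict && anyNA(X[, 1]))
    stop("locations outside the region: rows ",
         paste(utils::head(which(is.na(X[, 1])), 10), collapse = ", "))
  drop(X %*% coefficients)
}

## prediction design matrix for a smoother_basis; soap film columns are
## exactly zero at on-boundary locations, NA outside the region
smoother_predict_matrix <- function(basis, locations, boundary_tol = 1e-6) {
  locations <- as.data.frame(locations)[, c("x", "y")]
  if (basis$spec$type == "tprs") {
    return(mgcv::PredictMat(basis$terms$tprs$smooth, locations))
  }
  region <- basis$spec$region
  ins <- point_in_region(region, locations$x, locations$y)
  on_bnd <- boundary_distance(region, locations$x, locations$y) <= boundary_tol
  nb <- ncol(basis$terms$boundary$design)
  nf <- ncol(basis$terms$film$design)
  X <- matrix(NA_real_, nrow(locations), nb + nf)
  interior <- ins & !on_bnd
  if (any(interior)) {
    li <- locations[interior, , drop = FALSE]
    X[interior, seq_len(nb)] <- mgcv::PredictMat(basis$terms$boundary$smooth, li)
    X[interior, nb + seq_len(nf)] <- mgcv::PredictMat(basis$terms$film$smooth, li)
  }
  if (any(on_bnd)) {
    lb <- nudge_inward(region, locations[on_bnd, , drop = FALSE])
    X[on_bnd, seq_len(nb)] <- mgcv::PredictMat(basis$terms$boundary$smooth, lb)
    X[on_bnd, nb + seq_len(nf)] <- 0   # Dirichlet condition: film is 0 on the boundary
  }
  X
}

## distance from points to the outer ring (and hole rings) of a region
boundary_distance <- function(region, x, y) {
  d <- dist_to_ring(region$outer, x, y)
  for (h in region$holes) d <- pmin(d, dist_to_ring(h, x, y))
  d
}

dist_to_ring <- function(ring, x, y) {
  n <- nrow(ring)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  out <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    t <- ((x - x1[k]) * dx[k] + (y - y1[k]) * dy[k]) / max(len2[k], 1e-12)
    t <- pmin(1, pmax(0, t))
    px <- x1[k] + t * dx[k]; py <- y1[k] + t * dy[k]
    out <- pmin(out, sqrt((x - px)^2 + (y - py)^2))
  }
  out
}

## move near-boundary points a small distance towards the region interior
## so the PDE-grid interpolation has support; used only for evaluating the
## boundary smooth at on-boundary locations.  Tries the inward normal of
## the nearest outer-ring segment first, then the opposite side, then the
## direction of the bounding-box centre, at increasing step sizes.
nudge_inward <- function(region, locations, step = NULL) {
  bb <- apply(region$outer, 2, range)
  if (is.null(step)) step <- 1e-4 * max(bb[2, ] - bb[1, ])
  cx <- mean(bb[, 1]); cy <- mean(bb[, 2])
  ring <- region$outer
  n <- nrow(ring)
  sx <- ring[, 1]; sy <- ring[, 2]
  ex <- c(sx[-1], sx[1]); ey <- c(sy[-1], sy[1])
  dx <- ex - sx; dy <- ey - sy
  len <- sqrt(dx^2 + dy^2)
  x <- locations$x; y <- locations$y
  for (i in seq_along(x)) {
    ## nearest segment
    t <- pmin(1, pmax(0, ((x[i] - sx) * dx + (y[i] - sy) * dy) / pmax(len^2, 1e-12)))
    px <- sx + t * dx; py <- sy + t * dy
    k <- which.min((x[i] - px)^2 + (y[i] - py)^2)
    ## left normal of CCW ring points inward
    nx <- -dy[k] / len[k]; ny <- dx[k] / len[k]
    vc <- c(cx - x[i], cy - y[i])
    nv <- sqrt(sum(vc^2))
    dirs <- list(c(nx, ny), c(-nx, -ny),
                 if (nv > 1e-12) vc / nv else c(0, 0))
    done <- FALSE
    for (s in step * c(1, 2, 4, 8, 16)) {
      for (d in dirs) {
        xi <- x[i] + d[1] * s; yi <- y[i] + d[2] * s
        if (point_in_region(region, xi, yi) &&
            boundary_distance(region, xi, yi) >= 0.49 * s) {
          x[i] <- xi; y[i] <- yi; done <- TRUE; break
        }
      }
      if (done) break
    }
  }
  data.frame(x = x, y = y)
}
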