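#' Study region with a complex boundary
#'
#' A `region` represents the study area as a simple outer polygon with
#' optional interior holes, in projected (easting, northing) metres.  It is
#' the spatial domain for knot placement, soap-film smoothing, prediction
#' grids and abundance integration.
#'
#' Vertex order is normalized on construction: the outer ring is stored
#' counter-clockwise and holes clockwise.  The first stored vertex of the
#' outer ring is the origin of the boundary arc-length parameterization.
#'
#' @param outer two-column matrix (or data.frame) of outer-ring vertices,
#'   easting and northing in metres.  The ring may be given open or closed
#'   (first vertex repeated); it is stored open.
#' @param holes optional list of vertex matrices for interior holes.
#' @return An object of class `region` with elements `outer`, `holes`,
#'   `area_ha` (hectares), `perimeter_m` (metres).
#' @examples
#' sq <- region(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' sq$area_ha       # 1 ha
#' sq$perimeter_m   # 400 m
#' @export
region <- function(outer, holes = list()) {
  outer <- close_check_ring(outer, "outer ring")
  assert_simple_ring(outer, "outer ring")
  if (ring_signed_area(outer) < 0) outer <- outer[rev(seq_len(nrow(outer))), , drop = FALSE]
  holes <- lapply(seq_along(holes), function(i) {
    h <- close_check_ring(holes[[i]], sprintf("hole %d", i))
    assert_simple_ring(h, sprintf("hole %d", i))
    if (ring_signed_area(h) > 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
    if (!all(pip_ray(h[, 1], h[, 2], outer)))
      stop(sprintf("hole %d is not inside the outer ring", i))
    h
  })
  area <- ring_signed_area(outer) - sum(vapply(holes, function(h) -ring_signed_area(h), 0))
  if (area <= 0) stop("region area must be positive")
  out <- list(
    outer = outer, holes = holes,
    area_ha = area / 1e4,
    perimeter_m = ring_length(outer)
  )
  class(out) <- "region"
  out
}

#' @export
print.region <- function(x, ...) {
  cat("Study region:", format(round(x$area_ha, 1), big.mark = ","), "ha,",
      nrow(x$outer), "outer vertices,", length(x$holes), "hole(s),\n",
      " outer perimeter", format(round(x$perimeter_m), big.mark = ","), "m\n")
  invisible(x)
}

## ---- ring helpers -------------------------------------------------------

close_check_ring <- function(ring, what) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) < 2)
    stop(what, ": need a numeric two-column vertex matrix")
  ring <- ring[, 1:2, drop = FALSE]
  if (anyNA(ring)) stop(what, ": NA coordinates")
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) stop(what, ": need at least 3 distinct vertices")
  colnames(ring) <- c("x", "y")
  ring
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_length <- function(ring) {
  d <- rbind(diff(ring), ring[1, ] - ring[nrow(ring), ])
  sum(sqrt(rowSums(d^2)))
}

## segment intersection test for simplicity validation; O(n^2) is fine at
## the vertex counts used for study boundaries
assert_simple_ring <- function(ring, what) {
  n <- nrow(ring)
  a1 <- ring
  a2 <- ring[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ## skip adjacent segments (share an endpoint)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(a1[i, ], a2[i, ], a1[j, ], a2[j, ]))
        stop(sprintf("%s is self-intersecting: segment %d crosses segment %d",
                     what, i, j))
    }
  }
  invisible(TRUE)
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

## ray-casting point-in-ring, edge-inclusive (points on an edge count as in)
pip_ray <- function(x, y, ring) {
  rx <- ring[, 1]; ry <- ring[, 2]
  n <- length(rx)
  jx <- c(rx[n], rx[-n]); jy <- c(ry[n], ry[-n])
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- rx[k]; y1 <- ry[k]; x2 <- jx[k]; y2 <- jy[k]
    ## on-segment test
    cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_edge <- on_edge | (cr == 0 &
                            x >= pmin(x1, x2) & x <= pmax(x1, x2) &
                            y >= pmin(y1, y2) & y <= pmax(y1, y2))
    ## crossing test (half-open rule avoids double-counting vertices)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Is a point inside the study region?
#'
#' Edge-inclusive convention: points exactly on the outer boundary or on a
#' hole edge are treated as inside the region, so that knot and prediction
#' filtering is reproducible.
#'
#' @param region a [region()] object.
#' @param x,y numeric vectors of easting/northing (metres).
#' @return logical vector.
#' @export
point_in_region <- function(region, x, y) {
  stopifnot(inherits(region, "region"), length(x) == length(y))
  ins <- pip_ray(x, y, region$outer)
  for (h in region$holes) {
    on_h <- pip_on_edge(x, y, h)
    ins <- ins & (!pip_ray(x, y, h) | on_h)
  }
  ins
}

pip_on_edge <- function(x, y, ring) {
  rx <- ring[, 1]; ry <- ring[, 2]
  n <- length(rx)
  jx <- c(rx[n], rx[-n]); jy <- c(ry[n], ry[-n])
  on_edge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- rx[k]; y1 <- ry[k]; x2 <- jx[k]; y2 <- jy[k]
    cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_edge <- on_edge | (cr == 0 &
                            x >= pmin(x1, x2) & x <= pmax(x1, x2) &
                            y >= pmin(y1, y2) & y <= pmax(y1, y2))
  }
  on_edge
}

#' Regular knot lattice inside a region
#'
#' Lays an axis-aligned lattice of spacing `dx` by `dy` metres over the
#' region bounding box (south-west corner plus `offset`) and keeps the
#' points falling inside the region.  These are the interior knots of the
#' soap-film smoother.
#'
#' @param region a [region()] object.
#' @param dx,dy lattice spacings, metres.
#' @param offset numeric length-2: lattice origin relative to the
#'   bounding-box south-west corner.
#' @return A data.frame with columns `x`, `y`, ordered row-major from the
#'   south-west, with attributes `dx`, `dy`.
#' @export
make_knot_grid <- function(region, dx, dy, offset = c(dx / 2, dy / 2)) {
  stopifnot(inherits(region, "region"), dx > 0, dy > 0, length(offset) == 2)
  bb <- apply(region$outer, 2, range)
  if (bb[1, 1] + offset[1] > bb[2, 1] || bb[1, 2] + offset[2] > bb[2, 2])
    stop("no knots fall inside the region; use a smaller dx/dy spacing")
  xs <- seq(bb[1, 1] + offset[1], bb[2, 1], by = dx)
  ys <- seq(bb[1, 2] + offset[2], bb[2, 2], by = dy)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)  # row-major, SW first
  keep <- point_in_region(region, g$x, g$y)
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0)
    stop("no knots fall inside the region; use a smaller dx/dy spacing")
  rownames(g) <- NULL
  attr(g, "dx") <- dx
  attr(g, "dy") <- dy
  g
}

#' Even arc-length parameterization of the region boundary
#'
#' Returns `m` points evenly spaced by arc length along the outer ring,
#' starting at the first stored vertex (position 0).  Used to evaluate
#' model predictions at even distances around the boundary.
#'
#' @param region a [region()] object.
#' @param m number of points, at least 3.
#' @return A data.frame with columns `s` (arc-length position, metres,
#'   in `[0, L)`), `x`, `y`; attribute `L` is the total perimeter.
#' @export
parameterize_boundary <- function(region, m) {
  stopifnot(inherits(region, "region"), m >= 3)
  ring <- region$outer
  n <- nrow(ring)
  seg <- ring[c(2:n, 1), , drop = FALSE] - ring
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  L <- cum[n + 1]
  s <- L * (seq_len(m) - 1) / m
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[idx]) / len[idx]
  out <- data.frame(
    s = s,
    x = ring[idx, 1] + frac * seg[idx, 1],
    y = ring[idx, 2] + frac * seg[idx, 2]
  )
  attr(out, "L") <- L
  out
}

#' Rasterize a region to a cell-centre inside mask
#'
#' Discretizes the region bounding box into square cells of side `h` and
#' flags each cell whose centre lies inside the region.  Supports area
#' integration and degenerate-geometry diagnostics; the sum of inside-cell
#' areas approximates the region area to within `2 * h * perimeter`.
#'
#' @param region a [region()] object.
#' @param h cell side, metres.
#' @param max_dim maximum allowed number of cells along either axis.
#' @return A list of class `raster_mask`: `origin` (bounding-box SW corner),
#'   `h`, `nx`, `ny`, `inside` (`ny` x `nx` logical matrix, row 1 = southern
#'   row), `boundary_cells` (two-column matrix of (row, col) indices of
#'   inside cells with at least one outside 4-neighbour), `area_ha`.
#' @export
rasterize_region <- function(region, h, max_dim = 2000) {
  stopifnot(inherits(region, "region"), h > 0)
  bb <- apply(region$outer, 2, range)
  nx <- ceiling((bb[2, 1] - bb[1, 1]) / h)
  ny <- ceiling((bb[2, 2] - bb[1, 2]) / h)
  if (nx > max_dim || ny > max_dim)
    stop(sprintf("raster would be %d x %d cells (max %d); use a coarser h",
                 ny, nx, max_dim))
  cx <- bb[1, 1] + (seq_len(nx) - 0.5) * h
  cy <- bb[1, 2] + (seq_len(ny) - 0.5) * h
  g <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  ins <- matrix(point_in_region(region, g$x, g$y), nrow = ny, ncol = nx, byrow = TRUE)
  pad <- function(m, r, c) {
    ok <- r >= 1 & r <= ny & c >= 1 & c <= nx
    v <- rep(FALSE, length(r)); v[ok] <- m[cbind(r[ok], c[ok])]; v
  }
  idx <- which(ins, arr.ind = TRUE)
  nb_out <- !pad(ins, idx[, 1] + 1, idx[, 2]) | !pad(ins, idx[, 1] - 1, idx[, 2]) |
    !pad(ins, idx[, 1], idx[, 2] + 1) | !pad(ins, idx[, 1], idx[, 2] - 1)
  structure(list(
    origin = bb[1, ], h = h, nx = nx, ny = ny, inside = ins,
    boundary_cells = idx[nb_out, , drop = FALSE],
    area_ha = sum(ins) * h^2 / 1e4
  ), class = "raster_mask")
}

#' @export
print.raster_mask <- function(x, ...) {
  cat("Raster mask:", x$ny, "x", x$nx, "cells of", x$h, "m;",
      sum(x$inside), "inside,", nrow(x$boundary_cells), "boundary cells;",
      "area", round(x$area_ha, 2), "ha\n")
  invisible(x)
}

## mgcv boundary-loop representation of a region (outer + holes)
as_soap_boundary <- function(region) {
  ring_to_loop <- function(r) list(x = c(r[, 1], r[1, 1]), y = c(r[, 2], r[1, 2]))
  c(list(ring_to_loop(region$outer)), lapply(region$holes, ring_to_loop))
}
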