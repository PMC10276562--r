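# shared small geometries and simulation helpers

unit_square <- function(side = 100) {
  region(cbind(c(0, side, side, 0), c(0, 0, side, side)))
}

holed_square <- function(side = 100, hole = 20) {
  c0 <- (side - hole) / 2
  region(cbind(c(0, side, side, 0), c(0, 0, side, side)),
         holes = list(cbind(c(c0, c0 + hole, c0 + hole, c0),
                            c(c0, c0, c0 + hole, c0 + hole))))
}

circle_region <- function(r = 100, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  region(cbind(r * cos(th), r * sin(th)))
}

## independent point-in-polygon oracle: winding number
winding_inside <- function(ring, x, y) {
  n <- nrow(ring)
  vapply(seq_along(x), function(i) {
    wn <- 0
    for (k in seq_len(n)) {
      p1 <- ring[k, ]; p2 <- ring[if (k == n) 1 else k + 1, ]
      isleft <- (p2[1] - p1[1]) * (y[i] - p1[2]) - (x[i] - p1[1]) * (p2[2] - p1[2])
      if (p1[2] <= y[i]) {
        if (p2[2] > y[i] && isleft > 0) wn <- wn + 1
      } else {
        if (p2[2] <= y[i] && isleft < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, TRUE)
}

## a small convex region + survey for fast DSM tests
small_survey <- function(seed = 1, n_side = 8, family_theta = Inf,
                         amplitude = 2, baseline = 0.4) {
  set.seed(seed)
  reg <- region(cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000)))
  pts <- expand.grid(x = seq(150, 1850, length.out = n_side),
                     y = seq(150, 1850, length.out = n_side))
  pts$point_id <- sprintf("q%02d", seq_len(nrow(pts)))
  surf <- intensity_surface(reg, components = list(
    list(amplitude = amplitude, centre = c(700, 700), sd = c(400, 400))
  ), baseline = baseline)
  sv <- simulate_survey(surf, pts, list(key = "hn", sigma = 30),
                        w_max = 58, theta = family_theta, seed = seed)
  sv
}

small_soap_spec <- function(reg, nmax = 60, k_boundary = 10, spacing = 300) {
  smoother_spec("soap", region = reg,
                knots = make_knot_grid(reg, spacing, spacing),
                k_boundary = k_boundary, nmax = nmax)
}
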