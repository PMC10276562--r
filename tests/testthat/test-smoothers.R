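# basis construction and boundary behaviour of the two smoothers

test_that("TPRS basis exposes k-1 free coefficients and a linear null space", {
  set.seed(71)
  pts <- data.frame(x = runif(300) * 1000, y = runif(300) * 1000)
  bs <- build_smoother(smoother_spec("tprs", k = 127), pts)
  expect_equal(ncol(bs$design), 126)

  bs2 <- build_smoother(smoother_spec("tprs", k = 20), pts)
  ## unpenalized least-squares fit of a linear surface is exact and lies in
  ## the penalty null space
  z <- 2 + 0.003 * pts$x - 0.001 * pts$y
  A <- cbind(1, bs2$design)
  cf <- qr.solve(qr(A), z)
  expect_equal(drop(A %*% cf), z, tolerance = 1e-8)
  S <- bs2$terms$tprs$penalty
  bend <- drop(t(cf[-1]) %*% S %*% cf[-1])
  expect_lt(bend / max(diag(S)), 1e-8)
  ## penalty is symmetric PSD
  expect_equal(S, t(S), tolerance = 1e-10)
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("richer TPRS bases fit a curved surface better", {
  set.seed(72)
  pts <- expand.grid(x = seq(100, 900, length.out = 5),
                     y = seq(100, 900, length.out = 5))
  z <- 1 + ((pts$x - 500) / 400)^2 + ((pts$y - 400) / 400)^2
  rss <- vapply(c(5, 10), function(k) {
    bs <- build_smoother(smoother_spec("tprs", k = k), pts)
    A <- cbind(1, bs$design)
    sum((z - A %*% qr.solve(qr(A), z))^2)
  }, 0)
  expect_lt(rss[2], rss[1])
})

test_that("soap specification validates its inputs", {
  reg <- unit_square(2000)
  expect_error(smoother_spec("soap", region = NULL), "requires a region")
  expect_error(smoother_spec("soap", region = reg,
                             knots = data.frame(x = 5000, y = 5000)),
               "inside the region")
  expect_error(smoother_spec("tprs", k = 2), "k >= 3")
  kn <- make_knot_grid(reg, 300, 300)
  spec <- smoother_spec("soap", region = reg, knots = kn, nmax = 60)
  out <- data.frame(x = c(100, 5000), y = c(100, 100))
  expect_error(build_smoother(spec, out), "outside the region")
})

test_that("the soap film vanishes on the boundary and decays toward it", {
  set.seed(73)
  reg <- unit_square(2000)
  spec <- small_soap_spec(reg)
  pts <- data.frame(x = runif(120, 100, 1900), y = runif(120, 100, 1900))
  bs <- build_smoother(spec, pts)

  bp <- parameterize_boundary(reg, 200)
  X <- smoother_predict_matrix(bs, bp[, c("x", "y")])
  nb <- ncol(bs$terms$boundary$design)
  film_cols <- (nb + 1):ncol(X)
  expect_false(anyNA(X))
  colmax <- apply(abs(bs$terms$film$design), 2, max)
  expect_lt(max(t(abs(t(X[, film_cols])) / colmax)), 1e-6)

  ## film magnitude grows away from the boundary
  mean_mag <- vapply(c(30, 150, 500), function(d) {
    p <- nudge_inward(reg, bp[, c("x", "y")], step = d)
    mean(abs(mgcv::PredictMat(bs$terms$film$smooth, p)))
  }, 0)
  expect_true(all(diff(mean_mag) > 0))
})

test_that("a constant boundary function extends to a constant film (harmonic extension)", {
  set.seed(74)
  reg <- unit_square(2000)
  spec <- small_soap_spec(reg)
  pts <- data.frame(x = runif(100, 100, 1900), y = runif(100, 100, 1900))
  bs <- build_smoother(spec, pts)
  bp <- parameterize_boundary(reg, 120)
  Xb <- smoother_predict_matrix(bs, bp[, c("x", "y")])[, seq_len(ncol(bs$terms$boundary$design))]
  A <- cbind(1, Xb)
  cf <- qr.solve(qr(A), rep(1, nrow(A)))
  expect_lt(max(abs(A %*% cf - 1)), 1e-8)
  ## interior evaluation of the same combination stays 1
  interior <- make_knot_grid(reg, 250, 250)
  Xi <- smoother_predict_matrix(bs, interior)[, seq_len(ncol(Xb))]
  vi <- drop(cbind(1, Xi) %*% cf)
  expect_lt(max(abs(vi - 1)), 1e-6)
})

test_that("boundary-extension columns are discretely harmonic, film columns are not", {
  set.seed(75)
  reg <- unit_square(2000)
  spec <- small_soap_spec(reg)
  pts <- data.frame(x = runif(100, 100, 1900), y = runif(100, 100, 1900))
  bs <- build_smoother(spec, pts)
  ## 5-point Laplacian stencil at interior probes, h larger than the PDE cell
  probes <- expand.grid(x = seq(400, 1600, by = 200), y = seq(400, 1600, by = 200))
  h <- 100
  lap <- function(smooth) {
    v0 <- mgcv::PredictMat(smooth, probes)
    vE <- mgcv::PredictMat(smooth, transform(probes, x = x + h))
    vW <- mgcv::PredictMat(smooth, transform(probes, x = x - h))
    vN <- mgcv::PredictMat(smooth, transform(probes, y = y + h))
    vS <- mgcv::PredictMat(smooth, transform(probes, y = y - h))
    res <- vE + vW + vN + vS - 4 * v0
    mean(abs(res)) / mean(abs(v0))
  }
  lap_bnd <- lap(bs$terms$boundary$smooth)
  lap_film <- lap(bs$terms$film$smooth)
  expect_lt(lap_bnd, lap_film / 5)   # film columns carry Poisson sources
})

test_that("penalties of the soap components are symmetric PSD", {
  set.seed(76)
  reg <- unit_square(2000)
  bs <- build_smoother(small_soap_spec(reg),
                       data.frame(x = runif(80, 100, 1900),
                                  y = runif(80, 100, 1900)))
  for (tm in bs$terms) {
    S <- tm$penalty
    expect_equal(S, t(S), tolerance = 1e-8)
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8 * max(abs(S)))
  }
})

test_that("evaluate_smoother is a design-matrix product with outside-NA contract", {
  set.seed(77)
  reg <- unit_square(2000)
  spec <- small_soap_spec(reg)
  pts <- data.frame(x = runif(60, 100, 1900), y = runif(60, 100, 1900))
  bs <- build_smoother(spec, pts)
  p <- ncol(bs$design)
  ## zero coefficients give zeros
  expect_equal(evaluate_smoother(bs, rep(0, p), pts), rep(0, nrow(pts)))
  ## at the data points, evaluation equals the design-matrix product
  cf <- rnorm(p)
  expect_equal(evaluate_smoother(bs, cf, pts), drop(bs$design %*% cf),
               tolerance = 1e-10)
  ## outside: NA, never an extrapolated number; strict mode errors
  v <- evaluate_smoother(bs, cf, data.frame(x = 5000, y = 5000))
  expect_true(is.na(v))
  expect_error(evaluate_smoother(bs, cf, data.frame(x = 5000, y = 5000),
                                 strict = TRUE), "outside")
  expect_error(evaluate_smoother(bs, cf[-1], pts), "does not match")
})

test_that("grid refinement gives converging film evaluations", {
  set.seed(78)
  reg <- unit_square(2000)
  pts <- data.frame(x = runif(80, 100, 1900), y = runif(80, 100, 1900))
  probes <- data.frame(x = runif(50, 300, 1700), y = runif(50, 300, 1700))
  kn <- make_knot_grid(reg, 400, 400)
  ev <- lapply(c(40, 80, 160), function(nm) {
    bs <- build_smoother(smoother_spec("soap", region = reg, knots = kn,
                                       k_boundary = 10, nmax = nm), pts)
    mgcv::PredictMat(bs$terms$film$smooth, probes)
  })
  d1 <- mean(abs(ev[[2]] - ev[[1]]))
  d2 <- mean(abs(ev[[3]] - ev[[2]]))
  expect_lt(d2, d1)
})

test_that("soap and TPRS agree away from the boundary", {
  ## noiseless samples of a smooth surface on a convex region: interior
  ## predictions from the two smoothers should be close
  set.seed(79)
  reg <- unit_square(2000)
  pts <- expand.grid(x = seq(150, 1850, length.out = 12),
                     y = seq(150, 1850, length.out = 12))
  z <- sin(pts$x / 600) + cos(pts$y / 500)
  fit_pred <- function(spec) {
    bs <- build_smoother(spec, pts)
    A <- cbind(1, bs$design)
    cf <- qr.solve(qr(A), z)
    probes <- expand.grid(x = seq(500, 1500, by = 125),
                          y = seq(500, 1500, by = 125))
    drop(cbind(1, smoother_predict_matrix(bs, probes)) %*% cf)
  }
  p_soap <- fit_pred(small_soap_spec(reg, nmax = 80, spacing = 250))
  p_tprs <- fit_pred(smoother_spec("tprs", k = 60))
  expect_lt(sqrt(mean((p_soap - p_tprs)^2)), 0.1 * sd(z))
})
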