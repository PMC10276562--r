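# stage-2 count model: fitting, oracles, diagnostics

test_that("intercept-only Poisson fit reproduces the GLM closed form", {
  set.seed(81)
  cnt <- rpois(40, 2)
  xy <- data.frame(x = runif(40) * 100, y = runif(40) * 100)
  nu <- runif(40, 5000, 9000)
  f <- fit_dsm(cnt, xy, nu, smoother = NULL, family = "poisson")
  expect_equal(unname(exp(coef(f)[1])), sum(cnt) / sum(nu), tolerance = 1e-10)
})

test_that("input validation catches degenerate count data", {
  xy <- data.frame(x = 1:10, y = 1:10)
  expect_error(fit_dsm(rep(0, 10), xy, 1000, NULL), "all counts are zero")
  expect_error(fit_dsm(c(-1, rep(1, 9)), xy, 1000, NULL), "non-negative")
  expect_error(fit_dsm(c(0.5, rep(1, 9)), xy, 1000, NULL), "non-negative")
  expect_error(fit_dsm(rep(1, 10), data.frame(x = rep(1, 10), y = rep(1, 10)),
                       1000, NULL), "distinct")
})

test_that("unpenalized fit matches an independent IRLS implementation", {
  sv <- small_survey(seed = 82)
  cnt <- counts_per_point(sv$records, sv$points, 58)
  xy <- sv$points[, c("x", "y")]
  nu <- effective_area(0.7, 58)
  f <- fit_dsm(cnt, xy, nu, smoother_spec("tprs", k = 12),
               family = "poisson", sp = 0)
  X <- predict(f, newdata = xy, type = "lpmatrix")
  g <- glm.fit(X, cnt, family = poisson(),
               offset = rep(log(nu), length(cnt)))
  expect_equal(unname(coef(f)), unname(g$coefficients), tolerance = 1e-6)
})

test_that("infinite smoothing shrinks terms to their null space", {
  sv <- small_survey(seed = 83)
  cnt <- counts_per_point(sv$records, sv$points, 58)
  xy <- sv$points[, c("x", "y")]
  spec <- small_soap_spec(sv$region, nmax = 50, spacing = 400)
  f <- fit_dsm(cnt, xy, 6000, spec, family = "poisson", sp = c(1e9, 1e9))
  expect_lt(unname(f$edf["film"]), 0.01)
  ## cyclic boundary penalty null space is the constant, which the
  ## centering constraint removes: the whole surface collapses to the mean
  eta <- predict(f, newdata = xy, type = "link")
  expect_lt(diff(range(eta)), 0.02)
})

test_that("negative binomial with huge dispersion reproduces the Poisson fit", {
  sv <- small_survey(seed = 84, family_theta = Inf)
  cnt <- counts_per_point(sv$records, sv$points, 58)
  xy <- sv$points[, c("x", "y")]
  spec <- smoother_spec("tprs", k = 15)
  fp <- fit_dsm(cnt, xy, 6000, spec, family = "poisson")
  fn <- fit_dsm(cnt, xy, 6000, spec, family = "nb", theta = 1e6)
  expect_equal(unname(coef(fp)), unname(coef(fn)), tolerance = 1e-4)
})

test_that("rescaling the offset shifts only the intercept", {
  sv <- small_survey(seed = 85)
  cnt <- counts_per_point(sv$records, sv$points, 58)
  xy <- sv$points[, c("x", "y")]
  spec <- smoother_spec("tprs", k = 15)
  f1 <- fit_dsm(cnt, xy, 6000, spec, family = "poisson", sp = 1)
  f2 <- fit_dsm(cnt, xy, 6000 * 7, spec, family = "poisson", sp = 1)
  expect_equal(unname(coef(f2)[1]), unname(coef(f1)[1]) - log(7), tolerance = 1e-7)
  d1 <- predict(f1, newdata = xy, type = "link")
  d2 <- predict(f2, newdata = xy, type = "link") + log(7)
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("per-term EDF decreases as the smoothing parameter grows", {
  sv <- small_survey(seed = 86)
  cnt <- counts_per_point(sv$records, sv$points, 58)
  xy <- sv$points[, c("x", "y")]
  spec <- smoother_spec("tprs", k = 20)
  edfs <- vapply(c(1e-4, 1e-1, 1e2, 1e5), function(l) {
    unname(fit_dsm(cnt, xy, 6000, spec, family = "poisson", sp = l)$edf["tprs"])
  }, 0)
  expect_true(all(diff(edfs) < 0))
})

test_that("REML-selected smoothing beats the extremes out of sample", {
  set.seed(87)
  n_rep <- 8
  wins0 <- winsInf <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sv <- small_survey(seed = 870 + i, n_side = 9)
    cnt <- counts_per_point(sv$records, sv$points, 58)
    xy <- sv$points[, c("x", "y")]
    spec <- smoother_spec("tprs", k = 25)
    idx <- sample(nrow(xy), 27)            # hold out a third
    tr <- setdiff(seq_len(nrow(xy)), idx)
    mse <- vapply(list(NULL, 0, 1e9), function(l) {
      f <- fit_dsm(cnt[tr], xy[tr, ], 6000, spec, family = "poisson",
                   sp = if (is.null(l)) NULL else l)
      mu_hat <- exp(predict(f, newdata = xy[idx, ], type = "link") + log(6000))
      mean((cnt[idx] - mu_hat)^2)
    }, 0)
    wins0[i] <- mse[1] <= mse[2]
    winsInf[i] <- mse[1] <= mse[3]
  }
  expect_lte(0.5, median(wins0))
  expect_lte(0.5, median(winsInf))
})

test_that("dispersion and surface shape are recovered on synthetic NB surveys", {
  ## two-hotspot 289-point surveys with NB(theta = 10) counts
  n_rep <- 8
  th <- cr <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sv <- hakalau_like_fixture(seed = i)
    cnt <- counts_per_point(sv$records, sv$points, 58)
    xy <- sv$points[, c("x", "y")]
    f <- fit_dsm(cnt, xy, effective_area(0.631, 58),
                 smoother_spec("tprs", k = 60), family = "nb")
    th[i] <- f$theta
    d_true <- surface_density(sv$truth$surface, xy$x, xy$y)
    cr[i] <- cor(log(pmax(d_true, 1e-6)), predict(f, newdata = xy, type = "link"))
  }
  expect_lt(abs(log(median(th) / 10)), log(2))   # within a factor of 2
  expect_gte(median(cr), 0.8)
})

test_that("coefficient posterior machinery is internally consistent", {
  sv <- small_survey(seed = 89)
  cnt <- counts_per_point(sv$records, sv$points, 58)
  f <- fit_dsm(cnt, sv$points[, c("x", "y")], 6000,
               smoother_spec("tprs", k = 10), family = "poisson")
  V <- vcov(f)
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_true(all(f$edf >= 0))
  expect_gte(deviance_explained(f), 0)
  expect_lte(deviance_explained(f), 1)
  B <- simulate(f, nsim = 500, seed = 4)
  expect_equal(dim(B), c(500L, length(coef(f))))
  expect_equal(unname(colMeans(B)), unname(coef(f)), tolerance = 0.2)
})

test_that("deviance explained matches direct computation and its limits", {
  sv <- small_survey(seed = 90)
  cnt <- counts_per_point(sv$records, sv$points, 58)
  xy <- sv$points[, c("x", "y")]
  f0 <- fit_dsm(cnt, xy, 6000, NULL, family = "poisson")
  expect_equal(deviance_explained(f0), 0, tolerance = 1e-10)
  f <- fit_dsm(cnt, xy, 6000, smoother_spec("tprs", k = 15), family = "poisson")
  expect_equal(deviance_explained(f),
               1 - deviance(f$engine) / f$engine$null.deviance,
               tolerance = 1e-12)
  ## saturated-capacity unpenalized fit approaches 1
  set.seed(901)
  xy8 <- data.frame(x = runif(8) * 1000, y = runif(8) * 1000)
  fs <- fit_dsm(c(5L, 9L, 1L, 14L, 3L, 8L, 2L, 11L), xy8, 6000,
                smoother_spec("tprs", k = 8), family = "poisson", sp = 0)
  expect_gt(deviance_explained(fs), 0.95)
})

test_that("residual refit flags structure and passes white noise", {
  set.seed(91)
  sv <- small_survey(seed = 91, n_side = 9)
  cnt <- counts_per_point(sv$records, sv$points, 58)
  xy <- sv$points[, c("x", "y")]
  f <- fit_dsm(cnt, xy, 6000, smoother_spec("tprs", k = 25), family = "poisson")
  ## white-noise refits: REML shrinks the refit to (near) zero EDF in the
  ## clear majority of replicates, and the typical (median) EDF is zero
  set.seed(911)
  tot <- replicate(50, {
    sum(residual_refit_check(f, residuals = rnorm(nrow(xy)))$refit_edf)
  })
  expect_gte(mean(tot < 1), 0.6)
  expect_lt(median(tot), 0.5)
  ## the model's own residual refit runs and reports per-term EDF
  chk <- residual_refit_check(f)
  expect_true(all(chk$refit_edf >= 0))
  ## a strong injected gradient is detected
  r_grad <- as.numeric(scale(xy$x)) * 2 + rnorm(nrow(xy), 0, 0.3)
  chk_g <- residual_refit_check(f, residuals = r_grad)
  expect_gt(sum(chk_g$refit_edf), 1)
  expect_false(chk_g$pass)
  ## exactly-zero residuals give numerically zero EDF
  chk0 <- residual_refit_check(f, residuals = rep(0, nrow(xy)))
  expect_equal(sum(chk0$refit_edf), 0)
})

test_that("basis adequacy index is near 1 for exchangeable residuals", {
  set.seed(92)
  xy <- data.frame(x = runif(150) * 1000, y = runif(150) * 1000)
  idx <- replicate(100, {
    basis_adequacy_index(list(residuals = rnorm(150), coords = xy))
  })
  expect_gte(mean(idx > 0.8 & idx < 1.2), 0.9)
  ## smooth unmodelled oscillation (wavelength >> nearest-neighbour gap)
  r_osc <- sin(xy$x / 80) + cos(xy$y / 80)
  expect_lt(basis_adequacy_index(list(residuals = r_osc, coords = xy)), 0.8)
  ## constant residuals are degenerate
  expect_warning(
    v <- basis_adequacy_index(list(residuals = rep(2, 150), coords = xy)),
    "degenerate")
  expect_equal(v, 0)
})
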