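test_that("metrics follow their defining formulas", {
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rSquared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(rSquared(c(2, 2), c(1, 2)), "degenerate response")
  expect_equal(rmse(c(3, 0), c(0, 4)), sqrt(25 / 2))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:4, 1:4 + 2), 2)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_equal(rpd(10, 10), 1)
  expect_equal(rpd(20, 10), 2 * rpd(10, 10))
  # sd back-solved from a printed (RMSEp, RPD) pair forward-checks
  expect_equal(rpd(97.96, 54.12), 1.81, tolerance = 1e-3)
  expect_error(rpd(10, 0), "positive")
})

test_that("PLS1 recovers exact relations and matches least squares at full rank", {
  x <- matrix(1:10, 10, 1)
  m <- plsFit(x, 2 * (1:10), 1)
  expect_equal(m@coefficients[1, 1], 2, tolerance = 1e-12)
  expect_equal(rSquared(2 * (1:10), plsPredict(m, x)), 1, tolerance = 1e-12)
  set.seed(5)
  X <- matrix(rnorm(160), 20, 8)
  y <- rnorm(20)
  full <- plsFit(X, y, 8)
  ols <- unname(cbind(1, X) %*% coef(lm(y ~ X)))
  expect_lt(max(abs(plsPredict(full, X) - as.vector(ols))), 1e-8)
  # successive scores orthogonal
  G <- crossprod(full@scores)
  expect_lt(max(abs(G[upper.tri(G)] / sqrt(diag(G)[1]))), 1e-8)
  expect_error(plsFit(X, y, 25), "out of range")
  expect_error(plsFit(X, rep(1, 20), 2), "zero-variance")
})

test_that("internal CV engine agrees with the NIPALS model route", {
  set.seed(6)
  X <- matrix(rnorm(400), 20, 20)
  y <- rnorm(20)
  foldid <- glycospec:::makeFolds(20, 5, 1)
  path <- glycospec:::cpp_cv_rmse_path(X, y, as.integer(foldid), 8L)
  for (lv in c(1, 4, 8)) {
    pred <- numeric(20)
    for (f in 1:5) {
      tr <- foldid != f
      m <- plsFit(X[tr, ], y[tr], lv)
      pred[!tr] <- plsPredict(m, X[!tr, , drop = FALSE], lv)
    }
    expect_equal(path[lv], rmse(y, pred), tolerance = 1e-10)
  }
})

test_that("latent-variable selection minimizes RMSECV", {
  # noiseless rank-3 structure is solved with at most 3 LVs
  set.seed(7)
  T3 <- matrix(rnorm(150), 50, 3)
  P3 <- matrix(rnorm(36), 12, 3)
  X <- T3 %*% t(P3)
  y <- as.vector(T3 %*% c(1, -2, 0.5))
  lv <- selectLV(X, y, max_lv = 8, seed = 1)
  expect_lte(as.integer(lv), 3L)
  expect_lt(attr(lv, "rmsecv")[as.integer(lv)], 1e-6 * sd(y))
  # the returned LV beats every other candidate
  expect_equal(as.integer(lv), which.min(attr(lv, "rmsecv")))
  expect_equal(as.integer(selectLV(X, y, max_lv = 1, seed = 1)), 1L)
})

test_that("SVR honors the epsilon tube, fits smooth signals, ignores scaling", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  y <- rep(5, 50) + runif(50, -0.4, 0.4)
  m <- svrFit(X, y, C = 10, epsilon = 1)
  expect_lt(max(abs(svrPredict(m, X) - 5)), 1 + 0.45)
  xg <- matrix(seq(0, 2 * pi, length.out = 200), ncol = 1)
  ys <- sin(xg[, 1])
  ms <- svrFit(xg, ys, C = 100, epsilon = 0.01, gamma = 1)
  expect_lt(rmse(ys, svrPredict(ms, xg)), 0.1)
  sc <- c(10, 0.1, 5, 2)
  m2 <- svrFit(sweep(X, 2, sc, "*"), y, C = 10, epsilon = 1)
  expect_equal(svrPredict(m, X), svrPredict(m2, sweep(X, 2, sc, "*")),
               tolerance = 1e-10)
  expect_error(svrFit(X, y, C = -1), "C must be")
  expect_error(svrFit(X, y, epsilon = -1), "epsilon must be")
})

test_that("SVR tuning scans the grid and avoids extreme corners", {
  set.seed(9)
  X <- matrix(rnorm(300), 60, 5)
  y <- as.vector(X %*% c(3, -2, 1, 0, 0)) + rnorm(60, 0, 0.5)
  one <- tuneSVR(X, y, C_grid = 10, eps_grid = 0.5)
  expect_equal(one$C, 10)
  expect_equal(one$epsilon, 0.5)
  tb <- tuneSVR(X, y, C_grid = c(1e-4, 1, 10, 1e5),
                eps_grid = c(0.01, 0.5, 1, 50), seed = 2)
  g <- tb$rmsecv
  expect_equal(min(g$rmsecv),
               g$rmsecv[g$C == tb$C & g$epsilon == tb$epsilon])
  expect_false(tb$C %in% c(1e-4, 1e5) && tb$epsilon %in% c(0.01, 50))
})

test_that("LOOCV pools out-of-fold predictions correctly", {
  meanEst <- list(fit = function(X, y) mean(y),
                  predict = function(m, X) rep(m, nrow(X)),
                  label = "mean")
  out <- loocv(matrix(0, 3, 2), c(0, 0, 3), meanEst)
  expect_equal(out$predicted, c(1.5, 1.5, 0))
  expect_equal(rmse(out$actual, out$predicted), sqrt(4.5), tolerance = 1e-12)
  expect_equal(nrow(out), 3L)
  # permuting sample order leaves pooled metrics unchanged
  set.seed(10)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20, 100, 10)
  est <- plsrEstimator(n_lv = 3)
  a <- loocv(X, y, est)
  perm <- sample(20)
  b <- loocv(X[perm, ], y[perm], est)
  expect_equal(rmse(a$actual, a$predicted), rmse(b$actual, b$predicted),
               tolerance = 1e-10)
  expect_error(loocv(X[1:2, ], y[1:2], est), "at least 3")
})

test_that("70:30 split partitions the sample deterministically", {
  sp <- splitTrainTest(210, seed = 3)
  expect_length(sp$train, 147L)
  expect_length(sp$test, 63L)
  expect_setequal(c(sp$train, sp$test), 1:210)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(splitTrainTest(210, seed = 3), sp)
  expect_error(splitTrainTest(5, seed = 1), "at least 10")
})

test_that("evaluateModel emits a consistent metric row", {
  sim <- generateDataset(syntheticConfig(n_per_day = 15, seed = 21))
  X <- spectra(sim$dataset)
  y <- tga(sim$dataset)
  row <- evaluateModel(X, y, plsrEstimator(n_lv = 8),
                       chain = chainFromLabel("1st Derivative"),
                       split_seed = 4)
  expect_equal(row$rpd, row$sd_p / row$rmse_p, tolerance = 1e-9)
  expect_true(row$rmse_cv >= 0 && row$rmse_p >= 0)
  expect_gt(row$r2_cv, 0)   # TGA signal is present at default noise
})
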