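test_that("Mann-Whitney U matches enumeration and the normal approximation", {
  mw <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 1 / 3, tolerance = 1e-12)
  # identical samples: maximal two-sided p
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p.value, 1,
               tolerance = 1e-9)
  # antisymmetry: swapping maps U -> mn - U with the same p
  a <- c(0.3, 1.2, 5); b <- c(0.8, 2.5, 2.5, 4)
  f <- mannWhitneyU(a, b); g <- mannWhitneyU(b, a)
  expect_equal(f$U + g$U, length(a) * length(b))
  expect_equal(f$p.value, g$p.value, tolerance = 1e-12)
  # approximate branch against wilcox.test's tie-corrected normal p
  set.seed(11)
  x <- rnorm(15); y <- rnorm(12, 0.8)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  ours <- mannWhitneyU(x, y)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  expect_error(mannWhitneyU(numeric(0), 1), "empty")
})

test_that("CARS follows the EDF schedule and the argmin contract", {
  bm <- generateBenchmark(n = 120, p = 40, n_informative = 5, seed = 3)
  res <- carsSelect(bm$X, bm$y, n_runs = 30, seed = 5,
                    wavelengths_nm = bm$wavelengths)
  tr <- selectionTrace(res)
  p <- 40; N <- 30
  kdec <- log(p / 2) / (N - 1)
  sched <- pmax(ceiling(exp(kdec) * exp(-kdec * seq_len(N)) * p - 1e-9), 2)
  expect_equal(tr$edf_budget, sched)
  expect_true(all(diff(sched) <= 0))
  expect_equal(sched[1], p)          # run 1 retains everything
  expect_equal(sched[N], 2)          # run N retains two bands
  expect_true(all(diff(tr$retained_counts) <= 0))
  expect_true(all(tr$retained_counts <= sched))
  # the returned subset is the run with minimal recorded RMSECV
  expect_equal(tr$rmsecv[tr$best_run], min(tr$rmsecv))
  expect_setequal(selectedBands(res), tr$subsets[[tr$best_run]])
  expect_true(all(selectedBands(res) %in% seq_len(p)))
  expect_equal(wavelengths(res), bm$wavelengths[selectedBands(res)])
  # determinism
  res2 <- carsSelect(bm$X, bm$y, n_runs = 30, seed = 5,
                     wavelengths_nm = bm$wavelengths)
  expect_identical(selectedBands(res), selectedBands(res2))
})

test_that("backward elimination prunes without ever leaving the initial set", {
  bm <- generateBenchmark(n = 100, p = 20, n_informative = 4, seed = 6)
  res <- backwardEliminate(bm$X, bm$y, initial_bands = 1:20, seed = 7)
  expect_true(all(selectedBands(res) %in% 1:20))
  expect_gte(length(selectedBands(res)), 1L)
  # unconditional acceptance degenerates to a single band
  res_inf <- backwardEliminate(bm$X, bm$y, initial_bands = 1:10,
                               tolerance = Inf, seed = 7)
  expect_length(selectedBands(res_inf), 1L)
  expect_error(backwardEliminate(bm$X, bm$y, initial_bands = 3), ">= 2")
  expect_identical(selectedBands(res),
                   selectedBands(backwardEliminate(bm$X, bm$y, 1:20,
                                                   seed = 7)))
})

test_that("backward elimination separates signal bands from a noise band", {
  kept12 <- removed3 <- logical(10)
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 120
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    y <- x1 + x2 + rnorm(n, 0, 0.3)
    sel <- selectedBands(backwardEliminate(cbind(x1, x2, x3), y, 1:3,
                                           seed = 400 + s))
    kept12[s] <- all(c(1L, 2L) %in% sel)
    removed3[s] <- !(3L %in% sel)
  }
  expect_true(all(kept12))        # signal bands always survive
  expect_gte(sum(removed3), 8L)   # the noise band goes in nearly every run
})

test_that("IRIV classifies bands and shrinks the retained set monotonically", {
  bm <- generateBenchmark(n = 100, p = 12, n_informative = 3, seed = 8)
  res <- irivSelect(bm$X, bm$y, seed = 9, max_lv = 6,
                    wavelengths_nm = bm$wavelengths)
  rounds <- selectionTrace(res)$rounds
  expect_gte(length(rounds), 1L)
  sizes <- vapply(rounds, nrow, integer(1))
  expect_true(all(diff(sizes) <= 0))
  cls <- rounds[[1]]
  expect_setequal(names(cls), c("band", "wavelength_nm", "mean_included",
                                "mean_excluded", "p_value", "class"))
  expect_true(all(cls$class %in% c("strongly_informative",
                                   "weakly_informative", "uninformative",
                                   "interfering")))
  # retained = bands never classified droppable in the last round
  last <- rounds[[length(rounds)]]
  expect_setequal(selectedBands(res),
                  last$band[last$class %in% c("strongly_informative",
                                              "weakly_informative")])
  expect_identical(selectedBands(res),
                   selectedBands(irivSelect(bm$X, bm$y, seed = 9,
                                            max_lv = 6)))
})

test_that("IRIV flags a y-orthogonal pure-noise band as droppable in round one", {
  hits <- logical(20)
  for (s in 1:20) {
    bm <- generateBenchmark(n = 100, p = 10, n_informative = 3,
                            seed = 500 + s)
    set.seed(600 + s)
    z <- rnorm(100, 0, 0.05)                       # band 11: pure noise,
    z <- z - bm$y * sum(bm$y * z) / sum(bm$y^2)    # orthogonal to y
    res <- irivSelect(cbind(bm$X, z), bm$y, seed = 700 + s, max_lv = 6,
                      max_rounds = 1, n_rows = 300)
    cls <- selectionTrace(res)$rounds[[1]]
    hits[s] <- cls$class[cls$band == 11] %in% c("uninformative",
                                                "interfering")
  }
  expect_gte(mean(hits), 0.9)
})
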