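test_that("ENVI round trip is exact for BIL and BSQ", {
  cube <- float32Cube()
  for (il in c("bil", "bsq")) {
    hdr <- file.path(withr::local_tempdir(), paste0("cube_", il, ".hdr"))
    writeENVI(cube, hdr, interleave = il)
    back <- readENVI(hdr)
    expect_identical(back@values, cube@values)
    expect_equal(back@wavelengths, cube@wavelengths, tolerance = 1e-9)
  }
})

test_that("ENVI interleaves agree with explicit index arithmetic", {
  cube <- float32Cube(rows = 3, cols = 4, bands = 2)
  td <- withr::local_tempdir()
  writeENVI(cube, file.path(td, "a.hdr"), "bil")
  writeENVI(cube, file.path(td, "b.hdr"), "bsq")
  readRaw <- function(p) readBin(p, "numeric", n = 24, size = 4,
                                 endian = "little")
  bil <- readRaw(file.path(td, "a.dat"))
  bsq <- readRaw(file.path(td, "b.dat"))
  S <- 4; B <- 2
  for (l in 1:3) for (b in 1:B) for (s in 1:S) {
    v32 <- bil[(l - 1) * B * S + (b - 1) * S + s]
    expect_equal(v32, cube@values[l, s, b], tolerance = 1e-7)
    expect_identical(bsq[(b - 1) * 3 * S + (l - 1) * S + s], v32)
  }
  expect_identical(readENVI(file.path(td, "a.hdr"))@values,
                   readENVI(file.path(td, "b.hdr"))@values)
})

test_that("malformed ENVI headers are rejected with format errors", {
  cube <- float32Cube()
  td <- withr::local_tempdir()
  hdr <- file.path(td, "c.hdr")
  writeENVI(cube, hdr)
  lines <- readLines(hdr)
  # band count disagreeing with the wavelength list
  writeLines(sub("^bands = 5", "bands = 4", lines), hdr)
  expect_error(readENVI(hdr), "does not match wavelength count")
  # unsupported interleave dialect, named in the error
  writeLines(sub("interleave = bil", "interleave = bip", lines), hdr)
  expect_error(readENVI(hdr), "bip")
  # missing wavelength list
  writeLines(grep("wavelength =", lines, invert = TRUE, value = TRUE), hdr)
  expect_error(readENVI(hdr), "wavelength")
})

test_that("reflectance calibration follows (raw - dark)/(white - dark)", {
  w <- Hypercube(array(0.9, c(4, 3, 2)), c(1000, 1100))
  d <- Hypercube(array(0.1, c(4, 3, 2)), c(1000, 1100))
  mk <- function(v) Hypercube(array(v, c(4, 3, 2)), c(1000, 1100))
  expect_true(all(calibrateReflectance(mk(0.9), w, d)@values == 1))
  expect_true(all(calibrateReflectance(mk(0.1), w, d)@values == 0))
  expect_true(all(calibrateReflectance(mk(0.5), w, d)@values == 0.5))
  expect_error(calibrateReflectance(mk(0.5), d, w), "calibration error")
  # affine invariance under a common positive gain
  set.seed(3)
  raw <- Hypercube(array(runif(24, 0.1, 0.9), c(4, 3, 2)), c(1000, 1100))
  g <- 3.7
  scale_cube <- function(cb) Hypercube(cb@values * g, cb@wavelengths)
  r1 <- calibrateReflectance(raw, w, d)@values
  r2 <- calibrateReflectance(scale_cube(raw), scale_cube(w),
                             scale_cube(d))@values
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("Otsu threshold equals the brute-force between-class argmax", {
  img <- matrix(c(rep(0.02, 60), rep(0.5, 40)), 10)
  thr <- otsuThreshold(img)
  expect_gt(thr, 0.02)
  expect_lt(thr, 0.5)
  set.seed(7)
  for (k in 1:5) {
    im <- matrix(c(rnorm(80, 0.1, 0.03), rnorm(60, 0.6, 0.1)), 10)
    expect_equal(otsuThreshold(im), otsuOracle(im), tolerance = 1e-12)
  }
  expect_error(otsuThreshold(matrix(0.5, 4, 4)), "degenerate")
})

test_that("masks recover the simulated tuber and reject empty scenes", {
  cfg <- smallConfig()
  hc <- generateHypercube(140, cfg, seed = 9)
  m <- buildMask(hc$cube)
  expect_setequal(unique(as.vector(m)), c(0L, 1L))
  inter <- sum(m & hc$mask)
  expect_gt(inter / sum(m | hc$mask), 0.95)       # IoU against ground truth
  expect_lt(abs(sum(m) / sum(hc$mask) - 1), 0.05) # area within 5%
  flat_cube <- Hypercube(array(0.02, c(8, 8, 3)), c(1, 2, 3))
  expect_error(buildMask(flat_cube), "degenerate")
})

test_that("mean spectrum averages exactly over the mask", {
  cube <- float32Cube(rows = 4, cols = 3, bands = 5)
  m1 <- matrix(0L, 4, 3); m1[2, 2] <- 1L
  expect_equal(meanSpectrum(cube, m1), cube@values[2, 2, ])
  mall <- matrix(1L, 4, 3)
  expect_equal(meanSpectrum(cube, mall), apply(cube@values, 3, mean))
  m2 <- matrix(0L, 4, 3); m2[1, 1] <- 1L; m2[4, 3] <- 1L
  expect_equal(meanSpectrum(cube, m2),
               (cube@values[1, 1, ] + cube@values[4, 3, ]) / 2)
  expect_error(meanSpectrum(cube, matrix(0L, 4, 3)), "empty mask")
})

test_that("dataset extraction aligns spectra with the reference table", {
  cfg0 <- noiselessConfig()
  cubes <- lapply(c(80, 120, 160),
                  function(t) generateHypercube(t, cfg0, seed = t)$cube)
  masks <- lapply(c(80, 120, 160),
                  function(t) generateHypercube(t, cfg0, seed = t)$mask)
  ref <- data.frame(tga_ppm = c(80, 120, 160), day = c("Day0", "Day7", "Day14"))
  ds <- extractDataset(cubes, ref, masks)
  expect_equal(nrow(spectra(ds)), 3L)
  for (i in 1:3)
    expect_equal(unname(spectra(ds)[i, ]),
                 generateSpectrum(ref$tga_ppm[i], cfg0), tolerance = 1e-12)
  # mismatched wavelength grids abort
  other <- Hypercube(cubes[[1]]@values,
                     wavelengths(cubes[[1]]) + 1)
  expect_error(extractDataset(list(cubes[[1]], other), ref[1:2, ],
                              masks[1:2]), "mismatch")
})

test_that("dataset CSV round trips through the declared column layout", {
  sim <- generateDataset(smallConfig())
  path <- file.path(withr::local_tempdir(), "ds.csv")
  writeSpectra(sim$dataset, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(gsub('"', "", hdr[1:3]), c("sample_id", "day", "tga_ppm"))
  back <- readSpectra(path)
  expect_equal(spectra(back), spectra(sim$dataset), tolerance = 1e-6)
  expect_equal(tga(back), tga(sim$dataset), tolerance = 1e-8)
  expect_equal(as.character(dayGroup(back)),
               as.character(dayGroup(sim$dataset)))
})
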