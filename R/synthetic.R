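#' Configuration for the synthetic SWIR study generator
#'
#' Builds the parameter list that defines the simulated greening-tuber study:
#' three light-exposure day groups (Day 0/7/14) with group TGA means of
#' 97.13, 159.56 and 128.41 ppm, 70 tubers per group, and reflectance spectra
#' on the instrument grid of 169 bands starting at 901.121 nm in steps of
#' 9.527 nm. Spectra follow a physically motivated additive model: a matrix
#' baseline with water/carbohydrate absorption peaks near 976, 1214, 1431,
#' 1781 and 1905 nm, plus TGA-proportional absorptions at the
#' consensus glycoalkaloid-associated bands (1166.3, 1649.3, 1791.4, 2047.1,
#' 2085.0, 2378.5 nm and the 1933.4 nm water region), degraded by
#' multiplicative scatter, a random linear baseline and additive white noise.
#'
#' Peaks are Gaussian in wavelength; `width_nm` is the Gaussian standard
#' deviation. The TGA effect is linear in ppm by default; `tga_nonlin` adds a
#' quadratic distortion for robustness experiments.
#'
#' @param n_per_day tubers per day group (3 groups).
#' @param day_means_ppm group mean TGA (ppm) for Day 0, 7, 14.
#' @param day_sd_ppm within-group TGA spread (ppm); sampling is truncated at 0.
#' @param grid list with `start_nm`, `step_nm`, `n_bands`.
#' @param base_reflectance matrix reflectance level before absorptions.
#' @param matrix_peaks data.frame with `center_nm`, `width_nm`, `depth`.
#' @param tga_peaks data.frame with `center_nm`, `width_nm`, `depth_per_ppm`.
#' @param tga_nonlin quadratic TGA distortion coefficient (default 0, linear).
#' @param scatter_sd sdlog of the lognormal multiplicative gain.
#' @param baseline_slope_sd sd of the additive baseline slope (per nm).
#' @param noise_sd sd of additive white noise (reflectance units).
#' @param image list describing the simulated frame: `rows`, `cols`, ellipse
#'   semi-axes `semi_row`/`semi_col`, `background` reflectance and
#'   `pixel_jitter_sd` (per-pixel multiplicative gain spread).
#' @param seed integer seed used by [generateDataset()].
#' @return validated list of class `"SyntheticConfig"`.
#' @examples
#' cfg <- syntheticConfig(n_per_day = 5, noise_sd = 0)
#' length(wavelengthGrid(cfg))
#' @export
syntheticConfig <- function(
    n_per_day = 70L,
    day_means_ppm = c(97.13, 159.56, 128.41),
    day_sd_ppm = 30,
    grid = list(start_nm = 901.121, step_nm = 9.527, n_bands = 169L),
    base_reflectance = 0.6,
    matrix_peaks = data.frame(
      center_nm = c(976, 1214, 1431, 1781, 1905),
      width_nm = 30,
      depth = c(0.10, 0.08, 0.18, 0.06, 0.25)),
    tga_peaks = data.frame(
      center_nm = c(1166.3, 1649.3, 1791.4, 2047.1, 2085.0, 2378.5, 1933.4),
      width_nm = 20,
      depth_per_ppm = 8e-5),
    tga_nonlin = 0,
    scatter_sd = 0.05,
    baseline_slope_sd = 5e-5,
    noise_sd = 0.005,
    image = list(rows = 64L, cols = 48L, semi_row = 20, semi_col = 14,
                 background = 0.02, pixel_jitter_sd = 0.02),
    seed = 1L) {
  cfg <- list(n_per_day = as.integer(n_per_day),
              day_means_ppm = day_means_ppm, day_sd_ppm = day_sd_ppm,
              grid = grid, base_reflectance = base_reflectance,
              matrix_peaks = matrix_peaks, tga_peaks = tga_peaks,
              tga_nonlin = tga_nonlin, scatter_sd = scatter_sd,
              baseline_slope_sd = baseline_slope_sd, noise_sd = noise_sd,
              image = image, seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
  cfg
}

validateSyntheticConfig <- function(cfg) {
  g <- cfg$grid
  if (is.null(g$n_bands) || g$n_bands < 2)
    stop("invalid config: grid must have n_bands >= 2")
  if (is.null(g$step_nm) || g$step_nm <= 0)
    stop("invalid config: grid step must be positive")
  if (cfg$n_per_day < 1) stop("invalid config: n_per_day must be >= 1")
  if (length(cfg$day_means_ppm) != 3 || any(cfg$day_means_ppm < 0))
    stop("invalid config: day_means_ppm must be three nonnegative values")
  if (cfg$day_sd_ppm < 0) stop("invalid config: day_sd_ppm must be >= 0")
  lo <- g$start_nm
  hi <- g$start_nm + (g$n_bands - 1) * g$step_nm
  centers <- c(cfg$matrix_peaks$center_nm, cfg$tga_peaks$center_nm)
  if (any(centers < lo | centers > hi))
    stop("invalid config: all peak centers must lie within the wavelength grid")
  invisible(TRUE)
}

#' Band-center wavelength grid
#'
#' @param config a [syntheticConfig()] (or any list with a `grid` element).
#' @return numeric vector: `start_nm + k * step_nm` for k = 0..n_bands-1.
#' @examples
#' g <- wavelengthGrid(syntheticConfig())
#' g[169]  # 2501.657
#' @export
wavelengthGrid <- function(config) {
  g <- config$grid
  if (is.null(g$n_bands) || g$n_bands < 2 || is.null(g$step_nm) ||
      g$step_nm <= 0)
    stop("invalid config: need n_bands >= 2 and a positive step")
  g$start_nm + (seq_len(g$n_bands) - 1) * g$step_nm
}

gaussPeak <- function(lambda, center, width) {
  exp(-(lambda - center)^2 / (2 * width^2))
}

# summed matrix / TGA absorption profiles on the grid
matrixProfile <- function(config) {
  lambda <- wavelengthGrid(config)
  pk <- config$matrix_peaks
  rowSums(mapply(function(c0, w, d) d * gaussPeak(lambda, c0, w),
                 pk$center_nm, pk$width_nm, pk$depth))
}

tgaProfile <- function(config) {
  lambda <- wavelengthGrid(config)
  pk <- config$tga_peaks
  rowSums(mapply(function(c0, w, d) d * gaussPeak(lambda, c0, w),
                 pk$center_nm, pk$width_nm, pk$depth_per_ppm))
}

#' Simulate one tuber reflectance spectrum
#'
#' R(lambda) = clip( g * [R0 + b (lambda - mean) - matrix absorptions -
#' tga_eff * TGA absorptions] + noise, 0, 1.2 ) with gain
#' g ~ lognormal(0, scatter_sd), slope b ~ N(0, baseline_slope_sd) and white
#' noise ~ N(0, noise_sd). With all three spreads zero the output is
#' deterministic. Uses R's global RNG; seed upstream for reproducibility.
#'
#' @param tga_ppm nonnegative TGA concentration.
#' @param config a [syntheticConfig()].
#' @param parts return the deterministic parts alongside the spectrum.
#' @return reflectance vector (length n_bands), or a list when `parts = TRUE`.
#' @export
generateSpectrum <- function(tga_ppm, config, parts = FALSE) {
  if (tga_ppm < 0) stop("tga_ppm must be nonnegative")
  lambda <- wavelengthGrid(config)
  g <- if (config$scatter_sd > 0) rlnorm(1, 0, config$scatter_sd) else 1
  b <- if (config$baseline_slope_sd > 0)
    rnorm(1, 0, config$baseline_slope_sd) else 0
  eps <- if (config$noise_sd > 0)
    rnorm(length(lambda), 0, config$noise_sd) else 0
  tga_eff <- tga_ppm * (1 + config$tga_nonlin * tga_ppm)
  clean <- g * (config$base_reflectance + b * (lambda - mean(lambda)) -
                matrixProfile(config) - tga_eff * tgaProfile(config))
  r <- pmin(pmax(clean + eps, 0), 1.2)
  if (parts) list(spectrum = r, clean = clean, gain = g, slope = b) else r
}

#' Simulate the full day-group study dataset
#'
#' Draws `3 * n_per_day` tubers: TGA per day group from a normal truncated at
#' zero, then one spectrum per tuber via [generateSpectrum()]. The returned
#' ground truth (per-sample gains, slopes, noiseless spectra and the two
#' absorption profiles) is sufficient to reconstruct every noiseless spectrum.
#'
#' @param config a [syntheticConfig()]; `config$seed` fixes the draw.
#' @return list with `dataset` (a [SpectralDataset]) and `truth`.
#' @examples
#' sim <- generateDataset(syntheticConfig(n_per_day = 4, seed = 7))
#' dim(spectra(sim$dataset))
#' @export
generateDataset <- function(config) {
  validateSyntheticConfig(config)
  set.seed(config$seed)
  days <- rep(c(0L, 7L, 14L), each = config$n_per_day)
  mu <- rep(config$day_means_ppm, each = config$n_per_day)
  tga_ppm <- vapply(mu, rtruncnorm0, numeric(1), sd = config$day_sd_ppm)
  n <- length(tga_ppm)
  p <- config$grid$n_bands
  X <- matrix(0, n, p)
  clean <- matrix(0, n, p)
  gains <- numeric(n); slopes <- numeric(n)
  for (i in seq_len(n)) {
    si <- generateSpectrum(tga_ppm[i], config, parts = TRUE)
    X[i, ] <- si$spectrum
    clean[i, ] <- si$clean
    gains[i] <- si$gain
    slopes[i] <- si$slope
  }
  ds <- SpectralDataset(X, wavelengthGrid(config), tga_ppm,
                        day = paste0("Day", days))
  list(dataset = ds,
       truth = list(tga_ppm = tga_ppm, day = days, gains = gains,
                    slopes = slopes, clean = clean,
                    matrix_profile = matrixProfile(config),
                    tga_profile = tgaProfile(config)))
}

# normal truncated at zero by rejection; degenerate sd returns the mean
rtruncnorm0 <- function(mean, sd) {
  if (sd == 0) return(max(mean, 0))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= 0) return(x)
  }
}

#' Simulate a tuber hypercube with its true mask
#'
#' An elliptical "tuber" of per-pixel spectra over a dark flat background.
#' All foreground pixels share one sample-level spectrum from
#' [generateSpectrum()], modulated by a small per-pixel multiplicative gain
#' jitter; background pixels are flat at `image$background` plus the
#' configured white noise.
#'
#' @param tga_ppm TGA concentration of the simulated tuber.
#' @param config a [syntheticConfig()].
#' @param seed optional seed set before drawing.
#' @return list with `cube` (a [Hypercube]) and `mask` (0/1 matrix, 1 on the
#'   ellipse).
#' @export
generateHypercube <- function(tga_ppm, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  im <- config$image
  cr <- (im$rows + 1) / 2
  cc <- (im$cols + 1) / 2
  if (cr - im$semi_row < 1 || cr + im$semi_row > im$rows ||
      cc - im$semi_col < 1 || cc + im$semi_col > im$cols)
    stop("invalid config: ellipse does not fit inside the frame")
  p <- config$grid$n_bands
  s0 <- generateSpectrum(tga_ppm, config)
  rr <- matrix(seq_len(im$rows), im$rows, im$cols)
  cmat <- matrix(seq_len(im$cols), im$rows, im$cols, byrow = TRUE)
  mask <- ((rr - cr) / im$semi_row)^2 + ((cmat - cc) / im$semi_col)^2 <= 1
  mask <- matrix(as.integer(mask), im$rows, im$cols)
  vals <- array(0, c(im$rows, im$cols, p))
  flat <- matrix(vals, im$rows * im$cols, p)
  fg <- which(mask == 1)
  bg <- which(mask == 0)
  jit <- if (im$pixel_jitter_sd > 0)
    1 + rnorm(length(fg), 0, im$pixel_jitter_sd) else rep(1, length(fg))
  flat[fg, ] <- jit %o% s0
  bgnoise <- if (config$noise_sd > 0)
    matrix(rnorm(length(bg) * p, 0, config$noise_sd), length(bg), p) else 0
  flat[bg, ] <- im$background + bgnoise
  flat <- pmin(pmax(flat, 0), 1.2)
  cube <- Hypercube(array(flat, c(im$rows, im$cols, p)),
                    wavelengthGrid(config),
                    meta = list(tga_ppm = tga_ppm, simulated = TRUE))
  list(cube = cube, mask = mask)
}

#' Simulate white and dark reference hypercubes
#'
#' White: a fluoropolymer tile at 99 percent reflectance plus the configured
#' white noise. Dark: closed-shutter counts near zero (noise at one tenth of
#' `noise_sd`). Both share the sample-cube geometry.
#'
#' @param config a [syntheticConfig()].
#' @param seed optional seed set before drawing.
#' @return list with `white` and `dark` [Hypercube]s.
#' @export
generateReferences <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  im <- config$image
  p <- config$grid$n_bands
  nvox <- im$rows * im$cols * p
  wnoise <- if (config$noise_sd > 0) rnorm(nvox, 0, config$noise_sd) else 0
  dnoise <- if (config$noise_sd > 0)
    rnorm(nvox, 0, config$noise_sd / 10) else 0
  w <- array(0.99 + wnoise, c(im$rows, im$cols, p))
  d <- array(0 + dnoise, c(im$rows, im$cols, p))
  g <- wavelengthGrid(config)
  list(white = Hypercube(w, g, meta = list(reference = "white")),
       dark = Hypercube(d, g, meta = list(reference = "dark")))
}

#' Sparse-signal benchmark for wavelength-selection recovery
#'
#' Generates an n x p spectra-like matrix in which exactly `n_informative`
#' bands carry response information, so recovery of the true band set is
#' well posed. Each sample has a latent concentration c ~ N(0, 1); the
#' informative bands respond to it with band-specific coefficients, every
#' band additionally carries smooth low-rank background variation that is
#' independent of c (scatter-like nuisance), plus independent per-band
#' measurement noise. The reference value is y = c. The coefficient scale is
#' set analytically against the per-band noise so the population R-squared
#' of the best linear predictor equals `target_r2` (signal-to-noise ratio
#' target_r2 / (1 - target_r2)); full-spectrum cross-validated R-squared
#' then lands close to that value.
#'
#' @param n,p samples and bands (defaults mirror the study: 210 x 169).
#' @param n_informative number of truly informative bands.
#' @param target_r2 population proportion of response variance explainable
#'   from the spectra.
#' @param noise_sd per-band measurement noise standard deviation.
#' @param seed integer seed.
#' @return list with `X`, `y`, `informative` (sorted band indices),
#'   `beta` (coefficients on the informative bands) and `wavelengths`.
#' @export
generateBenchmark <- function(n = 210L, p = 169L, n_informative = 10L,
                              target_r2 = 0.8, noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  grid <- 901.121 + (seq_len(p) - 1) * 9.527
  # smooth response-independent background: 3 random broad components
  ncmp <- 3L
  scores <- matrix(rnorm(n * ncmp), n, ncmp)
  loadings <- sapply(seq_len(ncmp), function(k) {
    ctr <- runif(1, min(grid), max(grid))
    wd <- runif(1, 300, 800)
    0.1 * exp(-(grid - ctr)^2 / (2 * wd^2))
  })
  informative <- sort(sample.int(p, n_informative))
  beta <- sample(c(-1, 1), n_informative, replace = TRUE) *
    runif(n_informative, 0.8, 1.2)
  # scale so the optimal linear predictor reaches target_r2:
  # SNR = sum(beta^2) / noise_sd^2 = target_r2 / (1 - target_r2)
  beta <- beta * sqrt(target_r2 / (1 - target_r2) * noise_sd^2 /
                        sum(beta^2))
  conc <- rnorm(n)
  signal <- matrix(0, n, p)
  signal[, informative] <- conc %o% beta
  X <- scores %*% t(loadings) + signal +
    matrix(rnorm(n * p, 0, noise_sd), n, p)
  list(X = X, y = conc, informative = informative, beta = beta,
       wavelengths = grid)
}
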