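#' Write a hypercube as an ENVI header + binary pair
#'
#' Supports the dialect the SWIR workflow uses: 32-bit little-endian floats,
#' BIL or BSQ interleave, wavelengths (nm) in the header's `wavelength` list.
#' Values are stored as single-precision floats; the companion binary file
#' replaces the `.hdr` extension with `.dat`.
#'
#' @param cube a [Hypercube].
#' @param header_path path ending in `.hdr`.
#' @param interleave `"bil"` or `"bsq"`.
#' @return invisibly, the header path.
#' @seealso [readENVI()]
#' @export
writeENVI <- function(cube, header_path, interleave = c("bil", "bsq")) {
  interleave <- match.arg(interleave)
  stopifnot(is(cube, "Hypercube"))
  if (!grepl("\\.hdr$", header_path))
    header_path <- paste0(header_path, ".hdr")
  data_path <- sub("\\.hdr$", ".dat", header_path)
  d <- dim(cube@values)
  hdr <- c(
    "ENVI",
    "description = {glycospec hypercube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(sprintf("%.6f", cube@wavelengths), collapse = ", "), "}")
  )
  writeLines(hdr, header_path)
  v <- switch(interleave,
    bil = aperm(cube@values, c(2, 3, 1)),  # sample, band, line
    bsq = aperm(cube@values, c(2, 1, 3)))  # sample, line, band
  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(as.vector(v), con, size = 4L, endian = "little")
  invisible(header_path)
}

#' Read an ENVI header + binary pair into a Hypercube
#'
#' @param header_path path to the `.hdr` file; the binary cube is looked up
#'   at the same path with extension `.dat` (falling back to the extensionless
#'   name).
#' @return a [Hypercube].
#' @export
readENVI <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  txt <- paste(readLines(header_path, warn = FALSE), collapse = "\n")
  getNum <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key, "\\s*=\\s*(\\d+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NA_integer_ else as.integer(m[2])
  }
  samples <- getNum("samples"); lines <- getNum("lines")
  bands <- getNum("bands"); dtype <- getNum("data type")
  border <- getNum("byte order")
  if (anyNA(c(samples, lines, bands)))
    stop("ENVI format error: header must declare samples, lines and bands")
  il <- regmatches(txt, regexec("(?mi)^interleave\\s*=\\s*(\\w+)", txt,
                                perl = TRUE))[[1]]
  if (length(il) < 2)
    stop("ENVI format error: header must declare the interleave")
  interleave <- tolower(il[2])
  if (!interleave %in% c("bil", "bsq"))
    stop("ENVI format error: unsupported interleave '", interleave,
         "' (only BIL and BSQ are supported)")
  if (!is.na(dtype) && dtype != 4L)
    stop("ENVI format error: only data type 4 (float32) is supported")
  if (!is.na(border) && border != 0L)
    stop("ENVI format error: only little-endian (byte order 0) is supported")
  wm <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(wm) < 2)
    stop("ENVI format error: missing wavelength list")
  w <- as.numeric(strsplit(wm[2], ",")[[1]])
  if (anyNA(w)) stop("ENVI format error: unparsable wavelength list")
  if (length(w) != bands)
    stop("ENVI format error: header band count (", bands,
         ") does not match wavelength count (", length(w), ")")
  data_path <- sub("\\.hdr$", ".dat", header_path)
  if (!file.exists(data_path)) data_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(data_path)) stop("ENVI binary file not found")
  con <- file(data_path, "rb")
  on.exit(close(con))
  nvox <- samples * lines * bands
  v <- readBin(con, "numeric", n = nvox, size = 4L, endian = "little")
  if (length(v) != nvox) stop("ENVI format error: truncated binary cube")
  vals <- switch(interleave,
    bil = aperm(array(v, c(samples, bands, lines)), c(3, 1, 2)),
    bsq = aperm(array(v, c(samples, lines, bands)), c(2, 1, 3)))
  Hypercube(vals, w, meta = list(source = header_path,
                                 interleave = interleave))
}

#' Calibrate raw counts to reflectance against white/dark references
#'
#' R = (raw - dark) / (white - dark) per pixel and band, with the white and
#' dark references averaged over their spatial extent per band, then clipped
#' to [0, 1.2]. Scaling all three cubes by a common positive gain leaves the
#' result unchanged.
#'
#' @param raw,white,dark [Hypercube]s on the same wavelength grid.
#' @return a reflectance [Hypercube] with the geometry of `raw`.
#' @export
calibrateReflectance <- function(raw, white, dark) {
  stopifnot(is(raw, "Hypercube"), is(white, "Hypercube"), is(dark, "Hypercube"))
  p <- dim(raw@values)[3]
  if (dim(white@values)[3] != p || dim(dark@values)[3] != p)
    stop("calibration error: band counts differ")
  wbar <- apply(white@values, 3, mean)
  dbar <- apply(dark@values, 3, mean)
  if (any(wbar <= dbar))
    stop("calibration error: white reference <= dark reference at ",
         sum(wbar <= dbar), " band(s)")
  d <- dim(raw@values)
  flat <- matrix(raw@values, d[1] * d[2], p)
  flat <- sweep(sweep(flat, 2, dbar, "-"), 2, wbar - dbar, "/")
  flat <- pmin(pmax(flat, 0), 1.2)
  Hypercube(array(flat, d), raw@wavelengths,
            meta = c(raw@meta, list(calibrated = TRUE)))
}

#' Otsu threshold of an intensity image
#'
#' Candidate thresholds are the 256-bin histogram edges between the image
#' minimum and maximum; the returned threshold is the edge that maximizes the
#' between-class variance w0 * w1 * (mu0 - mu1)^2 of the pixel population
#' split at that edge (ties resolved to the lowest edge). Deterministic.
#'
#' @param img numeric matrix (or vector) of intensities with at least two
#'   distinct values.
#' @return the threshold value.
#' @export
otsuThreshold <- function(img) {
  v <- as.vector(img)
  v <- v[!is.na(v)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate image: constant intensity, no threshold exists")
  edges <- seq(rng[1], rng[2], length.out = 257L)[2:256]
  sv <- sort(v)
  n <- length(sv)
  cs <- cumsum(sv)
  total <- cs[n]
  # pixels strictly below each candidate edge
  n0 <- findInterval(edges, sv, left.open = TRUE)
  valid <- n0 > 0 & n0 < n
  n0 <- n0[valid]; edges <- edges[valid]
  if (length(edges) == 0)
    stop("degenerate image: no admissible split")
  w0 <- n0 / n
  mu0 <- cs[n0] / n0
  mu1 <- (total - cs[n0]) / (n - n0)
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  edges[which.max(bcv)]
}

#' Build a tuber mask from a hypercube
#'
#' Thresholds the band-averaged intensity image with [otsuThreshold()]
#' (foreground = above threshold) and keeps the largest connected foreground
#' component.
#'
#' @param cube a [Hypercube].
#' @return integer 0/1 matrix with the spatial shape of the cube.
#' @export
buildMask <- function(cube) {
  stopifnot(is(cube, "Hypercube"))
  img <- apply(cube@values, c(1, 2), mean)
  thr <- otsuThreshold(img)
  fg <- img > thr
  if (!any(fg)) stop("degenerate image: empty foreground after thresholding")
  lab <- EBImage::bwlabel(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  matrix(as.integer(lab == keep), nrow(fg), ncol(fg))
}

#' Mean spectrum over the masked region
#'
#' @param cube a [Hypercube].
#' @param mask 0/1 matrix with the cube's spatial shape and at least one
#'   foreground pixel.
#' @return reflectance vector, one value per band (mean over foreground
#'   pixels).
#' @export
meanSpectrum <- function(cube, mask) {
  stopifnot(is(cube, "Hypercube"))
  d <- dim(cube@values)
  if (!all(dim(mask) == d[1:2]))
    stop("mask shape must match the cube's spatial shape")
  idx <- which(mask == 1)
  if (length(idx) == 0) stop("empty mask: no foreground pixels")
  flat <- matrix(cube@values, d[1] * d[2], d[3])
  colMeans(flat[idx, , drop = FALSE])
}

#' Extract the n x p analysis matrix from calibrated cubes
#'
#' One mean spectrum per tuber cube, aligned with the reference TGA table.
#'
#' @param cubes list of [Hypercube]s on a common wavelength grid.
#' @param masks list of 0/1 matrices, one per cube (built with [buildMask()]
#'   when omitted).
#' @param ref data.frame with one row per cube: `tga_ppm`, optional
#'   `sample_id`, `day`.
#' @return a [SpectralDataset].
#' @export
extractDataset <- function(cubes, ref, masks = NULL) {
  n <- length(cubes)
  if (nrow(ref) != n)
    stop("reference table must have one row per cube")
  if (is.null(masks)) masks <- lapply(cubes, buildMask)
  w <- wavelengths(cubes[[1]])
  for (i in seq_len(n))
    if (!isTRUE(all.equal(wavelengths(cubes[[i]]), w, tolerance = 1e-9)))
      stop("wavelength grid mismatch across cubes (cube ", i, ")")
  X <- t(vapply(seq_len(n),
                function(i) meanSpectrum(cubes[[i]], masks[[i]]),
                numeric(length(w))))
  SpectralDataset(X, w, ref$tga_ppm,
                  day = if ("day" %in% names(ref)) ref$day else NULL,
                  sample_id = if ("sample_id" %in% names(ref))
                    ref$sample_id else NULL)
}

#' Write / read a SpectralDataset as CSV
#'
#' Columns: `sample_id`, `day`, `tga_ppm`, then one reflectance column per
#' band named by its wavelength in nm.
#'
#' @param ds a [SpectralDataset].
#' @param path CSV path.
#' @return `readSpectra()` returns a [SpectralDataset]; `writeSpectra()` the
#'   path, invisibly.
#' @export
writeSpectra <- function(ds, path) {
  X <- spectra(ds)
  df <- data.frame(sample_id = sampleIds(ds),
                   day = as.character(dayGroup(ds)),
                   tga_ppm = tga(ds), check.names = FALSE)
  Xdf <- as.data.frame(X)
  names(Xdf) <- sprintf("%.6f", wavelengths(ds))
  write.csv(cbind(df, Xdf), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectra
#' @export
readSpectra <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- c("sample_id", "day", "tga_ppm")
  if (!all(meta %in% names(df)))
    stop("dataset CSV must carry sample_id, day and tga_ppm columns")
  wcols <- setdiff(names(df), meta)
  w <- as.numeric(wcols)
  if (anyNA(w)) stop("non-wavelength column in dataset CSV")
  SpectralDataset(as.matrix(df[, wcols]), w, df$tga_ppm, day = df$day,
                  sample_id = df$sample_id)
}

#' Export a mask as a PNG for visual inspection
#'
#' @param mask 0/1 matrix.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
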