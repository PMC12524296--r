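#' Hypercube: a 3-D reflectance image block
#'
#' Rows x cols x bands reflectance array together with its band-center
#' wavelength grid (nm) and free-form acquisition metadata. The SWIR camera
#' emulated here produces 169 bands between 901.121 and 2501.657 nm.
#'
#' @slot values numeric 3-D array, rows x cols x bands.
#' @slot wavelengths numeric vector of band centers (nm), strictly increasing,
#'   one per band.
#' @slot meta list of acquisition metadata.
#'
#' @param values,wavelengths,meta see slots.
#' @return `Hypercube()` returns a validated object.
#' @examples
#' cube <- Hypercube(array(0.5, c(4, 3, 2)), wavelengths = c(1000, 1100))
#' dim(cube)
#' @export Hypercube
#' @exportClass Hypercube
#' @aliases Hypercube
setClass("Hypercube",
  representation(values = "array", wavelengths = "numeric", meta = "list"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a rows x cols x bands array")
    if (d[3] != length(object@wavelengths))
      return("bands dimension must match wavelength count")
    if (length(object@wavelengths) > 1 && any(diff(object@wavelengths) <= 0))
      return("wavelengths must be strictly increasing")
    if (anyNA(object@values)) return("values must not contain NA")
    TRUE
  }
)

Hypercube <- function(values, wavelengths, meta = list()) {
  new("Hypercube", values = values, wavelengths = as.numeric(wavelengths),
      meta = meta)
}

#' @rdname Hypercube-class
#' @export
setMethod("wavelengths", "Hypercube", function(x) x@wavelengths)

#' @rdname Hypercube-class
#' @export
setMethod("dim", "Hypercube", function(x) dim(x@values))

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@values)
  cat(sprintf("Hypercube: %d x %d pixels, %d bands (%.3f-%.3f nm)\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
})

#' SpectralDataset: mean spectra with reference TGA values
#'
#' A \linkS4class{SummarizedExperiment} holding the n x p analysis matrix of
#' per-tuber mean reflectance spectra. The assay `"reflectance"` is stored
#' bands x samples; `rowData` carries the wavelength grid and `colData` the
#' per-sample identifier, light-exposure day group and reference total
#' glycoalkaloid concentration (ppm).
#'
#' `spectra()` returns the samples x bands matrix used by the chemometric
#' functions; `tga()`, `dayGroup()`, `sampleIds()` and `wavelengths()` expose
#' the annotations.
#'
#' @param X numeric samples x bands matrix of reflectance spectra.
#' @param wavelengths_nm numeric band centers (nm), strictly increasing.
#' @param tga_ppm numeric reference TGA per sample (ppm).
#' @param day per-sample day-group label (coerced to factor).
#' @param sample_id character sample identifiers.
#' @param x a `SpectralDataset`.
#' @return `SpectralDataset()` returns a validated object.
#' @examples
#' ds <- SpectralDataset(matrix(runif(6), 2, 3), c(1000, 1100, 1200),
#'                       tga_ppm = c(95, 140))
#' spectra(ds); tga(ds)
#' @export SpectralDataset
#' @exportClass SpectralDataset
#' @aliases SpectralDataset
setClass("SpectralDataset", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
      return("assay 'reflectance' is required")
    A <- SummarizedExperiment::assay(object, "reflectance")
    if (anyNA(A)) return("reflectance matrix must not contain missing values")
    w <- rowData(object)$wavelength_nm
    if (is.null(w)) return("rowData must carry wavelength_nm")
    if (length(w) > 1 && any(diff(w) <= 0))
      return("wavelengths must be strictly increasing")
    cd <- colData(object)
    for (f in c("sample_id", "day", "tga_ppm"))
      if (!f %in% names(cd)) return(paste("colData must carry", f))
    if (anyNA(cd$tga_ppm)) return("tga_ppm must not contain missing values")
    TRUE
  }
)

SpectralDataset <- function(X, wavelengths_nm, tga_ppm, day = NULL,
                            sample_id = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(tga_ppm) != n)
    stop("tga_ppm must have one value per spectrum row")
  if (is.null(sample_id)) sample_id <- sprintf("S%03d", seq_len(n))
  if (is.null(day)) day <- rep(NA_character_, n)
  se <- SummarizedExperiment(
    assays = list(reflectance = t(unname(X))),
    rowData = DataFrame(wavelength_nm = as.numeric(wavelengths_nm)),
    colData = DataFrame(sample_id = as.character(sample_id),
                        day = factor(day),
                        tga_ppm = as.numeric(tga_ppm))
  )
  colnames(se) <- sample_id
  new("SpectralDataset", se)
}

#' @rdname SpectralDataset-class
#' @export
setMethod("spectra", "SpectralDataset", function(x) {
  m <- t(assay(x, "reflectance"))
  dimnames(m) <- list(colData(x)$sample_id,
                      format(rowData(x)$wavelength_nm, trim = TRUE))
  m
})

#' @rdname SpectralDataset-class
#' @export
setMethod("wavelengths", "SpectralDataset",
          function(x) rowData(x)$wavelength_nm)

#' @rdname SpectralDataset-class
#' @export
setMethod("tga", "SpectralDataset", function(x) colData(x)$tga_ppm)

#' @rdname SpectralDataset-class
#' @export
setMethod("dayGroup", "SpectralDataset", function(x) colData(x)$day)

#' @rdname SpectralDataset-class
#' @export
setMethod("sampleIds", "SpectralDataset", function(x) colData(x)$sample_id)

setMethod("show", "SpectralDataset", function(object) {
  cat(sprintf(
    "SpectralDataset: %d samples x %d bands (%.3f-%.3f nm), TGA %.1f-%.1f ppm\n",
    ncol(object), nrow(object), min(wavelengths(object)),
    max(wavelengths(object)), min(tga(object)), max(tga(object))))
})

#' PLSModel: a fitted NIPALS partial least squares regression
#'
#' Univariate-response PLS fitted by NIPALS with mean-centering of X and y.
#' Slots hold the per-latent-variable weight, score and loading vectors and
#' the collapsed regression coefficients for every truncation 1..nLV, so
#' predictions at any smaller latent-variable count need no refit.
#'
#' @slot xMeans,yMean centering statistics of the training data.
#' @slot weights,loadings p x A weight and X-loading matrices.
#' @slot yLoadings length-A response loadings.
#' @slot scores n x A orthogonal score matrix.
#' @slot coefficients p x A collapsed coefficients (column a uses a LVs).
#' @slot nLV number of latent variables extracted.
#' @exportClass PLSModel
setClass("PLSModel",
  representation(xMeans = "numeric", yMean = "numeric", weights = "matrix",
                 loadings = "matrix", yLoadings = "numeric",
                 scores = "matrix", coefficients = "matrix",
                 nLV = "integer"),
  validity = function(object) {
    if (object@nLV < 1L) return("nLV must be >= 1")
    if (ncol(object@coefficients) != object@nLV)
      return("coefficient path must have one column per LV")
    TRUE
  }
)

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variables, %d bands\n",
              object@nLV, nrow(object@coefficients)))
})

#' SVMModel: a fitted RBF support-vector regression
#'
#' Thin wrapper around an epsilon-insensitive RBF SVR fit; inputs are
#' standardized by training statistics inside the fit.
#'
#' @slot fit the underlying e1071 svm object.
#' @slot cost,epsilon hyperparameters (regularization C; tube width, ppm).
#' @exportClass SVMModel
setOldClass("svm")
setClass("SVMModel",
  representation(fit = "ANY", cost = "numeric", epsilon = "numeric"),
  validity = function(object) {
    if (object@cost <= 0) return("cost must be > 0")
    if (object@epsilon < 0) return("epsilon must be >= 0")
    TRUE
  }
)

setMethod("show", "SVMModel", function(object) {
  cat(sprintf("SVMModel: RBF eps-regression, C = %g, epsilon = %g ppm\n",
              object@cost, object@epsilon))
})

#' SelectionResult: output of a wavelength-selection run
#'
#' Selected band indices (sorted, 1-based) with their nm values, plus the
#' per-iteration trace needed to replot the selection path: retained counts
#' and RMSECV per sampling run and coefficient magnitudes (CARS), or the
#' per-round classification tables (IRIV), or the per-step RMSECV path (BE).
#'
#' @slot method selector name ("cars", "iriv" or "backward_elimination").
#' @slot selected integer band indices, sorted, nonempty.
#' @slot wavelengths nm values of the selected bands.
#' @slot trace list of per-iteration diagnostics.
#' @slot seed integer seed the run used.
#' @slot settings evaluator settings (folds, max LV, ...).
#' @param x a `SelectionResult`.
#' @export SelectionResult
#' @exportClass SelectionResult
#' @aliases SelectionResult
setClass("SelectionResult",
  representation(method = "character", selected = "integer",
                 wavelengths = "numeric", trace = "list", seed = "integer",
                 settings = "list"),
  validity = function(object) {
    if (length(object@selected) == 0) return("selected set must be nonempty")
    if (is.unsorted(object@selected, strictly = TRUE))
      return("selected indices must be sorted and unique")
    if (any(object@selected < 1)) return("band indices are 1-based")
    if (length(object@wavelengths) != length(object@selected))
      return("wavelengths must align with selected indices")
    TRUE
  }
)

SelectionResult <- function(method, selected, wavelengths, trace = list(),
                            seed = NA_integer_, settings = list()) {
  new("SelectionResult", method = method,
      selected = as.integer(sort(selected)),
      wavelengths = as.numeric(wavelengths), trace = trace,
      seed = as.integer(seed), settings = settings)
}

#' @rdname SelectionResult-class
#' @export
setMethod("selectedBands", "SelectionResult", function(x) x@selected)

#' @rdname SelectionResult-class
#' @export
setMethod("wavelengths", "SelectionResult", function(x) x@wavelengths)

#' @rdname SelectionResult-class
#' @export
setMethod("selectionTrace", "SelectionResult", function(x) x@trace)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s]: %d bands selected (seed %d)\n",
              object@method, length(object@selected), object@seed))
})
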