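#' Published selected-wavelength fixtures
#'
#' The package ships verbatim transcriptions of the study's printed
#' selected-wavelength lists: `"table2"` holds the CARS- and IRIV-selected
#' sets before backward elimination (with their LV counts and
#' cross-validation metrics), `"table3"` the best-feature sets after
#' backward elimination, keyed by selection method and pre-processing label.
#' Because the printed values do not fall exactly on the uniform instrument
#' grid, [nearestBands()] maps them to band indices by nearest wavelength.
#'
#' @param table `"table2"` or `"table3"`.
#' @param method `"CARS"` or `"IRIV"`.
#' @param preprocessing a printed row label, e.g. `"OSC + 1st Derivative"`
#'   (matching is insensitive to case and spacing).
#' @return list with at least `n` and `wavelengths_nm`.
#' @examples
#' length(loadFixture("table3", "CARS", "OSC + 1st Derivative")$wavelengths_nm)
#' @export
loadFixture <- function(table = c("table2", "table3"), method,
                        preprocessing) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, "_selections.json"),
                      package = "glycospec", mustWork = TRUE)
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- function(x) gsub("\\s+", "", tolower(x))
  mkey <- names(fx)[norm(names(fx)) == norm(method)]
  if (length(mkey) != 1)
    stop("unknown method '", method, "'; available: ",
         paste(names(fx), collapse = ", "))
  pkeys <- names(fx[[mkey]])
  pkey <- pkeys[norm(pkeys) == norm(preprocessing)]
  if (length(pkey) != 1)
    stop("unknown pre-processing '", preprocessing, "' for ", mkey,
         " in ", table, "; available: ", paste(pkeys, collapse = ", "))
  fx[[mkey]][[pkey]]
}

#' @rdname loadFixture
#' @param nm numeric wavelengths (nm).
#' @param grid band-center grid to match against (defaults to the 169-band
#'   instrument grid).
#' @return `nearestBands()` returns 1-based band indices.
#' @export
nearestBands <- function(nm, grid = wavelengthGrid(syntheticConfig())) {
  vapply(nm, function(x) which.min(abs(grid - x)), integer(1))
}
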