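#' Configuration of a full experiment grid
#'
#' Bundles everything [runExperiment()] needs: a data source (a
#' [SpectralDataset] or a [syntheticConfig()] to simulate one),
#' the pre-processing chains, selectors and regressors to cross, the
#' evaluation scheme, and one global seed from which all per-stage seeds are
#' derived (stage seed = seed * 1000 + combination index, so every
#' combination is independently reproducible).
#'
#' @param dataset a [SpectralDataset], or NULL to simulate from `synthetic`.
#' @param synthetic a [syntheticConfig()] used when `dataset` is NULL.
#' @param chains character vector of pre-processing labels (parsed by
#'   [chainFromLabel()]).
#' @param selectors subset of `"full"`, `"cars+be"`, `"iriv+be"`.
#' @param regressors subset of `"plsr"`, `"svmr"`.
#' @param max_lv latent-variable ceiling.
#' @param split_fraction training fraction of the random split.
#' @param cars,iriv,be named lists of selector-argument overrides.
#' @param svr list with `C_grid` and `eps_grid` for [tuneSVR()].
#' @param seed global seed (small integer).
#' @return validated list of class `"RunConfig"`.
#' @export
runConfig <- function(dataset = NULL, synthetic = syntheticConfig(),
                      chains = c("None", "1st Derivative"),
                      selectors = "full", regressors = "plsr",
                      max_lv = 15L, split_fraction = 0.7,
                      cars = list(), iriv = list(), be = list(),
                      svr = list(C_grid = c(1, 10, 100, 1000),
                                 eps_grid = c(1, 5, 10, 20)),
                      seed = 1L) {
  if (length(chains) == 0 || length(selectors) == 0 ||
      length(regressors) == 0)
    stop("config needs at least one chain, selector and regressor")
  stopifnot(all(selectors %in% c("full", "cars+be", "iriv+be")),
            all(regressors %in% c("plsr", "svmr")))
  structure(list(dataset = dataset, synthetic = synthetic, chains = chains,
                 selectors = selectors, regressors = regressors,
                 max_lv = as.integer(max_lv),
                 split_fraction = split_fraction, cars = cars, iriv = iriv,
                 be = be, svr = svr, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full experiment grid
#'
#' For every (pre-processing chain) x (selector) x (regressor) combination:
#' pre-process the spectra, select wavelengths (CARS or IRIV followed by
#' backward elimination, or the full spectrum), then evaluate by LOOCV and a
#' random 70:30 split via [evaluateModel()] (pre-processing refit per
#' training set). Selection runs once on the chain-processed full dataset;
#' SVR hyperparameters are tuned once per combination and then frozen.
#' Deterministic given the config seed. A failing combination is recorded in
#' the log and the remaining combinations continue.
#'
#' @param config a [runConfig()].
#' @return list with `table` (one metrics row per combination, the report
#'   table), `selections` (named list of [SelectionResult]s), `log`
#'   (character), and `dataset`.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  ds <- config$dataset
  if (is.null(ds)) {
    syn <- config$synthetic
    syn$seed <- config$seed * 1000L
    ds <- generateDataset(syn)$dataset
  }
  X <- spectra(ds)
  y <- tga(ds)
  wl <- wavelengths(ds)
  grid <- expand.grid(regressor = config$regressors,
                      selector = config$selectors,
                      chain = config$chains, stringsAsFactors = FALSE)
  rows <- list()
  selections <- list()
  logs <- character(0)
  for (i in seq_len(nrow(grid))) {
    combo <- grid[i, ]
    stage_seed <- config$seed * 1000L + i
    key <- paste(combo$selector, combo$chain, combo$regressor, sep = " | ")
    t0 <- Sys.time()
    res <- tryCatch({
      chain <- chainFromLabel(combo$chain)
      Xp <- applyChain(chain, X, y)$train
      sel <- NULL
      bands <- seq_len(ncol(X))
      if (combo$selector == "cars+be") {
        cargs <- modifyList(list(X = Xp, y = y, max_lv = config$max_lv,
                                 seed = stage_seed, wavelengths_nm = wl),
                            config$cars)
        s1 <- do.call(carsSelect, cargs)
        bargs <- modifyList(list(X = Xp, y = y,
                                 initial_bands = selectedBands(s1),
                                 max_lv = config$max_lv,
                                 seed = stage_seed + 1L,
                                 wavelengths_nm = wl), config$be)
        sel <- do.call(backwardEliminate, bargs)
        bands <- selectedBands(sel)
        selections[[paste("cars", combo$chain, sep = " | ")]] <- s1
      } else if (combo$selector == "iriv+be") {
        iargs <- modifyList(list(X = Xp, y = y, max_lv = config$max_lv,
                                 seed = stage_seed, wavelengths_nm = wl),
                            config$iriv)
        s1 <- do.call(irivSelect, iargs)
        bargs <- modifyList(list(X = Xp, y = y,
                                 initial_bands = selectedBands(s1),
                                 max_lv = config$max_lv,
                                 seed = stage_seed + 1L,
                                 wavelengths_nm = wl), config$be)
        sel <- do.call(backwardEliminate, bargs)
        bands <- selectedBands(sel)
        selections[[paste("iriv", combo$chain, sep = " | ")]] <- s1
      }
      if (!is.null(sel)) selections[[key]] <- sel
      if (combo$regressor == "plsr") {
        n_lv <- as.integer(selectLV(Xp[, bands, drop = FALSE], y,
                                    max_lv = config$max_lv,
                                    seed = stage_seed + 2L))
        est <- plsrEstimator(n_lv = n_lv)
        hyper <- sprintf("LV=%d", n_lv)
      } else {
        tune <- tuneSVR(Xp[, bands, drop = FALSE], y,
                        C_grid = config$svr$C_grid,
                        eps_grid = config$svr$eps_grid,
                        seed = stage_seed + 2L)
        est <- svmrEstimator(C = tune$C, epsilon = tune$epsilon)
        hyper <- sprintf("C=%g,eps=%g", tune$C, tune$epsilon)
      }
      met <- evaluateModel(X, y, est, chain = chain, bands = bands,
                           split_seed = stage_seed + 3L)
      cbind(data.frame(selector = combo$selector,
                       preprocessing = chain$label,
                       regressor = toupper(combo$regressor),
                       n_selected = length(bands), hyper = hyper),
            met,
            data.frame(selected_nm = paste(sprintf("%.3f", wl[bands]),
                                           collapse = " ")))
    }, error = function(e) e)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      logs <- c(logs, sprintf("FAIL  %-45s (%.1fs): %s", key, dt,
                              conditionMessage(res)))
    } else {
      logs <- c(logs, sprintf("OK    %-45s (%.1fs)", key, dt))
      rows[[key]] <- res
    }
  }
  if (length(rows) == 0) stop("every combination failed:\n",
                              paste(logs, collapse = "\n"))
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, selections = selections, log = logs, dataset = ds)
}

#' Write / read an experiment report
#'
#' `writeReport()` emits the metrics table as full-precision CSV plus a
#' human-readable markdown rendering, and the selected wavelength lists as
#' JSON. `readReport()` reads the CSV back losslessly.
#'
#' @param result a [runExperiment()] result (or any list with a `table`).
#' @param dir output directory (created if needed).
#' @return `writeReport()` returns the directory invisibly; `readReport()`
#'   the table.
#' @export
writeReport <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- result$table
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  write.csv(out, file.path(dir, "report.csv"), row.names = FALSE,
            quote = TRUE)
  md <- c("# TGA prediction report", "",
          paste("|", paste(names(tab), collapse = " | "), "|"),
          paste("|", paste(rep("---", ncol(tab)), collapse = " | "), "|"),
          vapply(seq_len(nrow(tab)), function(i) {
            vals <- vapply(seq_len(ncol(tab)), function(j) {
              v <- tab[i, j]
              if (is.numeric(v)) sprintf("%.4g", v) else as.character(v)
            }, character(1))
            paste("|", paste(vals, collapse = " | "), "|")
          }, character(1)))
  writeLines(md, file.path(dir, "report.md"))
  if (!is.null(result$selections) && length(result$selections) > 0) {
    sel <- lapply(result$selections, function(s)
      list(method = s@method, bands = s@selected,
           wavelengths_nm = s@wavelengths, seed = s@seed))
    jsonlite::write_json(sel, file.path(dir, "selections.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(result$log))
    writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @rdname writeReport
#' @export
readReport <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "report.csv") else dir
  tab <- read.csv(path, check.names = FALSE, colClasses = "character")
  numcols <- c("n_selected", "r2_cv", "rmse_cv", "r2_c", "rmse_c", "r2_p",
               "rmse_p", "sd_p", "rpd")
  for (cl in intersect(numcols, names(tab))) tab[[cl]] <- as.numeric(tab[[cl]])
  tab
}
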