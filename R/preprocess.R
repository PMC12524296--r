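#' Standard normal variate (SNV)
#'
#' Centers every spectrum (row) to mean zero and scales it to unit sample
#' standard deviation. Idempotent; errors on a constant row.
#'
#' @param X numeric matrix, samples x bands.
#' @return matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  m <- rowMeans(X)
  s <- apply(X, 1, sd)
  if (any(s == 0))
    stop("degenerate spectrum: constant row(s) ",
         paste(head(which(s == 0)), collapse = ", "))
  (X - m) / s
}

#' Savitzky-Golay derivative along the spectral axis
#'
#' Per-row local-polynomial derivative with respect to band index. Edge
#' values come from the asymmetric polynomial fits within the terminal
#' windows, so the filter is exact on polynomials up to `polyorder`
#' everywhere, including the edges.
#'
#' @param X numeric matrix, samples x bands (bands >= window).
#' @param window odd filter length, greater than `polyorder`.
#' @param polyorder fitting polynomial degree.
#' @param order derivative order (1 = first derivative).
#' @return matrix of the same shape.
#' @export
sgDerivative <- function(X, window = 11L, polyorder = 2L, order = 1L) {
  if (window %% 2 == 0) stop("config error: window must be odd")
  if (window <= polyorder)
    stop("config error: window must exceed polyorder")
  if (order < 1 || order > polyorder)
    stop("config error: derivative order must be in 1..polyorder")
  X <- as.matrix(X)
  if (ncol(X) < window)
    stop("config error: spectra must have at least `window` bands")
  t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window, m = order))
}

#' Orthogonal signal correction (OSC)
#'
#' Removes components of X whose scores are orthogonal to the response y.
#' Each component's weight vector is the leading right singular vector of X
#' after projecting X'y out of the weight space, so the training scores are
#' orthogonal to y by construction (not merely to iterative tolerance). The
#' fitted directions are frozen and applied to new spectra without their
#' response.
#'
#' @param X training matrix (samples x bands).
#' @param y training response.
#' @param n_components number of orthogonal components to remove (must be
#'   below the rank of the centered X).
#' @return an object of class `"OSCFit"` with the corrected training matrix
#'   in `$corrected`.
#' @seealso [oscApply()]
#' @export
oscFit <- function(X, y, n_components = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X row count must equal length(y)")
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  rk <- qr(Xc)$rank
  if (n_components >= rk)
    stop("n_components (", n_components, ") must be below rank(X) = ", rk)
  ws <- vector("list", n_components)
  ps <- vector("list", n_components)
  for (k in seq_len(n_components)) {
    v <- as.vector(crossprod(Xc, yc))
    vn2 <- sum(v^2)
    if (vn2 < 1e-300) stop("degenerate OSC: X'y is numerically zero")
    # X with the y-covariant weight direction projected out
    Xp <- Xc - (Xc %*% v) %*% t(v) / vn2
    w <- svd(Xp, nu = 0, nv = 1)$v[, 1]
    w <- w - v * sum(v * w) / vn2   # numerical re-orthogonalization
    w <- w / sqrt(sum(w^2))
    t_sc <- Xc %*% w
    pl <- as.vector(crossprod(Xc, t_sc)) / sum(t_sc^2)
    Xc <- Xc - t_sc %*% t(pl)
    ws[[k]] <- w
    ps[[k]] <- pl
  }
  structure(list(weights = ws, loadings = ps, x_means = xm, y_mean = ym,
                 n_components = n_components,
                 corrected = Xc + rep(xm, each = nrow(Xc))),
            class = "OSCFit")
}

#' @rdname oscFit
#' @param fit a fitted `"OSCFit"`.
#' @param X new spectra to correct (samples x bands).
#' @export
oscApply <- function(fit, X) {
  stopifnot(inherits(fit, "OSCFit"))
  X <- as.matrix(X)
  Xc <- sweep(X, 2, fit$x_means)
  for (k in seq_len(fit$n_components)) {
    t_sc <- Xc %*% fit$weights[[k]]
    Xc <- Xc - t_sc %*% t(fit$loadings[[k]])
  }
  Xc + rep(fit$x_means, each = nrow(Xc))
}

#' Pre-processing chains
#'
#' A chain is an ordered list of steps applied left-to-right, mirroring the
#' labels used in chemometric report tables ("SNV + 1st Derivative",
#' "OSC + 1st derivative", "|1st Der| + SNV", ...). Available steps:
#' `stepNone()`, `stepSNV()`, `stepSG(window, polyorder, order)`, `stepAbs()`
#' (elementwise absolute value, only directly after a derivative) and
#' `stepOSC(n_components)` (at most once per chain; the only step that uses
#' the training response).
#'
#' @param ... step objects.
#' @return a `PreprocessChain` list.
#' @examples
#' ch <- preprocessChain(stepSNV(), stepSG())
#' chainFromLabel("SNV + 1st Derivative")
#' @export
preprocessChain <- function(...) {
  steps <- list(...)
  if (length(steps) == 0) steps <- list(stepNone())
  kinds <- vapply(steps, function(s) s$step, character(1))
  if (sum(kinds == "osc") > 1)
    stop("invalid chain: osc may appear at most once")
  for (i in which(kinds == "abs"))
    if (i == 1 || kinds[i - 1] != "sg")
      stop("invalid chain: abs only immediately after a derivative")
  structure(list(steps = steps, label = chainLabel(kinds, steps)),
            class = "PreprocessChain")
}

#' @rdname preprocessChain
#' @export
stepNone <- function() list(step = "none")

#' @rdname preprocessChain
#' @export
stepSNV <- function() list(step = "snv")

#' @rdname preprocessChain
#' @param window,polyorder,order Savitzky-Golay settings (see
#'   [sgDerivative()]).
#' @export
stepSG <- function(window = 11L, polyorder = 2L, order = 1L) {
  list(step = "sg", window = window, polyorder = polyorder, order = order)
}

#' @rdname preprocessChain
#' @export
stepAbs <- function() list(step = "abs")

#' @rdname preprocessChain
#' @param n_components OSC components to remove.
#' @export
stepOSC <- function(n_components = 1L) {
  list(step = "osc", n_components = n_components)
}

chainLabel <- function(kinds, steps) {
  lab <- vapply(seq_along(kinds), function(i) {
    switch(kinds[i],
           none = "None", snv = "SNV", sg = "1st Derivative",
           abs = "|.|", osc = "OSC", kinds[i])
  }, character(1))
  # the "|1st Der| + SNV" idiom: derivative followed by abs
  out <- character(0)
  i <- 1
  while (i <= length(lab)) {
    if (lab[i] == "1st Derivative" && i < length(lab) && lab[i + 1] == "|.|") {
      out <- c(out, "|1st Derivative|"); i <- i + 2
    } else {
      out <- c(out, lab[i]); i <- i + 1
    }
  }
  paste(out, collapse = " + ")
}

#' @rdname preprocessChain
#' @param label a report-table row label such as `"OSC + 1st derivative"`;
#'   parsing is insensitive to case, spacing and the Der/Derivative
#'   abbreviation.
#' @export
chainFromLabel <- function(label) {
  tok <- strsplit(gsub("\\s+", "", tolower(label)), "+", fixed = TRUE)[[1]]
  steps <- list()
  for (t in tok) {
    t <- sub("^1stderivative$|^1stder$", "sg", t)
    t <- sub("^\\|1stderivative\\|$|^\\|1stder\\|$", "absder", t)
    steps <- c(steps, switch(t,
      none = list(stepNone()),
      snv = list(stepSNV()),
      sg = list(stepSG()),
      osc = list(stepOSC()),
      absder = list(stepSG(), stepAbs()),
      stop("unknown pre-processing token: '", t, "' in label '", label, "'")))
  }
  do.call(preprocessChain, steps)
}

#' Apply a pre-processing chain fold-safely
#'
#' Steps run left-to-right. Response-free steps (SNV, derivative, abs) are
#' applied rowwise and identically to training and test spectra; OSC is
#' fitted on the training rows only and applied frozen to the test rows, so
#' no test-fold response ever enters the transformation.
#'
#' @param chain a [preprocessChain()].
#' @param X_train,y_train training spectra and response.
#' @param X_test optional test spectra.
#' @return list with `train`, `test` (NULL if no test given) and `fits`
#'   (fitted state of response-dependent steps).
#' @export
applyChain <- function(chain, X_train, y_train = NULL, X_test = NULL) {
  stopifnot(inherits(chain, "PreprocessChain"))
  fits <- list()
  for (s in chain$steps) {
    switch(s$step,
      none = NULL,
      snv = {
        X_train <- snv(X_train)
        if (!is.null(X_test)) X_test <- snv(X_test)
      },
      sg = {
        X_train <- sgDerivative(X_train, s$window, s$polyorder, s$order)
        if (!is.null(X_test))
          X_test <- sgDerivative(X_test, s$window, s$polyorder, s$order)
      },
      abs = {
        X_train <- abs(X_train)
        if (!is.null(X_test)) X_test <- abs(X_test)
      },
      osc = {
        if (is.null(y_train))
          stop("chain contains OSC but no training response was given")
        f <- oscFit(X_train, y_train, s$n_components)
        X_train <- f$corrected
        if (!is.null(X_test)) X_test <- oscApply(f, X_test)
        fits <- c(fits, list(f))
      },
      stop("unknown step: ", s$step))
  }
  list(train = X_train, test = X_test, fits = fits)
}
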