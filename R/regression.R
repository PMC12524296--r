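#' Evaluation metrics: R-squared, RMSE, RPD
#'
#' `rSquared` is 1 - sum((y - yhat)^2) / sum((y - mean(y))^2), with the mean
#' taken over the actual values of the evaluated set (cross-validation,
#' calibration or prediction set respectively). `rmse` is
#' sqrt(mean((y - yhat)^2)) in ppm. `rpd` is the residual predictive
#' deviation sd_p / rmse_p: above 2.5 is good, 1.4-1.8 fair.
#'
#' @param actual,predicted aligned numeric vectors (ppm).
#' @return a single number.
#' @examples
#' rSquared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' rmse(c(3, 0), c(0, 4))            # sqrt(25/2)
#' @export
rSquared <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0)
    stop("degenerate response: actual values are all equal")
  1 - sum((actual - predicted)^2) / sst
}

#' @rdname rSquared
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) == 0) stop("empty prediction set")
  stopifnot(length(actual) == length(predicted))
  sqrt(mean((actual - predicted)^2))
}

#' @rdname rSquared
#' @param sd_p standard deviation of the reference values in the prediction
#'   set (ppm).
#' @param rmse_p prediction RMSE (ppm), must be positive.
#' @export
rpd <- function(sd_p, rmse_p) {
  if (rmse_p <= 0) stop("rpd undefined: rmse_p must be positive")
  sd_p / rmse_p
}

#' Fit a NIPALS partial least squares regression (PLS1)
#'
#' Mean-centers X and y and extracts up to `n_lv` orthogonal latent
#' variables by NIPALS; the collapsed coefficient path is stored so
#' [plsPredict()] can predict at any smaller latent-variable count. If the
#' numerical rank is exhausted earlier, the model stops at the last usable
#' component.
#'
#' @param X samples x bands matrix (n >= 2).
#' @param y response (ppm); must not be constant.
#' @param n_lv latent variables, 1 <= n_lv <= min(n - 1, p).
#' @return a [PLSModel].
#' @export
plsFit <- function(X, y, n_lv) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least two samples")
  if (length(y) != n) stop("X row count must equal length(y)")
  if (var(y) == 0) stop("degenerate response: zero-variance y")
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop("n_lv out of range: must be in 1..min(n-1, p) = ", min(n - 1, p))
  f <- cpp_pls1_fit(X, y, as.integer(n_lv))
  new("PLSModel", xMeans = as.vector(f$xmeans), yMean = f$ymean,
      weights = f$weights, loadings = f$loadings,
      yLoadings = as.vector(f$yloadings), scores = f$scores,
      coefficients = f$coef, nLV = as.integer(f$ncomp))
}

#' @rdname plsFit
#' @param model a [PLSModel].
#' @param n_lv_use latent variables to use for prediction (default: all
#'   extracted).
#' @export
plsPredict <- function(model, X, n_lv_use = model@nLV) {
  stopifnot(is(model, "PLSModel"))
  X <- as.matrix(X)
  if (n_lv_use < 1 || n_lv_use > model@nLV)
    stop("n_lv_use out of range")
  b <- model@coefficients[, n_lv_use]
  as.vector(sweep(X, 2, model@xMeans) %*% b) + model@yMean
}

# seeded fold assignment: K roughly equal folds in random order
makeFolds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Choose the PLS latent-variable count by cross-validated RMSE
#'
#' Evaluates LV = 1..`max_lv` by pooled K-fold cross-validation and returns
#' the count with minimal RMSECV (ties to the smallest count). The RMSECV
#' path is attached as attribute `"rmsecv"`.
#'
#' @param X,y data.
#' @param max_lv largest latent-variable count to consider (default 15).
#' @param folds cross-validation folds (5) or `"loo"`.
#' @param seed seed fixing the fold assignment.
#' @return integer LV count with attribute `rmsecv`.
#' @export
selectLV <- function(X, y, max_lv = 15L, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- if (identical(folds, "loo")) n else as.integer(folds)
  max_lv <- min(max_lv, ncol(X), n - ceiling(n / k) - 1)
  if (max_lv < 1) stop("max_lv invalid for this data size")
  foldid <- makeFolds(n, k, seed)
  path <- cpp_cv_rmse_path(X, y, as.integer(foldid), as.integer(max_lv))
  structure(which.min(path), rmsecv = as.vector(path))
}

#' Fit / predict an RBF support-vector regression
#'
#' Epsilon-insensitive support-vector regression with a radial basis
#' function kernel; inputs are standardized by training statistics inside
#' the fit. Deterministic for fixed inputs.
#'
#' @param X,y training data.
#' @param C regularization parameter (> 0).
#' @param epsilon insensitive-tube width (ppm, >= 0).
#' @param gamma RBF kernel width; default 1/ncol(X).
#' @return an [SVMModel].
#' @export
svrFit <- function(X, y, C = 10, epsilon = 5, gamma = NULL) {
  if (C <= 0) stop("invalid hyperparameter: C must be > 0")
  if (epsilon < 0) stop("invalid hyperparameter: epsilon must be >= 0")
  X <- as.matrix(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  # standardize X by training statistics ourselves: e1071's scale=TRUE would
  # also scale y, silently turning epsilon-in-ppm into epsilon-in-sd-units
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    cost = C, epsilon = epsilon, gamma = gamma,
                    scale = FALSE, fitted = FALSE)
  attr(fit, "x_center") <- ctr
  attr(fit, "x_scale") <- scl
  if (fit$tot.nSV == 0) {
    # every target inside the tube: w = 0 is optimal and any intercept in
    # [max(y)-eps, min(y)+eps] is loss-free; take the interval midpoint
    attr(fit, "const_pred") <- mean(range(y))
  }
  new("SVMModel", fit = fit, cost = C, epsilon = epsilon)
}

#' @rdname svrFit
#' @param model an [SVMModel].
#' @export
svrPredict <- function(model, X) {
  stopifnot(is(model, "SVMModel"))
  cp <- attr(model@fit, "const_pred")
  if (!is.null(cp)) return(rep(cp, nrow(as.matrix(X))))
  Xs <- scale(as.matrix(X), center = attr(model@fit, "x_center"),
              scale = attr(model@fit, "x_scale"))
  as.vector(predict(model@fit, Xs))
}

#' Tune SVR hyperparameters on a grid
#'
#' Minimizes pooled K-fold RMSECV over the (C, epsilon) grid. Ties are
#' resolved toward the simpler model: smaller C first, then larger epsilon.
#' The chosen pair is intended to be frozen for every model of a run.
#'
#' @param X,y data.
#' @param C_grid,eps_grid candidate values.
#' @param folds,seed cross-validation setup.
#' @return list with `C`, `epsilon` and the full `rmsecv` grid.
#' @export
tuneSVR <- function(X, y, C_grid = c(1, 10, 100, 1000),
                    eps_grid = c(1, 5, 10, 20), folds = 5L, seed = 1L) {
  if (length(C_grid) == 0 || length(eps_grid) == 0)
    stop("empty hyperparameter grid")
  X <- as.matrix(X)
  n <- nrow(X)
  foldid <- makeFolds(n, folds, seed)
  # simpler-first ordering so which.min's first match is the tie-break
  grid <- expand.grid(epsilon = sort(eps_grid, decreasing = TRUE),
                      C = sort(C_grid))
  score <- vapply(seq_len(nrow(grid)), function(i) {
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- foldid != f
      m <- svrFit(X[tr, , drop = FALSE], y[tr], C = grid$C[i],
                  epsilon = grid$epsilon[i])
      pred[!tr] <- svrPredict(m, X[!tr, , drop = FALSE])
    }
    rmse(y, pred)
  }, numeric(1))
  i <- which.min(score)
  list(C = grid$C[i], epsilon = grid$epsilon[i],
       rmsecv = cbind(grid, rmsecv = score))
}

#' Estimator specifications for cross-validation
#'
#' Small fit/predict closures consumed by [loocv()] and [evaluateModel()].
#' `plsrEstimator(n_lv = NULL)` selects the latent-variable count per
#' training set with [selectLV()]; a fixed `n_lv` skips the selection.
#'
#' @param n_lv fixed latent-variable count, or NULL to select by CV.
#' @param max_lv,folds,seed settings for the inner LV selection.
#' @return list with `fit(X, y)`, `predict(model, X)` and `label`.
#' @export
plsrEstimator <- function(n_lv = NULL, max_lv = 15L, folds = 5L, seed = 1L) {
  list(
    fit = function(X, y) {
      a <- if (is.null(n_lv))
        as.integer(selectLV(X, y, max_lv = max_lv, folds = folds,
                            seed = seed))
      else min(n_lv, ncol(X), nrow(X) - 1)
      plsFit(X, y, a)
    },
    predict = function(model, X) plsPredict(model, X),
    label = "PLSR")
}

#' @rdname plsrEstimator
#' @param C,epsilon,gamma SVR hyperparameters (see [svrFit()]).
#' @export
svmrEstimator <- function(C = 10, epsilon = 5, gamma = NULL) {
  list(fit = function(X, y) svrFit(X, y, C = C, epsilon = epsilon,
                                   gamma = gamma),
       predict = function(model, X) svrPredict(model, X),
       label = "SVMR")
}

#' Leave-one-out cross-validation with fold-safe pre-processing
#'
#' n folds; in each fold the pre-processing chain is refitted on the n-1
#' training spectra (full spectrum), the band subset is then taken, the
#' estimator fitted and the held-out sample predicted. Pooled out-of-fold
#' predictions are returned.
#'
#' @param X samples x bands matrix (full spectrum).
#' @param y response (ppm).
#' @param estimator a [plsrEstimator()] / [svmrEstimator()] style list.
#' @param chain optional [preprocessChain()] refit per fold.
#' @param bands optional band indices used by the model (after
#'   pre-processing).
#' @param leaky_preprocess fit the chain once on the full dataset instead of
#'   per fold (reproduces the common but leakage-prone practice).
#' @return data.frame with `actual` and `predicted` (one row per sample).
#' @export
loocv <- function(X, y, estimator, chain = NULL, bands = NULL,
                  leaky_preprocess = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("LOOCV needs at least 3 samples")
  if (is.null(bands)) bands <- seq_len(ncol(X))
  if (!is.null(chain) && leaky_preprocess) {
    X <- applyChain(chain, X, y)$train
    chain <- NULL
  }
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    Xte <- X[i, , drop = FALSE]
    if (!is.null(chain)) {
      pp <- applyChain(chain, Xtr, ytr, Xte)
      Xtr <- pp$train; Xte <- pp$test
    }
    m <- estimator$fit(Xtr[, bands, drop = FALSE], ytr)
    pred[i] <- estimator$predict(m, Xte[, bands, drop = FALSE])
  }
  data.frame(actual = y, predicted = pred)
}

#' Random 70:30 train/test split
#'
#' @param n sample count (>= 10).
#' @param seed seed fixing the partition.
#' @param fraction training fraction (train size = round(fraction * n)).
#' @return list with disjoint, exhaustive `train` and `test` index vectors.
#' @export
splitTrainTest <- function(n, seed, fraction = 0.7) {
  if (n < 10) stop("split needs at least 10 samples")
  set.seed(seed)
  ntr <- round(fraction * n)
  train <- sort(sample.int(n, ntr))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Evaluate one model configuration: LOOCV plus 70:30 split
#'
#' Computes the full metric row a chemometric report table needs: LOOCV
#' R2cv/RMSEcv on all samples, then a random 70:30 split giving calibration
#' (fitted training) R2c/RMSEc and prediction (held-out) R2p/RMSEp with
#' RPD = sd(test reference) / RMSEp. The pre-processing chain is refit on
#' each training set.
#'
#' @param X,y full-spectrum data.
#' @param estimator a [plsrEstimator()] / [svmrEstimator()] list.
#' @param chain optional [preprocessChain()].
#' @param bands optional selected band indices.
#' @param split_seed seed for the 70:30 partition.
#' @param leaky_preprocess see [loocv()].
#' @return one-row data.frame with r2_cv, rmse_cv, r2_c, rmse_c, r2_p,
#'   rmse_p, sd_p, rpd.
#' @export
evaluateModel <- function(X, y, estimator, chain = NULL, bands = NULL,
                          split_seed = 1L, leaky_preprocess = FALSE) {
  X <- as.matrix(X)
  if (is.null(bands)) bands <- seq_len(ncol(X))
  cv <- loocv(X, y, estimator, chain = chain, bands = bands,
              leaky_preprocess = leaky_preprocess)
  sp <- splitTrainTest(nrow(X), split_seed)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
  if (!is.null(chain)) {
    if (leaky_preprocess) {
      ppX <- applyChain(chain, X, y)$train
      Xtr <- ppX[sp$train, , drop = FALSE]
      Xte <- ppX[sp$test, , drop = FALSE]
    } else {
      pp <- applyChain(chain, Xtr, ytr, Xte)
      Xtr <- pp$train; Xte <- pp$test
    }
  }
  m <- estimator$fit(Xtr[, bands, drop = FALSE], ytr)
  fit_tr <- estimator$predict(m, Xtr[, bands, drop = FALSE])
  pred_te <- estimator$predict(m, Xte[, bands, drop = FALSE])
  rmse_p <- rmse(yte, pred_te)
  sd_p <- sd(yte)
  data.frame(r2_cv = rSquared(cv$actual, cv$predicted),
             rmse_cv = rmse(cv$actual, cv$predicted),
             r2_c = rSquared(ytr, fit_tr),
             rmse_c = rmse(ytr, fit_tr),
             r2_p = rSquared(yte, pred_te),
             rmse_p = rmse_p,
             sd_p = sd_p,
             rpd = rpd(sd_p, rmse_p))
}
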