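#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte Carlo wavelength selection. In each of `n_runs` sampling runs a
#' random subset of samples is drawn, a PLS model is fitted on the currently
#' retained bands, and the normalized coefficient magnitudes
#' w_j = |beta_j| / sum|beta| drive two elimination stages: the exponentially
#' decaying function (EDF) fixes the retention budget ceil(r_i * p) with
#' r_i = a * exp(-k * i) pinned so run 1 retains all p bands and run
#' `n_runs` retains 2, and adaptive reweighted sampling (ARS) fills that
#' budget by weighted sampling without replacement proportional to w
#' (zero-weight bands are never selected). After each run the retained set's
#' pooled K-fold RMSECV on the full sample set is recorded; the retained set
#' of the run with minimal RMSECV is returned.
#'
#' @param X samples x bands matrix (p >= 3).
#' @param y response (ppm).
#' @param n_runs Monte Carlo sampling runs (default 50).
#' @param mc_sample_ratio fraction of samples drawn per run (0.8).
#' @param cv_folds folds of the recorded RMSECV (5).
#' @param max_lv latent-variable ceiling for the internal PLS models (15).
#' @param seed integer seed; the run is deterministic given it.
#' @param wavelengths_nm optional nm values reported for selected bands.
#' @return a [SelectionResult] with trace entries `retained_counts`,
#'   `rmsecv`, `best_lv`, `weights` (p x n_runs, NA once dropped) and
#'   `subsets`.
#' @export
carsSelect <- function(X, y, n_runs = 50L, mc_sample_ratio = 0.8,
                       cv_folds = 5L, max_lv = 15L, seed = 1L,
                       wavelengths_nm = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 3) stop("CARS needs at least 3 bands")
  if (n < cv_folds) stop("CARS needs at least cv_folds samples")
  if (is.null(wavelengths_nm)) wavelengths_nm <- seq_len(p)
  set.seed(seed)
  foldid <- sample(rep(seq_len(cv_folds), length.out = n))
  # EDF constants pinned at (1, p) and (n_runs, 2)
  kdec <- log(p / 2) / (n_runs - 1)
  aconst <- exp(kdec)
  # 1e-9 guard: the pinned endpoints (p and 2) must not ceiling upward
  budget <- pmax(ceiling(aconst * exp(-kdec * seq_len(n_runs)) * p - 1e-9),
                 2L)
  m <- ceiling(mc_sample_ratio * n)
  retained <- seq_len(p)
  counts <- integer(n_runs)
  rmsecv <- numeric(n_runs)
  bestlv <- integer(n_runs)
  wtrace <- matrix(NA_real_, p, n_runs)
  subsets <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    samp <- sample.int(n, m)
    a <- min(max_lv, length(retained), m - 1)
    fit <- plsFit(X[samp, retained, drop = FALSE], y[samp], a)
    b <- abs(fit@coefficients[, fit@nLV])
    w <- b / sum(b)
    wtrace[retained, i] <- w
    budget_i <- min(budget[i], length(retained))
    pos <- w > 0
    if (sum(pos) <= budget_i) {
      retained <- retained[pos]
    } else {
      keep <- sample(seq_along(retained), budget_i, prob = w)
      retained <- sort(retained[keep])
    }
    if (length(retained) < 2) stop("internal invariant violation: EDF budget < 2")
    counts[i] <- length(retained)
    cvres <- cpp_subsets_cv_rmse(X, y, as.integer(foldid),
                                 as.integer(min(max_lv, length(retained))),
                                 list(as.integer(retained)))
    rmsecv[i] <- cvres$rmse[1]
    bestlv[i] <- cvres$best_lv[1]
    subsets[[i]] <- retained
  }
  best <- which.min(rmsecv)
  SelectionResult("cars", subsets[[best]], wavelengths_nm[subsets[[best]]],
                  trace = list(retained_counts = counts, rmsecv = rmsecv,
                               best_lv = bestlv, weights = wtrace,
                               subsets = subsets, best_run = best,
                               edf_budget = budget),
                  seed = seed,
                  settings = list(n_runs = n_runs,
                                  mc_sample_ratio = mc_sample_ratio,
                                  cv_folds = cv_folds, max_lv = max_lv))
}

#' Greedy backward elimination over a cross-validated evaluator
#'
#' Starting from `initial_bands`, repeatedly removes the single band whose
#' removal yields the lowest evaluator RMSECV; a removal is accepted only if
#' that RMSECV does not exceed the current RMSECV by more than `tolerance`
#' (ties in the argmin remove the lowest-index band). Stops otherwise, or at
#' one band.
#'
#' @param X,y data (full spectrum).
#' @param initial_bands starting band set (>= 2 bands).
#' @param tolerance accepted RMSECV worsening per step (0 = only
#'   non-worsening removals; Inf degenerates to the single best band).
#' @param cv_folds,max_lv,seed evaluator settings (pooled K-fold PLS RMSECV,
#'   LV chosen by the path minimum up to `max_lv`, folds fixed by `seed`).
#' @param n_rep fold partitions the evaluator RMSECV is averaged over.
#'   Single-partition comparisons of nested band sets are dominated by
#'   fold-assignment noise; averaging a few partitions makes the greedy
#'   accept/reject decision stable.
#' @param wavelengths_nm optional nm values reported for selected bands.
#' @return a [SelectionResult] with trace entries `rmsecv_path` and
#'   `removed`.
#' @export
backwardEliminate <- function(X, y, initial_bands, tolerance = 0,
                              cv_folds = 5L, max_lv = 15L, seed = 1L,
                              n_rep = 10L, wavelengths_nm = NULL) {
  X <- as.matrix(X)
  initial_bands <- sort(unique(as.integer(initial_bands)))
  if (length(initial_bands) < 2)
    stop("backward elimination needs an initial set of >= 2 bands")
  if (is.null(wavelengths_nm)) wavelengths_nm <- seq_len(ncol(X))
  foldids <- lapply(seq_len(n_rep),
                    function(r) makeFolds(nrow(X), cv_folds,
                                          seed + 7919L * (r - 1L)))
  evalSets <- function(sets) {
    sets <- lapply(sets, as.integer)
    acc <- numeric(length(sets))
    for (fid in foldids)
      acc <- acc + cpp_subsets_cv_rmse(X, y, as.integer(fid),
                                       as.integer(max_lv), sets)$rmse
    acc / length(foldids)
  }
  current <- initial_bands
  base <- evalSets(list(current))[1]
  path <- base
  removed <- integer(0)
  while (length(current) > 1) {
    cand <- lapply(seq_along(current), function(j) current[-j])
    sc <- evalSets(cand)
    j <- which.min(sc)  # first minimum = lowest-index band on ties
    if (sc[j] <= base + tolerance) {
      removed <- c(removed, current[j])
      current <- current[-j]
      base <- sc[j]
      path <- c(path, base)
    } else break
  }
  SelectionResult("backward_elimination", current, wavelengths_nm[current],
                  trace = list(rmsecv_path = path, removed = removed,
                               initial = initial_bands),
                  seed = seed,
                  settings = list(tolerance = tolerance, cv_folds = cv_folds,
                                  max_lv = max_lv))
}

#' Mann-Whitney U test (midrank ties, exact small-sample p)
#'
#' U is computed for the first sample via midranks. For combined sizes
#' m + n <= 12 the two-sided p-value is exact, by enumerating all
#' choose(m+n, m) labelings of the observed (possibly tied) values;
#' otherwise the normal approximation with tie correction is used (no
#' continuity correction).
#'
#' @param a,b nonempty numeric samples.
#' @return list with `U` (statistic of `a`) and `p.value` (two-sided).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mannWhitneyU <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  m <- length(a); n <- length(b)
  v <- c(a, b)
  r <- rank(v)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  if (m + n <= 12) {
    idx <- combn(m + n, m)
    Uall <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
  } else {
    N <- m + n
    ties <- table(v)
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    sig2 <- m * n / 12 * ((N + 1) - tiecor)
    if (sig2 <= 0)
      stop("degenerate samples: zero variance under the null")
    z <- (U - mu) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p.value = p)
}

#' Iteratively retaining informative variables (IRIV)
#'
#' Binary-matrix shuffling filter selection. Each round draws an
#' `n_rows` x p binary inclusion matrix (cells 1 with `inclusion_prob`,
#' at least two inclusions per row); every row's included-band subset is
#' scored by pooled K-fold PLS RMSECV, and for every band the paired
#' column-flip counterpart of every row is scored as well. Band j's
#' inclusion distribution A_j is then compared with its exclusion
#' distribution B_j by a two-sided Mann-Whitney U test and the band is
#' classified: strongly informative (mean(B) > mean(A), p < alpha), weakly
#' informative (mean(B) > mean(A), p >= alpha), uninformative
#' (mean(B) <= mean(A), p >= alpha) or interfering (mean(B) <= mean(A),
#' p < alpha). Uninformative and interfering bands are dropped and the
#' round repeats until nothing is dropped or `max_rounds` is reached.
#'
#' @param X samples x bands matrix (p >= 3).
#' @param y response (ppm).
#' @param n_rows rows of the inclusion matrix per round.
#' @param inclusion_prob probability a cell is 1.
#' @param alpha Mann-Whitney significance level.
#' @param max_rounds round cap.
#' @param cv_folds,max_lv,seed evaluator settings.
#' @param wavelengths_nm optional nm values reported for selected bands.
#' @return a [SelectionResult]; the trace holds one classification
#'   data.frame per round (band, mean RMSECV with/without, p-value, class).
#' @export
irivSelect <- function(X, y, n_rows = 100L, inclusion_prob = 0.5,
                       alpha = 0.05, max_rounds = 10L, cv_folds = 5L,
                       max_lv = 15L, seed = 1L, wavelengths_nm = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 3) stop("IRIV needs at least 3 bands")
  if (is.null(wavelengths_nm)) wavelengths_nm <- seq_len(p)
  set.seed(seed)
  foldid <- sample(rep(seq_len(cv_folds), length.out = n))
  current <- seq_len(p)
  rounds <- list()
  for (round in seq_len(max_rounds)) {
    pc <- length(current)
    M <- matrix(rbinom(n_rows * pc, 1L, inclusion_prob), n_rows, pc)
    short <- rowSums(M) < 2
    while (any(short)) {
      M[short, ] <- rbinom(sum(short) * pc, 1L, inclusion_prob)
      short <- rowSums(M) < 2
    }
    res <- cpp_iriv_round(X[, current, drop = FALSE], y,
                          as.integer(foldid), as.integer(max_lv), M)
    rmse0 <- as.vector(res$rmse0)
    rflip <- res$rmse_flip
    cls <- data.frame(band = current,
                      wavelength_nm = wavelengths_nm[current],
                      mean_included = NA_real_, mean_excluded = NA_real_,
                      p_value = NA_real_, class = NA_character_)
    for (j in seq_len(pc)) {
      incl <- ifelse(M[, j] == 1, rmse0, rflip[, j])
      excl <- ifelse(M[, j] == 1, rflip[, j], rmse0)
      mw <- mannWhitneyU(incl, excl)
      mi <- mean(incl); me <- mean(excl)
      cls$mean_included[j] <- mi
      cls$mean_excluded[j] <- me
      cls$p_value[j] <- mw$p.value
      cls$class[j] <- if (me > mi) {
        if (mw$p.value < alpha) "strongly_informative" else
          "weakly_informative"
      } else {
        if (mw$p.value < alpha) "interfering" else "uninformative"
      }
    }
    rounds[[round]] <- cls
    keep <- cls$class %in% c("strongly_informative", "weakly_informative")
    if (!any(keep))
      stop("IRIV dropped all bands in round ", round)
    dropped <- sum(!keep)
    current <- current[keep]
    if (dropped == 0) break
    if (length(current) < 3) break
  }
  SelectionResult("iriv", current, wavelengths_nm[current],
                  trace = list(rounds = rounds),
                  seed = seed,
                  settings = list(n_rows = n_rows,
                                  inclusion_prob = inclusion_prob,
                                  alpha = alpha, max_rounds = max_rounds,
                                  cv_folds = cv_folds, max_lv = max_lv))
}
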