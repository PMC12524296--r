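# shared fixtures, all generated in code

# small, fast study configuration: few tubers, full 169-band grid
smallConfig <- function(...) {
  syntheticConfig(n_per_day = 5L, seed = 11L, ...)
}

# fully deterministic configuration (no stochastic terms)
noiselessConfig <- function(...) {
  cfg <- syntheticConfig(scatter_sd = 0, baseline_slope_sd = 0, noise_sd = 0,
                         ...)
  cfg$image$pixel_jitter_sd <- 0
  cfg
}

# a small cube with float32-representable values so ENVI round trips are exact
float32Cube <- function(rows = 8, cols = 6, bands = 5, seed = 1) {
  set.seed(seed)
  v <- array(sample(0:255, rows * cols * bands, replace = TRUE) / 256,
             c(rows, cols, bands))
  Hypercube(v, seq(1000, by = 100, length.out = bands))
}

# brute-force Otsu oracle: for every 256-bin histogram edge, split the raw
# pixel population and compute the between-class variance directly
otsuOracle <- function(img) {
  v <- sort(as.vector(img))
  edges <- seq(min(v), max(v), length.out = 257L)[2:256]
  best <- -Inf
  best_edge <- NA_real_
  for (e in edges) {
    lo <- v[v < e]
    hi <- v[v >= e]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-15) {
      best <- bcv
      best_edge <- e
    }
  }
  best_edge
}

# independent Mann-Whitney oracle: enumerate group labelings via recursive
# index enumeration (not combn, which the implementation itself uses)
mwOracle <- function(a, b) {
  v <- c(a, b)
  r <- rank(v)
  m <- length(a); n <- length(b)
  mu <- m * n / 2
  subsets <- function(pool, k) {
    if (k == 0) return(list(integer(0)))
    if (length(pool) < k) return(list())
    c(lapply(subsets(pool[-1], k - 1), function(s) c(pool[1], s)),
      subsets(pool[-1], k))
  }
  Uall <- vapply(subsets(seq_len(m + n), m),
                 function(s) sum(r[s]) - m * (m + 1) / 2, numeric(1))
  Uobs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  list(U = Uobs, p.value = mean(abs(Uall - mu) >= abs(Uobs - mu) - 1e-9))
}
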