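# Independent oracles and fixture builders used across the suite.

# Brute-force decomposition: direct per-bin inner product with the
# kernel, no FFT. The reference the fast path is checked against.
naive_decompose <- function(x, grid) {
  x <- x - mean(x)
  T <- length(x)
  Fq <- length(grid$frequencies)
  power <- matrix(0, T, Fq)
  for (k in seq_len(Fq)) {
    ker <- make_kernel(grid$frequencies[k])
    n <- length(ker$taps)
    ctr <- ker$center_index
    for (t0 in 0:(T - 1)) {
      s <- 0 + 0i
      for (j in 0:(n - 1)) {
        u <- t0 + j - ctr
        if (u >= 0 && u < T) s <- s + x[u + 1] * Conj(ker$taps[j + 1])
      }
      power[t0 + 1, k] <- Mod(s)^2
    }
  }
  power
}

# Wrap a bare power matrix as a tft_map (independent-bin fixtures for
# permutation-test calibration checks).
fake_map <- function(power, f_max = NULL) {
  T <- nrow(power)
  grid <- frequency_grid(T, if (is.null(f_max)) ncol(power) / T else f_max)
  stopifnot(length(grid$frequencies) == ncol(power))
  structure(list(power = power, grid = grid,
                 coi_mask = matrix(FALSE, T, ncol(power)),
                 subject_id = NA_character_),
            class = "tft_map")
}

# Gaussian iid fake maps: n subjects, T x Fq bins.
iid_maps <- function(n, T, Fq, mean = 0, sd = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    fake_map(matrix(rnorm(T * Fq, mean, sd), T, Fq)))
}

# Exhaustive two-sided enumeration p for a single bin, independent
# design: all choose(n, na) relabelings, p = #{|t| >= |t_obs|} / N.
enum_p_independent <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  combs <- combn(length(pool), na)
  tstat <- function(x, y) {
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    (mean(x) - mean(y)) / se
  }
  t_obs <- tstat(a, b)
  t_all <- apply(combs, 2, function(idx)
    tstat(pool[idx], pool[-idx]))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# Exhaustive two-sided sign-flip enumeration p for a paired design.
enum_p_paired <- function(d) {
  np <- length(d)
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  t_obs <- tstat(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), np)))
  t_all <- apply(signs, 1, function(s) tstat(s * d))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# Sessions for a two-group comparison, decomposed. Kept small for speed.
cohort_maps <- function(params_a, params_b, n, seed, f_max = 0.5) {
  spec <- cohort_spec(params_a, params_b, n, n)
  coh <- simulate_cohort(spec, seed = seed)
  grid <- frequency_grid(params_a$T, f_max)
  list(a = lapply(coh$a, decompose, grid = grid),
       b = lapply(coh$b, decompose, grid = grid))
}
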