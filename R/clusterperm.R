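# Two-step nonparametric cluster-based permutation comparison of
# trial x frequency power maps.

# Flatten a list of maps into a B x n matrix (bins x subjects),
# column-major over (trial, frequency) with trial fastest.
stack_maps <- function(maps) {
  g <- check_same_grid(maps)
  X <- vapply(maps, function(m) as.vector(m$power),
              numeric(g$T * length(g$frequencies)))
  list(X = X, grid = g)
}

# Number of distinct relabelings of the design.
n_relabelings <- function(design, na, nb) {
  if (design == "independent") choose(na + nb, na) else 2^na
}

# Compute the (1 + S) x B matrix of t statistics (row 1 = observed
# labeling), the suprathreshold mask per relabeling and the observed
# row's permutation p-values. Group sums across relabelings are BLAS
# matrix products (indicator %*% data), so the per-shuffle cost is a
# dense matrix multiply rather than an R-level loop. Switches to
# exhaustive enumeration when the design admits <= n_shuffle distinct
# relabelings.
perm_t_and_p <- function(maps_a, maps_b, design, n_shuffle, seed,
                         alpha_bin, exclude_coi = FALSE) {
  design <- match.arg(design, c("independent", "paired"))
  if (!is_count(n_shuffle) || n_shuffle < 1) stop("n_shuffle must be >= 1")
  sa <- stack_maps(maps_a)
  sb <- stack_maps(maps_b)
  if (sa$grid$T != sb$grid$T ||
      length(sa$grid$frequencies) != length(sb$grid$frequencies))
    stop("the two groups' maps have heterogeneous dimensions")
  na <- length(maps_a); nb <- length(maps_b)
  exhaustive <- n_relabelings(design, na, nb) <= n_shuffle

  if (design == "independent") {
    if (na < 2 || nb < 2) stop("need at least 2 maps per group")
    Xt <- t(cbind(sa$X, sb$X))          # n x B, subjects in rows
    n <- na + nb
    if (exhaustive) {
      if (na == nb) {
        # equal sizes: each unordered partition appears twice in
        # combn(n, na) with identical |t|; enumerate each once (subject
        # 1 pinned to group A) — p is unchanged and ties stay exact
        combs <- rbind(1L, utils::combn(2:n, na - 1L))
      } else {
        combs <- utils::combn(n, na)    # first column is the identity 1:na
      }
      groupA <- t(combs)
    } else {
      groupA <- with_seed(seed,
        t(replicate(n_shuffle, sample.int(n, na))))
      groupA <- rbind(seq_len(na), groupA)
    }
    R <- nrow(groupA)
    W <- matrix(0, R, n)                # relabeling x subject indicator
    W[cbind(rep(seq_len(R), times = na), as.vector(groupA))] <- 1
    X2t <- Xt * Xt
    SA <- W %*% Xt
    SA2 <- W %*% X2t
    tmat <- .welch_from_sums(SA, SA2, colSums(Xt), colSums(X2t), na, nb)
  } else {
    if (na != nb) stop("paired design needs equal-length map lists")
    if (na < 2) stop("need at least 2 pairs")
    Dt <- t(sa$X - sb$X)                # np x B, pairs in rows
    if (exhaustive) {
      m <- 0:(2^na - 1)                 # m = 0 is the identity (all +1)
      signs <- 1 - 2 * t(vapply(m, function(v)
        bitwAnd(bitwShiftR(v, 0:(na - 1)), 1L), integer(na)))
    } else {
      signs <- with_seed(seed,
        matrix(sample(c(-1, 1), n_shuffle * na, replace = TRUE),
               n_shuffle, na))
      signs <- rbind(rep(1, na), signs)
    }
    tmat <- .paired_from_sums(signs %*% Dt, colSums(Dt * Dt), na)
  }
  thr <- .threshold_and_p(tmat, alpha_bin)
  excluded <- if (exclude_coi) {
    as.vector(Reduce(`|`, lapply(c(maps_a, maps_b), `[[`, "coi_mask")))
  } else {
    rep(FALSE, ncol(tmat))
  }
  list(tmat = tmat, sig = thr$sig, p_obs = thr$p_obs, grid = sa$grid,
       excluded = excluded, n_rows = nrow(tmat), exhaustive = exhaustive,
       design = design)
}

#' Bin-wise permutation test between two sets of power maps
#'
#' Step one of the cluster-based procedure: at every (trial, frequency)
#' bin a t statistic is computed between the two sets of maps
#' (unequal-variance two-sample t for independent groups; paired t on
#' per-pair differences), and its two-sided p-value is taken from a
#' permutation null built by shuffling group labels (independent) or
#' randomly swapping within pairs (paired). The add-one estimator
#' `p = (1 + #\{|t_perm| >= |t_obs|\}) / (1 + n_shuffle)` is used, so
#' p-values are bounded below by `1/(n_shuffle + 1)` and never zero.
#' When the design admits no more than `n_shuffle` distinct relabelings
#' the test enumerates all of them and the p-values are exact.
#'
#' Bins where all subjects share one value are degenerate: their t is 0
#' and their p-value 1.
#'
#' @param maps_a,maps_b Lists of [decompose()] maps (>= 2 per side;
#'   equal lengths and positional pairing for `design = "paired"`).
#' @param design `"independent"` or `"paired"`.
#' @param n_shuffle Number of random relabelings (default 5000).
#' @param alpha_bin Bin-level significance threshold (default 0.001).
#' @param seed Integer seed for the shuffles.
#' @param exclude_coi Force bins inside any map's cone of influence to be
#'   non-significant.
#' @return An object of class `tft_bintest`: `t_map`, `p_map`, `sig_mask`
#'   (all `T x F`), plus the test's parameters.
#' @export
binwise_permutation_test <- function(maps_a, maps_b,
                                     design = c("independent", "paired"),
                                     n_shuffle = 5000, alpha_bin = 0.001,
                                     seed = 1L, exclude_coi = FALSE) {
  design <- match.arg(design)
  if (!is.numeric(alpha_bin) || alpha_bin <= 0 || alpha_bin >= 1)
    stop("alpha_bin must lie in (0, 1)")
  pp <- perm_t_and_p(maps_a, maps_b, design, n_shuffle, seed, alpha_bin,
                     exclude_coi)
  T <- pp$grid$T; Fq <- length(pp$grid$frequencies)
  t_map <- matrix(pp$tmat[1L, ], T, Fq)
  p_map <- matrix(pp$p_obs, T, Fq)
  sig_mask <- p_map < alpha_bin & !matrix(pp$excluded, T, Fq)
  structure(
    list(t_map = t_map, p_map = p_map, sig_mask = sig_mask,
         grid = pp$grid, design = design, n_shuffle = pp$n_rows - 1L,
         alpha_bin = alpha_bin, seed = seed, exhaustive = pp$exhaustive),
    class = "tft_bintest"
  )
}

#' @export
print.tft_bintest <- function(x, ...) {
  cat(sprintf("<tft_bintest> %s design, %d shuffles%s; %d / %d bins with p < %g\n",
              x$design, x$n_shuffle, if (x$exhaustive) " (exhaustive)" else "",
              sum(x$sig_mask), length(x$sig_mask), x$alpha_bin))
  invisible(x)
}

# Turn the C++ labeling output into a list of cluster records.
clusters_from_labels <- function(obs_label, obs_mass, grid) {
  T <- grid$T
  lapply(seq_along(obs_mass), function(k) {
    j <- which(obs_label == k) - 1L
    bins <- cbind(trial = j %% T + 1L, freq = j %/% T + 1L)
    list(id = k, bins = bins, n_bins = nrow(bins),
         trial_range = range(bins[, "trial"]),
         freq_range = grid$frequencies[range(bins[, "freq"])],
         mass = obs_mass[k], sign = if (obs_mass[k] >= 0) 1L else -1L)
  })
}

#' Form clusters of contiguous significant bins
#'
#' Step two's clustering rule: connected components of the significant
#' bins in the trial x frequency grid, with positive and negative t
#' values clustered separately. The default 4-connectivity joins
#' orthogonal neighbors only; 8 also joins diagonals. Each cluster's
#' mass is the sum of its member t values.
#'
#' @param result A [binwise_permutation_test()] result.
#' @param connectivity 4 or 8.
#' @return A list of clusters, each with `bins` (two-column matrix of
#'   1-based trial/frequency indices), `n_bins`, `trial_range`,
#'   `freq_range` (cycles/trial), `mass` and `sign`.
#' @export
form_clusters <- function(result, connectivity = 4) {
  stopifnot(inherits(result, "tft_bintest"))
  tv <- as.vector(result$t_map)
  eng <- .cluster_engine(matrix(tv, 1L),
                         matrix(as.vector(result$sig_mask), 1L),
                         result$grid$T, length(result$grid$frequencies),
                         as.integer(connectivity),
                         rep(FALSE, length(tv)))
  clusters_from_labels(eng$obs_label, eng$obs_mass, result$grid)
}

#' Two-step cluster-based permutation test
#'
#' Compares two sets of trial x frequency power maps while correcting
#' for the multiple comparisons across all bins. Step 1 thresholds
#' every bin at `alpha_bin` against its permutation null (see
#' [binwise_permutation_test()]). Step 2 forms clusters of contiguous
#' suprathreshold bins and compares each observed cluster's mass (sum of
#' t values) to the Monte Carlo reference distribution of the *maximum*
#' absolute cluster mass across the shuffled maps — each shuffled map is
#' thresholded and clustered exactly like the observed one, which makes
#' the procedure exchangeable and controls the family-wise error at
#' `alpha_cluster`.
#'
#' @inheritParams binwise_permutation_test
#' @param alpha_cluster Cluster-level significance threshold (default
#'   0.05).
#' @param connectivity 4 (orthogonal neighbors, default) or 8.
#' @return An object of class `tft_clusters`: `clusters` (as in
#'   [form_clusters()], each augmented with `p_value` and `significant`),
#'   `n_significant`, `trials_covered_fraction` (fraction of the T trials
#'   intersected by at least one significant cluster), the bin-level
#'   `t_map`/`p_map`/`sig_mask`, and the run's parameters.
#' @export
cluster_permutation_test <- function(maps_a, maps_b,
                                     design = c("independent", "paired"),
                                     n_shuffle = 5000, alpha_bin = 0.001,
                                     alpha_cluster = 0.05, connectivity = 4,
                                     seed = 1L, exclude_coi = FALSE) {
  design <- match.arg(design)
  for (a in c(alpha_bin, alpha_cluster))
    if (!is.numeric(a) || a <= 0 || a >= 1) stop("alphas must lie in (0, 1)")
  pp <- perm_t_and_p(maps_a, maps_b, design, n_shuffle, seed, alpha_bin,
                     exclude_coi)
  T <- pp$grid$T; Fq <- length(pp$grid$frequencies)
  eng <- .cluster_engine(pp$tmat, pp$sig, T, Fq,
                         as.integer(connectivity), pp$excluded)
  n_rows <- pp$n_rows
  clusters <- clusters_from_labels(eng$obs_label, eng$obs_mass, pp$grid)
  for (k in seq_along(clusters)) {
    exceed <- sum(eng$perm_max >= abs(clusters[[k]]$mass))
    clusters[[k]]$p_value <- (1 + exceed) / n_rows
    clusters[[k]]$significant <- clusters[[k]]$p_value < alpha_cluster
  }
  sig_trials <- unique(unlist(lapply(clusters, function(cl)
    if (cl$significant) cl$bins[, "trial"] else integer(0))))
  structure(
    list(clusters = clusters,
         n_significant = sum(vapply(clusters, `[[`, logical(1), "significant")),
         trials_covered_fraction = length(sig_trials) / T,
         t_map = matrix(pp$tmat[1L, ], T, Fq),
         p_map = matrix(pp$p_obs, T, Fq),
         sig_mask = matrix(pp$p_obs < alpha_bin & !pp$excluded, T, Fq),
         grid = pp$grid, design = design, n_shuffle = n_rows - 1L,
         alpha_bin = alpha_bin, alpha_cluster = alpha_cluster,
         connectivity = as.integer(connectivity), seed = seed,
         exhaustive = pp$exhaustive),
    class = "tft_clusters"
  )
}

#' @export
print.tft_clusters <- function(x, ...) {
  cat(sprintf("<tft_clusters> %s design, %d shuffles%s\n", x$design,
              x$n_shuffle, if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  %d cluster(s), %d significant at p < %g; %.1f%% of trials covered\n",
              length(x$clusters), x$n_significant, x$alpha_cluster,
              100 * x$trials_covered_fraction))
  invisible(x)
}

#' Tabulate a cluster-permutation result
#'
#' @param result A [cluster_permutation_test()] result.
#' @return A data frame with one row per cluster (id, sign, bin count,
#'   trial and frequency extents, mass, p-value, significance flag), with
#'   attributes `n_clusters`, `n_significant` and
#'   `trials_covered_fraction`.
#' @export
report <- function(result) {
  stopifnot(inherits(result, "tft_clusters"))
  cl <- result$clusters
  df <- if (length(cl) == 0L) {
    data.frame(cluster = integer(0), sign = integer(0), n_bins = integer(0),
               trial_start = integer(0), trial_end = integer(0),
               freq_lo = numeric(0), freq_hi = numeric(0),
               mass = numeric(0), p_value = numeric(0),
               significant = logical(0))
  } else {
    data.frame(
      cluster = vapply(cl, `[[`, integer(1), "id"),
      sign = vapply(cl, `[[`, integer(1), "sign"),
      n_bins = vapply(cl, `[[`, integer(1), "n_bins"),
      trial_start = vapply(cl, function(c) c$trial_range[1], integer(1)),
      trial_end = vapply(cl, function(c) c$trial_range[2], integer(1)),
      freq_lo = vapply(cl, function(c) c$freq_range[1], numeric(1)),
      freq_hi = vapply(cl, function(c) c$freq_range[2], numeric(1)),
      mass = vapply(cl, `[[`, numeric(1), "mass"),
      p_value = vapply(cl, `[[`, numeric(1), "p_value"),
      significant = vapply(cl, `[[`, logical(1), "significant"))
  }
  attr(df, "n_clusters") <- length(cl)
  attr(df, "n_significant") <- result$n_significant
  attr(df, "trials_covered_fraction") <- result$trials_covered_fraction
  df
}
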