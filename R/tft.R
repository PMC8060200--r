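#' Frequency grid for the trial-frequency decomposition
#'
#' Frequencies are expressed in cycles per trial and discretized in steps
#' of `1/T`, where `T` is the number of trials (for a 300-trial session
#' the step is 1/300 = 0.0033). The grid runs from `1/T` up to `f_max`;
#' the default `f_max = 0.5` is the Nyquist limit on the trial index.
#'
#' @param T Series length in trials (>= 8).
#' @param f_max Highest frequency, in cycles/trial, 0 < f_max <= 0.5.
#' @return An object of class `tft_grid` with elements `T`, `step` and
#'   `frequencies`.
#' @examples
#' frequency_grid(300)$step  # 1/300
#' @export
frequency_grid <- function(T, f_max = 0.5) {
  if (!is_count(T) || T < 8)
    stop("T must be an integer >= 8 (shorter series have no usable frequencies)")
  if (!is.numeric(f_max) || length(f_max) != 1L || f_max <= 0 || f_max > 0.5)
    stop("f_max must lie in (0, 0.5] cycles/trial")
  T <- as.integer(T)
  step <- 1 / T
  k_max <- floor(f_max * T + 1e-9)
  if (k_max < 1L) stop("f_max below the lowest resolvable frequency 1/T")
  structure(list(T = T, step = step, frequencies = seq_len(k_max) * step),
            class = "tft_grid")
}

#' @export
print.tft_grid <- function(x, ...) {
  cat(sprintf("<tft_grid> T = %d trials, step = %.6g, %d frequencies up to %.4g cycles/trial\n",
              x$T, x$step, length(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Complex Morlet (Gabor) wavelet kernel
#'
#' Builds the discrete kernel
#' \deqn{G(\Delta t) = \frac{1}{\sqrt{2\pi}\,\sigma_G}
#'   \exp\!\left(-\frac{\Delta t^2}{2\sigma_G^2} + i\,2\pi f_G \Delta t\right)}
#' with amplitude standard deviation \eqn{\sigma_G = 0.5/f_G} trials and a
#' nominal support ("window") of \eqn{4\sigma_G} trials, realized as the
#' nearest odd number of taps at or above \eqn{4\sigma_G} so the kernel is
#' symmetric about an integer center.
#'
#' @param f_G Center frequency in cycles/trial (> 0).
#' @return An object of class `tft_kernel` with elements `f_G`, `sigma_G`,
#'   `window` (nominal, `4 * sigma_G`), `taps` (complex vector) and
#'   `center_index` (0-based index of the central tap).
#' @export
make_kernel <- function(f_G) {
  if (!is.numeric(f_G) || length(f_G) != 1L || !is.finite(f_G) || f_G <= 0)
    stop("f_G must be a positive frequency in cycles/trial")
  sigma_G <- 0.5 / f_G
  window <- 4 * sigma_G
  n_taps <- ceiling(window)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  center <- (n_taps - 1L) / 2L
  dt <- seq_len(n_taps) - 1L - center
  taps <- (1 / (sqrt(2 * pi) * sigma_G)) *
    exp(-dt^2 / (2 * sigma_G^2) + 1i * 2 * pi * f_G * dt)
  structure(list(f_G = f_G, sigma_G = sigma_G, window = window,
                 taps = taps, center_index = as.integer(center)),
            class = "tft_kernel")
}

# Cone-of-influence mask for one frequency: TRUE where the kernel support
# overhangs the series edge.
coi_for_kernel <- function(T, n_taps) {
  center <- (n_taps - 1L) / 2L
  t0 <- 0:(T - 1L)
  t0 < center | t0 + center > T - 1L
}

#' Trial-frequency decomposition of an RT series
#'
#' Convolves the mean-centered series with a complex Morlet kernel at
#' every grid frequency and returns the squared modulus of the
#' coefficients — the power of RT variation as a function of trial and
#' cycles/trial. The series is zero-padded outside its support;
#' `coi_mask` marks edge-contaminated bins (cone of influence) where the
#' kernel extends past the series.
#'
#' @param series An [rt_series()], [session()] (converted via
#'   [build_rt_series()]), or bare numeric vector.
#' @param grid A [frequency_grid()]; defaults to
#'   `frequency_grid(length(series), f_max)`.
#' @param f_max Passed to [frequency_grid()] when `grid` is `NULL`.
#' @return An object of class `tft_map`: `power` (`T x F` nonnegative
#'   matrix), `grid`, `coi_mask` (`T x F` logical) and `subject_id`.
#' @examples
#' x <- sin(2 * pi * 0.05 * (0:299))
#' m <- decompose(x)
#' which.max(colMeans(m$power[!m$coi_mask[, 15], , drop = FALSE]))
#' @export
decompose <- function(series, grid = NULL, f_max = 0.5) {
  subject_id <- NA_character_
  if (inherits(series, "tft_session")) {
    subject_id <- series$subject_id
    series <- build_rt_series(series)
  }
  x <- if (inherits(series, "rt_series")) series$values else as.numeric(series)
  if (!all(is.finite(x))) stop("series must be finite everywhere")
  T <- length(x)
  if (is.null(grid)) grid <- frequency_grid(T, f_max)
  stopifnot(inherits(grid, "tft_grid"))
  if (grid$T != T)
    stop(sprintf("series length (%d) does not match grid T (%d)", T, grid$T))

  xc <- x - mean(x)
  Fq <- length(grid$frequencies)
  power <- matrix(0, T, Fq)
  coi <- matrix(FALSE, T, Fq)
  t0 <- 0:(T - 1L)
  for (k in seq_len(Fq)) {
    ker <- make_kernel(grid$frequencies[k])
    n <- length(ker$taps)
    ctr <- ker$center_index
    L <- nextn(T + n)
    xf <- fft(c(xc, rep(0, L - T)))
    hf <- fft(c(ker$taps, rep(0 + 0i, L - n)))
    # circular cross-correlation; padding to L >= T + n - 1 kills wrap-around
    r <- fft(xf * Conj(hf), inverse = TRUE) / L
    coef <- r[(t0 - ctr) %% L + 1L]
    power[, k] <- Mod(coef)^2
    coi[, k] <- coi_for_kernel(T, n)
  }
  colnames(power) <- sprintf("f_%.6f", grid$frequencies)
  structure(list(power = power, grid = grid, coi_mask = coi,
                 subject_id = subject_id),
            class = "tft_map")
}

#' @export
print.tft_map <- function(x, ...) {
  cat(sprintf("<tft_map> %d trials x %d frequencies (step %.5g cycles/trial)%s\n",
              nrow(x$power), ncol(x$power), x$grid$step,
              if (is.na(x$subject_id)) "" else paste0(", subject '", x$subject_id, "'")))
  invisible(x)
}

#' Display a trial-frequency power map
#'
#' @param x A `tft_map`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.tft_map <- function(x, main = "TFT power", ...) {
  graphics::image(x = seq_len(nrow(x$power)) - 1L, y = x$grid$frequencies,
                  z = x$power, xlab = "trial", ylab = "cycles/trial",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

check_same_grid <- function(maps) {
  if (length(maps) == 0L) stop("no maps supplied")
  g <- maps[[1]]$grid
  for (m in maps) {
    stopifnot(inherits(m, "tft_map"))
    if (m$grid$T != g$T ||
        length(m$grid$frequencies) != length(g$frequencies) ||
        !isTRUE(all.equal(m$grid$frequencies, g$frequencies)))
      stop("maps have heterogeneous dimensions or frequency grids")
  }
  g
}

#' Element-wise mean of a set of power maps
#'
#' Used for group-level display panels. The cone-of-influence mask of the
#' mean map is the union (logical OR) of the members' masks.
#'
#' @param maps List of [decompose()] outputs sharing one grid.
#' @return A `tft_map`.
#' @export
group_mean_map <- function(maps) {
  g <- check_same_grid(maps)
  power <- Reduce(`+`, lapply(maps, `[[`, "power")) / length(maps)
  coi <- Reduce(`|`, lapply(maps, `[[`, "coi_mask"))
  structure(list(power = power, grid = g, coi_mask = coi,
                 subject_id = NA_character_),
            class = "tft_map")
}

#' Trial-marginal power profile
#'
#' Averages a map's power over frequencies, giving one value per trial —
#' the profile used to localize variability bursts along the session.
#'
#' @param map A `tft_map`.
#' @param exclude_coi Drop edge-contaminated bins from the average.
#' @return Numeric vector of length `T` (`NaN` where all bins at a trial
#'   are excluded).
#' @export
trial_marginal_power <- function(map, exclude_coi = FALSE) {
  stopifnot(inherits(map, "tft_map"))
  p <- map$power
  if (exclude_coi) p[map$coi_mask] <- NA_real_
  rowMeans(p, na.rm = TRUE)
}
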