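# Synthetic RT series and cohorts with controlled intra-individual
# variability structure: SD-matched profile archetypes, control-like and
# patient-like sessions, and a paired tonic-shift model.

# Place n non-overlapping epochs of length len: the session is split into
# n equal segments and one epoch lands uniformly inside each, so bursts
# are intermittent and spread across the session. Returns a 2-column
# matrix (start, end), 1-based inclusive.
place_epochs <- function(T, n, len) {
  if (n < 1L) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  seg <- floor(T / n)
  if (len > seg) stop("epoch length exceeds the per-epoch segment of the session")
  starts <- vapply(seq_len(n), function(k) {
    lo <- (k - 1L) * seg + 1L
    hi <- lo + seg - len
    if (hi > lo) sample(lo:hi, 1L) else lo
  }, integer(1))
  cbind(start = starts, end = starts + len - 1L)
}

epoch_mask <- function(T, epochs) {
  m <- rep(FALSE, T)
  if (nrow(epochs) > 0L)
    for (k in seq_len(nrow(epochs))) m[epochs[k, 1]:epochs[k, 2]] <- TRUE
  m
}

#' Generate an SD-matched performance-profile archetype
#'
#' Draws one of four deviation processes around a constant mean and then
#' rescales the deviations so the sample standard deviation equals
#' `target_sd` *exactly*. Because all four kinds can be generated at the
#' same SD, they demonstrate that RT_SD alone cannot distinguish
#' qualitatively different fluctuation profiles:
#' \describe{
#'   \item{uniform}{i.i.d. Gaussian trial-to-trial jitter.}
#'   \item{sparse_bursts}{few, strong variability epochs on a quiet
#'     baseline (default 2 epochs of 20 trials at 5x baseline SD).}
#'   \item{dense_bursts}{many, milder epochs (default 8 of 15 trials at
#'     2.5x).}
#'   \item{slow_drift}{a slow sinusoidal drift (default 0.01 cycles/trial)
#'     plus mild jitter.}
#' }
#'
#' @param kind Archetype name.
#' @param T Number of trials.
#' @param target_sd Sample SD of the output, in ms (> 0).
#' @param mean_rt Mean of the output, in ms.
#' @param n_epochs,epoch_len,burst_mult Burst-epoch count, length
#'   (trials) and within-epoch SD multiplier; defaults depend on `kind`.
#' @param drift_freq Drift frequency in cycles/trial (slow_drift only).
#' @param seed Integer seed; the output is fully determined by it.
#' @return An [rt_series()] (all trials valid) with attribute `epochs`,
#'   a (start, end) matrix of burst positions (empty for non-burst kinds).
#' @export
generate_profile <- function(kind = c("uniform", "sparse_bursts",
                                      "dense_bursts", "slow_drift"),
                             T = 300, target_sd = 247, mean_rt = 1200,
                             n_epochs = NULL, epoch_len = NULL,
                             burst_mult = NULL, drift_freq = 0.01,
                             seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(target_sd) || target_sd <= 0)
    stop("target_sd must be positive")
  defaults <- switch(kind,
    sparse_bursts = list(n_epochs = 2L, epoch_len = 20L, burst_mult = 5),
    dense_bursts = list(n_epochs = 8L, epoch_len = 15L, burst_mult = 2.5),
    list(n_epochs = 0L, epoch_len = 0L, burst_mult = 1))
  if (is.null(n_epochs)) n_epochs <- defaults$n_epochs
  if (is.null(epoch_len)) epoch_len <- defaults$epoch_len
  if (is.null(burst_mult)) burst_mult <- defaults$burst_mult

  res <- with_seed(seed, {
    epochs <- place_epochs(T, n_epochs, epoch_len)
    d <- switch(kind,
      uniform = rnorm(T),
      sparse_bursts = ,
      dense_bursts = {
        z <- rnorm(T)
        z[epoch_mask(T, epochs)] <- z[epoch_mask(T, epochs)] * burst_mult
        z
      },
      slow_drift = {
        phase <- runif(1, 0, 2 * pi)
        1.5 * sin(2 * pi * drift_freq * seq_len(T) + phase) + 0.5 * rnorm(T)
      })
    list(d = d, epochs = epochs)
  })
  d <- res$d - mean(res$d)
  s <- sd(d)
  if (s == 0) stop("degenerate deviation draw; cannot renormalize")
  out <- rt_series(mean_rt + d * target_sd / s)
  attr(out, "epochs") <- res$epochs
  attr(out, "kind") <- kind
  out
}

#' Generative parameters for one simulated group
#'
#' Each trial's RT is Gaussian: outside burst epochs
#' `N(mean_rt, tonic_sd)`; inside an epoch
#' `N(mean_rt - burst_shift, tonic_sd * burst_mult)`. A positive
#' `burst_shift` makes epochs *anticipatory* — responses collapse toward
#' premature presses, the signature of an attentional lapse — while
#' `burst_mult` scales the within-epoch jitter. Either mechanism (or
#' both) produces intermittent variability epochs that raise the overall
#' RT_SD without changing the tonic baseline.
#'
#' @param mean_rt Tonic (baseline) mean RT in ms. With anticipatory
#'   bursts the realized session mean is lower; the presets account for
#'   this.
#' @param tonic_sd SD of the baseline Gaussian trial-to-trial noise, ms.
#' @param n_epochs Number of burst epochs per session (0 = none).
#' @param epoch_len Burst epoch length in trials.
#' @param burst_mult Within-epoch SD multiplier (> 0).
#' @param burst_shift Within-epoch downward mean shift in ms.
#' @param miss_prob Per-trial probability of no key press.
#' @param T Trials per session.
#' @param burst_epochs Optional explicit (start, end) matrix (1-based,
#'   inclusive) overriding random epoch placement — used to inject a
#'   variability burst at a known location.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(mean_rt = 1200, tonic_sd = 250, n_epochs = 0L,
                          epoch_len = 20L, burst_mult = 1, burst_shift = 0,
                          miss_prob = 0, T = 300L, burst_epochs = NULL) {
  if (miss_prob < 0 || miss_prob > 1) stop("miss_prob must lie in [0, 1]")
  if (tonic_sd <= 0) stop("tonic_sd must be positive")
  if (burst_mult <= 0) stop("burst_mult must be positive")
  if (!is.null(burst_epochs)) {
    burst_epochs <- as.matrix(burst_epochs)
    if (any(burst_epochs < 1) || any(burst_epochs > T))
      stop("burst epochs must lie within [1, T]")
  }
  structure(list(mean_rt = mean_rt, tonic_sd = tonic_sd,
                 n_epochs = as.integer(n_epochs),
                 epoch_len = as.integer(epoch_len),
                 burst_mult = burst_mult, burst_shift = burst_shift,
                 miss_prob = miss_prob,
                 T = as.integer(T), burst_epochs = burst_epochs),
            class = "cohort_params")
}

#' Preset group parameters
#'
#' Presets emulating a 300-trial time-estimation session for a healthy
#' control child (`control_params`), an inattentive-presentation patient
#' (`add_params`) and a combined-presentation patient (`adhd_params`).
#' Controls carry tonic jitter only. Patient presets add intermittent
#' anticipatory burst epochs (premature-response lapses); their shift,
#' spread and coverage were calibrated so that on accepted responses in
#' the 400–2000 ms window the cohort means land near the reference
#' behavioral profile: mean RT ~1140 ms with RT_SD ~404 ms and ~105
#' early responses (ADD-like), RT_SD ~382 ms (ADHD-like), versus mean
#' ~1171 ms and RT_SD ~247 ms for controls. Symmetric variance inflation
#' alone cannot reach a 400 ms within-window RT_SD at realistic miss
#' counts — the acceptance window truncates the inflated tails — which
#' is why the patient bursts are anticipatory.
#'
#' @param ... Overrides passed to [cohort_params()].
#' @return A `cohort_params` object.
#' @export
control_params <- function(...) {
  do.call(cohort_params,
          modifyList(list(mean_rt = 1171, tonic_sd = 247, n_epochs = 0L,
                          miss_prob = 0.005),
                     list(...)))
}

#' @rdname control_params
#' @export
add_params <- function(...) {
  do.call(cohort_params,
          modifyList(list(mean_rt = 1385, tonic_sd = 240, n_epochs = 4L,
                          epoch_len = 26L, burst_mult = 160 / 240,
                          burst_shift = 760, miss_prob = 0.005),
                     list(...)))
}

#' @rdname control_params
#' @export
adhd_params <- function(...) {
  do.call(cohort_params,
          modifyList(list(mean_rt = 1355, tonic_sd = 245, n_epochs = 3L,
                          epoch_len = 31L, burst_mult = 160 / 245,
                          burst_shift = 710, miss_prob = 0.005),
                     list(...)))
}

#' Simulate one time-estimation session
#'
#' Draws `T` reaction times around `mean_rt` with tonic Gaussian noise;
#' inside burst epochs the mean drops by `burst_shift` and the noise SD
#' is multiplied by `burst_mult` (see [cohort_params()]). Each trial is
#' independently marked as an absent press with probability `miss_prob`,
#' and RTs are clipped at 0 ms. Response classification
#' (correct/early/late/missed) is applied downstream by
#' [classify_response()]/[summarize_session()].
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; the session is fully determined by it.
#' @param subject_id Subject identifier.
#' @return A [session()] object with attribute `epochs`.
#' @export
simulate_session <- function(params, seed = NULL, subject_id = "sim") {
  stopifnot(inherits(params, "cohort_params"))
  res <- with_seed(seed, {
    epochs <- if (!is.null(params$burst_epochs)) params$burst_epochs
              else place_epochs(params$T, params$n_epochs, params$epoch_len)
    in_burst <- epoch_mask(params$T, epochs)
    sd_t <- rep(params$tonic_sd, params$T)
    sd_t[in_burst] <- params$tonic_sd * params$burst_mult
    mu <- rep(params$mean_rt, params$T)
    mu[in_burst] <- params$mean_rt - params$burst_shift
    rt <- mu + rnorm(params$T) * sd_t
    rt <- pmax(rt, 0)
    if (params$miss_prob > 0)
      rt[runif(params$T) < params$miss_prob] <- NA_real_
    list(rt = rt, epochs = epochs)
  })
  out <- session(res$rt, subject_id = subject_id)
  attr(out, "epochs") <- res$epochs
  out
}

#' Cohort specification
#'
#' @param params_a,params_b [cohort_params()] for the two groups.
#' @param n_a,n_b Subjects per group (>= 2).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(params_a, params_b, n_a, n_b) {
  stopifnot(inherits(params_a, "cohort_params"),
            inherits(params_b, "cohort_params"),
            n_a >= 2, n_b >= 2)
  structure(list(params_a = params_a, params_b = params_b,
                 n_a = as.integer(n_a), n_b = as.integer(n_b)),
            class = "cohort_spec")
}

#' Simulate a two-group cohort
#'
#' Per-subject seeds are derived deterministically from `seed`, so the
#' same spec and seed always reproduce the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master integer seed.
#' @return A list with elements `a` and `b`, each a list of sessions.
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(seed, spec$n_a + spec$n_b)
  a <- lapply(seq_len(spec$n_a), function(i)
    simulate_session(spec$params_a, seed = seeds[i],
                     subject_id = sprintf("a%02d", i)))
  b <- lapply(seq_len(spec$n_b), function(i)
    simulate_session(spec$params_b, seed = seeds[spec$n_a + i],
                     subject_id = sprintf("b%02d", i)))
  list(a = a, b = b)
}

#' Apply a tonic (constant) RT shift to a session
#'
#' Models a pure tonic change in performance: every present response is
#' shifted by the same constant while missed trials stay missing. A
#' tonic shift moves responses relative to the classification windows
#' (so accuracy counts can change) but leaves the fluctuation profile —
#' and hence the trial-frequency power map — untouched as long as no
#' response crosses the 400/2000 ms acceptance bounds.
#'
#' @param session A [session()] object.
#' @param shift Shift in ms (finite; negative = faster responses).
#' @return A new session.
#' @export
apply_tonic_shift <- function(session, shift) {
  stopifnot(inherits(session, "tft_session"),
            is.numeric(shift), length(shift) == 1L, is.finite(shift))
  rt <- session$rt + shift
  if (any(rt < 0, na.rm = TRUE))
    stop("shift would produce negative reaction times")
  out <- session
  out$rt <- rt
  out
}
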