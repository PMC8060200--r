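#' Time-estimation response windows (ms)
#'
#' Boundaries of the response-classification windows used throughout the
#' package, in milliseconds after cue onset. The task asks for a 1200 ms
#' interval estimate; a press within 200 ms of the target
#' (`[1000, 1400]`) is correct, earlier presses back to 400 ms are early,
#' later presses up to 2000 ms are late, and anything before 400 ms,
#' after 2000 ms, or no press at all is a missed response. The correct
#' window is closed on both ends; early is half-open below it and late
#' half-open above it, so the classes partition the whole axis.
#'
#' @format A named numeric vector with elements `floor` (400), `lo`
#'   (1000), `hi` (1400) and `ceiling` (2000).
#' @export
response_windows <- c(floor = 400, lo = 1000, hi = 1400, ceiling = 2000)

#' Classify time-estimation responses
#'
#' Maps reaction times to the four task outcome categories. `NA` means no
#' key press was registered and is classified as missed.
#'
#' @param rt Numeric vector of reaction times in ms (may contain `NA`).
#' @param windows Named numeric vector of window boundaries, see
#'   [response_windows].
#' @return A factor with levels `correct`, `early`, `late`, `missed`.
#' @examples
#' classify_response(c(1200, 700, 1700, 300, NA))
#' @export
classify_response <- function(rt, windows = response_windows) {
  if (any(rt < 0, na.rm = TRUE))
    stop("reaction times must be nonnegative")
  out <- rep("missed", length(rt))
  ok <- !is.na(rt)
  out[ok & rt >= windows[["floor"]] & rt < windows[["lo"]]] <- "early"
  out[ok & rt >= windows[["lo"]] & rt <= windows[["hi"]]] <- "correct"
  out[ok & rt > windows[["hi"]] & rt <= windows[["ceiling"]]] <- "late"
  factor(out, levels = c("correct", "early", "late", "missed"))
}

#' Construct a task session
#'
#' A session is one subject's ordered sequence of time-estimation trials
#' (default 300 trials in blocks of 100). `NA` reaction times mean no
#' key press.
#'
#' @param rt Numeric vector of per-trial reaction times in ms, `NA` for
#'   absent responses.
#' @param subject_id Subject identifier.
#' @param block_size Trials per block (metadata only).
#' @return An object of class `tft_session`.
#' @export
session <- function(rt, subject_id = "subject", block_size = 100L) {
  if (length(rt) < 1L) stop("a session needs at least one trial")
  rt <- as.numeric(rt)
  if (any(rt < 0, na.rm = TRUE)) stop("reaction times must be nonnegative")
  structure(
    list(subject_id = as.character(subject_id), rt = rt,
         block_size = as.integer(block_size)),
    class = "tft_session"
  )
}

#' @export
print.tft_session <- function(x, ...) {
  cat(sprintf("<tft_session> subject '%s', %d trials (%d missing presses)\n",
              x$subject_id, length(x$rt), sum(is.na(x$rt))))
  invisible(x)
}

#' @export
length.tft_session <- function(x) length(x$rt)

#' Summarize a session's behavior
#'
#' Counts responses per outcome class and computes the mean and sample
#' standard deviation (the classical intra-individual-variability index
#' RT_SD) of the reaction times. The location/spread measures are taken
#' over all non-missed responses (early + correct + late) by default;
#' set `subset = "correct"` to restrict them to correct responses.
#'
#' @param session A [session()] object.
#' @param subset Which responses enter `mean_rt`/`sd_rt`:
#'   `"responded"` (default) or `"correct"`.
#' @return A list of class `behavior_summary` with elements `subject_id`,
#'   `n_correct`, `n_early`, `n_late`, `n_missed`, `mean_rt`, `sd_rt`.
#'   `mean_rt`/`sd_rt` are `NA` when undefined (no usable responses; `sd_rt`
#'   needs at least two).
#' @export
summarize_session <- function(session, subset = c("responded", "correct")) {
  stopifnot(inherits(session, "tft_session"))
  subset <- match.arg(subset)
  cls <- classify_response(session$rt)
  counts <- table(cls)
  keep <- if (subset == "responded") cls != "missed" else cls == "correct"
  vals <- session$rt[keep]
  structure(
    list(subject_id = session$subject_id,
         n_correct = unname(counts[["correct"]]),
         n_early = unname(counts[["early"]]),
         n_late = unname(counts[["late"]]),
         n_missed = unname(counts[["missed"]]),
         mean_rt = if (length(vals) >= 1L) mean(vals) else NA_real_,
         sd_rt = if (length(vals) >= 2L) sd(vals) else NA_real_),
    class = "behavior_summary"
  )
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(
    "<behavior_summary> %s: %d correct, %d early, %d late, %d missed; mean RT %.1f ms, RT_SD %.1f ms\n",
    x$subject_id, x$n_correct, x$n_early, x$n_late, x$n_missed,
    x$mean_rt, x$sd_rt))
  invisible(x)
}

#' @export
as.data.frame.behavior_summary <- function(x, ...) {
  data.frame(subject = x$subject_id, n_correct = x$n_correct,
             n_early = x$n_early, n_late = x$n_late, n_missed = x$n_missed,
             mean_rt = x$mean_rt, sd_rt = x$sd_rt,
             stringsAsFactors = FALSE)
}

#' Construct an RT series directly
#'
#' Low-level constructor for the contiguous series the wavelet
#' decomposition consumes. Most users will obtain one via
#' [build_rt_series()] or [generate_profile()].
#'
#' @param values Finite numeric vector of per-trial RTs in ms.
#' @param valid_mask Logical vector; `FALSE` marks trials whose value was
#'   imputed rather than observed.
#' @return An object of class `rt_series`.
#' @export
rt_series <- function(values, valid_mask = rep(TRUE, length(values))) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("series values must be finite")
  if (length(valid_mask) != length(values))
    stop("valid_mask length must match values")
  structure(list(values = values, valid_mask = as.logical(valid_mask)),
            class = "rt_series")
}

#' @export
length.rt_series <- function(x) length(x$values)

#' @export
print.rt_series <- function(x, ...) {
  cat(sprintf("<rt_series> %d trials, %d imputed; mean %.1f ms, SD %.1f ms\n",
              length(x$values), sum(!x$valid_mask),
              mean(x$values), sd(x$values)))
  invisible(x)
}

#' Build the contiguous RT series for decomposition
#'
#' The wavelet decomposition needs one finite value per trial, but missed
#' responses carry no RT. Missed trials (absent presses and presses
#' outside the 400–2000 ms acceptance range) are filled by linear
#' interpolation between the nearest valid neighbors; gaps at the series
#' edges are filled by extending the nearest valid value. The returned
#' `valid_mask` is `FALSE` exactly at imputed trials, so downstream
#' statistics can discount them.
#'
#' @param session A [session()] object with at least two non-missed trials.
#' @return An [rt_series()] of the same length as the session.
#' @export
build_rt_series <- function(session) {
  stopifnot(inherits(session, "tft_session"))
  cls <- classify_response(session$rt)
  valid <- cls != "missed"
  n_valid <- sum(valid)
  if (n_valid < 2L)
    stop("cannot build an RT series from fewer than 2 valid trials")
  T <- length(session$rt)
  idx <- which(valid)
  values <- session$rt
  if (n_valid < T) {
    values <- approx(x = idx, y = session$rt[idx], xout = seq_len(T),
                     method = "linear", rule = 2)$y
    values[idx] <- session$rt[idx]  # observed values untouched, bit-exact
  }
  rt_series(values, valid_mask = valid)
}
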