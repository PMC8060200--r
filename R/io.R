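# Delimited-text I/O for sessions, maps and cluster results.
# Trial indices are 0-based in all files; an empty rt_ms cell means no
# key press.

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) read.delim(path, stringsAsFactors = FALSE)
  else read.csv(path, stringsAsFactors = FALSE)
}

#' Read sessions from a delimited text file
#'
#' Two layouts are accepted: long format with header columns `subject`,
#' `trial` (0-based), `rt_ms` (empty cell = no key press), holding one or
#' more subjects; or a headerless single column of RTs for one subject.
#' Comma- and tab-separated files are both recognized.
#'
#' @param path File path.
#' @param subject_id Identifier used for the single-column layout.
#' @return A named list of [session()] objects.
#' @export
read_sessions <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("subject", first, fixed = TRUE)) {
    rt <- suppressWarnings(as.numeric(readLines(path)))
    rt <- rt[!is.na(rt) | seq_along(rt) <= length(rt)]  # keep NAs (missed)
    if (length(rt) == 0L) stop("empty input: ", path)
    id <- if (is.null(subject_id)) sub("\\.[^.]*$", "", basename(path)) else subject_id
    out <- list(session(rt, subject_id = id))
    names(out) <- id
    return(out)
  }
  df <- read_delim_auto(path)
  need <- c("subject", "trial", "rt_ms")
  if (!all(need %in% names(df)))
    stop("long-format session file needs columns subject, trial, rt_ms (",
         path, ")")
  if (nrow(df) == 0L) stop("empty input: ", path)
  df$rt_ms <- suppressWarnings(as.numeric(df$rt_ms))
  out <- lapply(split(df, df$subject), function(d) {
    d <- d[order(d$trial), , drop = FALSE]
    if (anyDuplicated(d$trial))
      stop("duplicate trial indices for subject ", d$subject[1])
    if (!identical(as.integer(d$trial), seq_len(nrow(d)) - 1L))
      stop("trial indices for subject ", d$subject[1],
           " are not contiguous 0-based")
    session(d$rt_ms, subject_id = d$subject[1])
  })
  out[order(names(out))]
}

#' Write sessions to long-format CSV
#'
#' @param sessions A list of [session()] objects.
#' @param path Output path.
#' @export
write_sessions <- function(sessions, path) {
  df <- do.call(rbind, lapply(sessions, function(s)
    data.frame(subject = s$subject_id,
               trial = seq_along(s$rt) - 1L,
               rt_ms = s$rt)))
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Write / read a trial-frequency power map
#'
#' The map is stored as a TSV matrix (rows = trials, first column the
#' 0-based trial index, remaining columns one per frequency, labelled in
#' cycles/trial) together with a JSON sidecar `<path>.json` holding the
#' grid metadata. The cone-of-influence mask is deterministic given the
#' grid and is reconstructed on read.
#'
#' @param map A `tft_map`.
#' @param path Output TSV path.
#' @return `write_tft_map` returns `path` invisibly; `read_tft_map`
#'   returns a `tft_map`.
#' @export
write_tft_map <- function(map, path) {
  stopifnot(inherits(map, "tft_map"))
  df <- data.frame(trial = seq_len(nrow(map$power)) - 1L, map$power,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(subject = map$subject_id, T = map$grid$T,
               step = map$grid$step,
               f_max = max(map$grid$frequencies),
               n_frequencies = length(map$grid$frequencies))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tft_map
#' @export
read_tft_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.delim(path, check.names = FALSE)
  power <- as.matrix(df[, -1, drop = FALSE])
  grid <- frequency_grid(meta$T, meta$f_max)
  if (length(grid$frequencies) != ncol(power))
    stop("map/sidecar mismatch for ", path)
  coi <- vapply(grid$frequencies, function(f)
    coi_for_kernel(grid$T, length(make_kernel(f)$taps)),
    logical(grid$T))
  structure(list(power = power, grid = grid, coi_mask = coi,
                 subject_id = if (is.null(meta$subject)) NA_character_
                              else meta$subject),
            class = "tft_map")
}

#' Write a cluster result as JSON and as a trial-interval TSV
#'
#' `write_cluster_json` stores the full result (parameters plus one
#' record per cluster). `write_cluster_intervals` emits a BED-like TSV
#' of the trial extent of every cluster, 0-based half-open, for
#' downstream plotting.
#'
#' @param result A [cluster_permutation_test()] result.
#' @param path Output path.
#' @export
write_cluster_json <- function(result, path) {
  stopifnot(inherits(result, "tft_clusters"))
  df <- report(result)
  out <- list(design = result$design, n_shuffle = result$n_shuffle,
              alpha_bin = result$alpha_bin,
              alpha_cluster = result$alpha_cluster,
              connectivity = result$connectivity, seed = result$seed,
              exhaustive = result$exhaustive,
              n_clusters = attr(df, "n_clusters"),
              n_significant = attr(df, "n_significant"),
              trials_covered_fraction = attr(df, "trials_covered_fraction"),
              clusters = df)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_cluster_json
#' @export
write_cluster_intervals <- function(result, path) {
  stopifnot(inherits(result, "tft_clusters"))
  df <- report(result)
  iv <- data.frame(cluster = df$cluster,
                   trial_start = df$trial_start - 1L,    # 0-based
                   trial_end = df$trial_end,             # half-open
                   sign = df$sign, mass = df$mass,
                   p_value = df$p_value, significant = df$significant)
  write.table(iv, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write behavioral summaries as TSV or JSON
#'
#' @param summaries A list of [summarize_session()] results (or one).
#' @param path Output path; `.json` extension selects JSON, anything
#'   else TSV (one row per subject).
#' @export
write_behavior_summaries <- function(summaries, path) {
  if (inherits(summaries, "behavior_summary")) summaries <- list(summaries)
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  if (grepl("\\.json$", path))
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  else
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
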