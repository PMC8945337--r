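#' Split a recording into fixed-length segments
#'
#' Returns contiguous, non-overlapping segments of `segment_min` minutes.
#' A trailing remainder shorter than one segment is dropped (with a
#' message). A 50-minute record therefore yields exactly ten 5-minute
#' segments.
#'
#' @param record A [signal_record()].
#' @param segment_min Segment length in minutes (default 5).
#' @return A list of numeric vectors, one per segment, with attributes
#'   `fs` and `dropped_s` (seconds of trailing signal discarded).
#' @export
segment_signal <- function(record, segment_min = 5) {
  stopifnot(inherits(record, "signal_record"))
  seg_n <- round(segment_min * 60 * record$fs)
  n <- length(record$samples)
  n_seg <- n %/% seg_n
  if (n_seg < 1)
    stop("segment_signal: record lasts ", round(n / record$fs / 60, 2),
         " min; at least ", segment_min, " min are required", call. = FALSE)
  dropped <- n - n_seg * seg_n
  if (dropped > 0)
    message(sprintf("segment_signal: dropping trailing %.2f min (%d samples)",
                    dropped / record$fs / 60, dropped))
  segs <- lapply(seq_len(n_seg), function(j)
    record$samples[((j - 1) * seg_n + 1):(j * seg_n)])
  attr(segs, "fs") <- record$fs
  attr(segs, "dropped_s") <- dropped / record$fs
  segs
}

#' Windowed signal power energy
#'
#' Computes the power energy `EN = sum(|x(n)|^2)` over consecutive
#' rectangular windows of `window_s` seconds. Windows advance by
#' `step_s` seconds (default: the window length, i.e. contiguous
#' non-overlapping windows); remainder samples beyond the last whole
#' window are dropped.
#'
#' @param segment Numeric sample vector (one segment).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 5).
#' @param step_s Window step in seconds (default `window_s`).
#' @return An object of class `energy_series`: a numeric vector of window
#'   energies with attributes `window_s`, `step_s` and `fs`.
#' @export
window_energy <- function(segment, fs, window_s = 5, step_s = window_s) {
  win_n <- round(window_s * fs)
  step_n <- round(step_s * fs)
  if (win_n < 1 || step_n < 1)
    stop("window_energy: window and step must contain at least one sample",
         call. = FALSE)
  n <- length(segment)
  if (n < win_n)
    stop("window_energy: segment (", n, " samples) is shorter than one ",
         "window (", win_n, " samples)", call. = FALSE)
  starts <- seq(1, n - win_n + 1, by = step_n)
  en <- vapply(starts, function(s)
    sum(segment[s:(s + win_n - 1)]^2), numeric(1))
  structure(en, class = "energy_series",
            window_s = window_s, step_s = step_s, fs = fs)
}

#' Mean window energy of a segment
#'
#' @param series An [window_energy()] result (or plain numeric vector of
#'   window energies).
#' @return The arithmetic mean of the window energies.
#' @export
segment_mean_energy <- function(series) {
  if (length(series) == 0)
    stop("segment_mean_energy: empty energy series", call. = FALSE)
  mean(as.numeric(series))
}

#' Per-subject segment mean energies of one record
#'
#' Convenience wrapper: segments a (preprocessed) record and returns the
#' mean window energy of each segment.
#'
#' @inheritParams segment_signal
#' @inheritParams window_energy
#' @return Numeric vector, one mean energy per segment.
#' @export
record_segment_energies <- function(record, segment_min = 5, window_s = 5,
                                    step_s = window_s) {
  segs <- segment_signal(record, segment_min)
  vapply(segs, function(s)
    segment_mean_energy(window_energy(s, record$fs, window_s, step_s)),
    numeric(1))
}

#' Group-mean energy profile
#'
#' Averages per-subject segment mean energies over the subjects of one
#' group, giving one profile point per segment (the "10 points per group"
#' of a 50-minute session). Subjects contributing more segments than the
#' common minimum are truncated to it.
#'
#' @param segment_means Matrix (or list of equal-length vectors) of
#'   per-subject segment mean energies, subjects in rows.
#' @param group Group label, `"caffeine"` or `"placebo"`.
#' @param modality Modality label.
#' @return An object of class `group_profile`: list with `points`,
#'   `group`, `modality`, `zscored`.
#' @export
group_mean_profile <- function(segment_means, group, modality = "ECG") {
  if (is.list(segment_means)) {
    if (length(segment_means) == 0)
      stop("group_mean_profile: no subjects", call. = FALSE)
    n_seg <- min(lengths(segment_means))
    if (n_seg < 1)
      stop("group_mean_profile: a subject contributes zero segments",
           call. = FALSE)
    segment_means <- do.call(rbind,
                             lapply(segment_means, function(v) v[seq_len(n_seg)]))
  }
  segment_means <- as.matrix(segment_means)
  if (nrow(segment_means) == 0 || ncol(segment_means) == 0)
    stop("group_mean_profile: empty segment-mean matrix", call. = FALSE)
  if (any(!is.finite(segment_means)))
    stop("group_mean_profile: non-finite segment means", call. = FALSE)
  group <- match.arg(group, c("caffeine", "placebo"))
  structure(list(points = colMeans(segment_means), group = group,
                 modality = modality, zscored = FALSE),
            class = "group_profile")
}

#' Joint z-scoring of two group profiles
#'
#' Standardizes the caffeine and placebo profiles with the pooled mean and
#' pooled standard deviation of their concatenated points, so the pooled
#' transformed points have mean 0 and standard deviation 1 while every
#' between-group difference keeps its sign. Per-group standardization
#' would instead erase the between-group gap the classifiers rely on.
#'
#' @param profile_a,profile_b [group_mean_profile()] objects of equal
#'   length.
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n - 1).
#' @return List of the two transformed profiles (`zscored = TRUE`), in the
#'   input order.
#' @export
zscore_joint <- function(profile_a, profile_b,
                         sd_type = c("population", "sample")) {
  stopifnot(inherits(profile_a, "group_profile"),
            inherits(profile_b, "group_profile"))
  sd_type <- match.arg(sd_type)
  if (length(profile_a$points) != length(profile_b$points))
    stop("zscore_joint: profiles have different lengths", call. = FALSE)
  pooled <- c(profile_a$points, profile_b$points)
  mu <- mean(pooled)
  sdv <- if (sd_type == "population") sd_pop(pooled) else stats::sd(pooled)
  if (sdv == 0)
    stop("zscore_joint: pooled standard deviation is zero (all points ",
         "identical)", call. = FALSE)
  za <- profile_a
  zb <- profile_b
  za$points <- (profile_a$points - mu) / sdv
  zb$points <- (profile_b$points - mu) / sdv
  za$zscored <- TRUE
  zb$zscored <- TRUE
  list(za, zb)
}
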