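#' Single-modality physiological recording
#'
#' Container for one modality's sample stream together with the metadata
#' the pipeline needs: sampling rate, modality, subject and condition
#' labels, and physical units. Time is implicit — sample `n` occurs at
#' `(n - 1) / fs` seconds from record start.
#'
#' @param samples Numeric vector of amplitudes (mV for ECG, microsiemens
#'   for EDA, arbitrary units for RF). Must be finite, length >= 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param modality One of `"ECG"`, `"EDA"`, `"RF"`.
#' @param subject_id Subject identifier (coerced to character).
#' @param condition One of `"caffeine"`, `"placebo"`.
#' @param units Physical units string; defaults by modality.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, fs, modality,
                          subject_id = "S01", condition = "placebo",
                          units = NULL) {
  modality <- match.arg(modality, c("ECG", "EDA", "RF"))
  condition <- match.arg(condition, c("caffeine", "placebo"))
  samples <- as.numeric(samples)
  if (length(samples) < 1)
    stop("signal_record: at least one sample is required", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("signal_record: samples contain NA/NaN/Inf", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("signal_record: fs must be a single positive number", call. = FALSE)
  if (is.null(units))
    units <- switch(modality, ECG = "mV", EDA = "uS", RF = "a.u.")
  structure(list(samples = samples, fs = fs, modality = modality,
                 subject_id = as.character(subject_id),
                 condition = condition, units = units),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<signal_record> %s | subject %s | %s\n",
              x$modality, x$subject_id, x$condition))
  cat(sprintf("  %d samples @ %g Hz (%.2f min), units %s\n",
              length(x$samples), x$fs, dur / 60, x$units))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param record A [signal_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  length(record$samples) / record$fs
}
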