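#' Per-modality FIR filter specification
#'
#' Defaults follow the analysis protocol: low-pass at 1 Hz for
#' electrodermal activity, low-pass at 3 Hz for respiration, band-pass
#' 1-30 Hz for the ECG. Filters are linear-phase FIR (Hamming window
#' design); the default order rule is `4 * fs / lowest cutoff` taps,
#' capped at 8192, which gives a transition band of roughly 0.8 cutoff
#' widths and more than 50 dB of stopband attenuation.
#'
#' @param modality One of `"ECG"`, `"EDA"`, `"RF"`. Sets the default kind
#'   and cutoffs.
#' @param kind `"low-pass"` or `"band-pass"`; default by modality.
#' @param cutoffs Cutoff frequency(ies) in Hz; default by modality.
#' @param order FIR order (number of taps minus one); `NULL` applies the
#'   default order rule at design time.
#' @param phase_mode `"zero-phase"` (forward-backward application, the
#'   default, so segment boundaries are not shifted by group delay) or
#'   `"single-pass"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(modality = c("ECG", "EDA", "RF"), kind = NULL,
                        cutoffs = NULL, order = NULL,
                        phase_mode = c("zero-phase", "single-pass")) {
  modality <- match.arg(modality)
  phase_mode <- match.arg(phase_mode)
  if (is.null(kind))
    kind <- switch(modality, ECG = "band-pass", EDA = "low-pass",
                   RF = "low-pass")
  kind <- match.arg(kind, c("low-pass", "band-pass"))
  if (is.null(cutoffs))
    cutoffs <- switch(modality, ECG = c(1, 30), EDA = 1, RF = 3)
  if (kind == "low-pass" && length(cutoffs) != 1)
    stop("filter_spec: low-pass needs exactly one cutoff", call. = FALSE)
  if (kind == "band-pass" &&
      (length(cutoffs) != 2 || cutoffs[1] >= cutoffs[2]))
    stop("filter_spec: band-pass needs two increasing cutoffs",
         call. = FALSE)
  if (any(cutoffs <= 0))
    stop("filter_spec: cutoffs must be positive", call. = FALSE)
  if (!is.null(order) && (order < 2 || order %% 2 != 0))
    stop("filter_spec: order must be an even integer >= 2", call. = FALSE)
  structure(list(modality = modality, kind = kind, cutoffs = cutoffs,
                 order = order, phase_mode = phase_mode),
            class = "filter_spec")
}

# Default order rule: 4 * fs / lowest cutoff taps, rounded to even,
# capped at 8192.
default_fir_order <- function(spec, fs) {
  ord <- ceiling(4 * fs / min(spec$cutoffs))
  ord <- ord + ord %% 2
  min(ord, 8192L)
}

#' Design a linear-phase FIR filter
#'
#' Hamming-window frequency-sampling design via [signal::fir2()], on a
#' grid fine enough to resolve cutoffs far below Nyquist (the fixed
#' 512-point grid of [signal::fir1()] misplaces a 1 Hz edge at a 1000 Hz
#' sampling rate). The returned coefficient vector is symmetric (exactly
#' linear phase), is normalized to unit gain at the passband center, and
#' its magnitude response crosses each cutoff at about -6 dB, the
#' standard behavior of window-design filters.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz. All cutoffs must be below `fs / 2`.
#' @return Numeric coefficient vector of length `order + 1`, with the
#'   design order attached as attribute `order`.
#' @export
design_fir <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (any(spec$cutoffs >= fs / 2))
    stop("design_fir: cutoff at or above Nyquist (", fs / 2, " Hz)",
         call. = FALSE)
  ord <- if (is.null(spec$order)) default_fir_order(spec, fs) else spec$order
  w <- spec$cutoffs / (fs / 2)
  if (spec$kind == "low-pass") {
    f <- c(0, w, w, 1)
    m <- c(1, 1, 0, 0)
    center <- w / 2
  } else {
    f <- c(0, w[1], w[1], w[2], w[2], 1)
    m <- c(0, 0, 1, 1, 0, 0)
    center <- mean(w)
  }
  grid_n <- 2^ceiling(log2(max(512, 4 * (ord + 1))))
  h <- as.numeric(signal::fir2(ord, f, m, grid_n = grid_n, ramp_n = 2,
                               window = signal::hamming(ord + 1)))
  # unit gain at the passband center
  h <- h / fir_response(h, center * fs / 2, fs)
  attr(h, "order") <- ord
  h
}

#' Magnitude frequency response of an FIR filter
#'
#' Direct evaluation of `|sum_k h_k exp(-i 2 pi f k / fs)|` at the
#' requested frequencies.
#'
#' @param h FIR coefficient vector.
#' @param freqs Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return Magnitude (linear scale) at each frequency.
#' @export
fir_response <- function(h, freqs, fs) {
  k <- seq_along(h) - 1
  vapply(freqs, function(f)
    Mod(sum(h * exp(-2i * pi * f * k / fs))), numeric(1))
}

#' Filter a recording
#'
#' Applies the FIR filter designed by [design_fir()] to a record. The
#' default zero-phase mode applies the filter forward and backward, so the
#' effective magnitude response is squared and the phase is exactly zero;
#' edges are handled by odd-symmetric reflection padding of one filter
#' length at each end, and the output has the same length as the input.
#' Single-pass mode applies the filter once and compensates the (integer)
#' group delay of the linear-phase filter.
#'
#' @param record A [signal_record()].
#' @param spec A [filter_spec()]; defaults to the record's modality spec.
#' @return The filtered [signal_record()].
#' @export
filter_signal <- function(record, spec = NULL) {
  stopifnot(inherits(record, "signal_record"))
  if (is.null(spec)) spec <- filter_spec(record$modality)
  h <- design_fir(spec, record$fs)
  ord <- attr(h, "order")
  x <- record$samples
  n <- length(x)
  if (n < 3 * ord)
    stop("filter_signal: signal length ", n, " is shorter than 3 x filter ",
         "order (", 3 * ord, "); use a shorter filter or a longer signal",
         call. = FALSE)
  L <- length(h)
  # odd-symmetric reflection padding of one filter length
  pre <- 2 * x[1] - x[(L + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - L)]
  xp <- c(pre, x, post)
  if (spec$phase_mode == "zero-phase") {
    # forward-backward pass of a symmetric FIR == one convolution with
    # conv(h, h), total delay 2 * (L - 1) / 2 = ord
    h2 <- fft_conv(h, h)
    y <- fft_conv(xp, h2)
    y <- y[(ord + 1):(ord + length(xp))]
  } else {
    y <- fft_conv(xp, h)
    y <- y[(ord / 2 + 1):(ord / 2 + length(xp))]
  }
  out <- record
  out$samples <- y[(L + 1):(L + n)]
  out
}

#' Amplitude normalization and mean removal
#'
#' Scales the whole record by its total energy and then removes the sample
#' mean. The default `unit-energy` mode divides by the square root of the
#' total energy, `x / sqrt(sum(x^2))`, so the scaled record has total
#' energy exactly 1 and the normalization is invariant to positive
#' rescaling of the input. The `literal` mode divides by the total energy
#' itself, `x / sum(x^2)`, for strict compatibility with the alternative
#' (non-scale-invariant) reading of the normalization; see the methods
#' vignette. In both modes the mean is subtracted after scaling.
#'
#' @param record A [signal_record()].
#' @param mode `"unit-energy"` (default) or `"literal"`.
#' @return The normalized [signal_record()] (units become dimensionless).
#' @export
normalize_amplitude <- function(record,
                                mode = c("unit-energy", "literal")) {
  stopifnot(inherits(record, "signal_record"))
  mode <- match.arg(mode)
  x <- record$samples
  energy <- sum(x^2)
  if (energy == 0)
    stop("normalize_amplitude: signal has zero energy", call. = FALSE)
  x <- if (mode == "unit-energy") x / sqrt(energy) else x / energy
  x <- x - mean(x)
  out <- record
  out$samples <- x
  out$units <- "normalized"
  out
}
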