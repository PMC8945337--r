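# Internal numerical helpers.

# Linear (open) convolution via FFT; returns length(x) + length(h) - 1.
# Zero-pads to a 2-3-5-smooth length (stats::nextn): R's mixed-radix FFT
# degrades badly on lengths with large prime factors.
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1
  nf <- stats::nextn(n, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(nf - length(x))))
  H <- stats::fft(c(h, numeric(nf - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nf
}

# Deterministic substream seed for (master seed, subject, modality,
# condition). Pure integer arithmetic carried out in doubles: every product
# stays below 2^53, so the result is exact and platform independent.
# Adding a subject never changes another subject's stream because the
# substream depends only on that subject's own indices.
substream_seed <- function(master, subject_idx, modality, condition) {
  mod_code <- match(modality, c("ECG", "EDA", "RF"))
  cond_code <- match(condition, c("caffeine", "placebo"))
  m <- 2147483647  # 2^31 - 1
  h <- (master %% m) * 1000003 %% m
  h <- (h + subject_idx * 10007) %% m
  h <- (h * 65537 + mod_code * 101 + cond_code) %% m
  as.integer(h)
}

# Stationary mean-reverting (discrete Ornstein-Uhlenbeck) noise with
# stationary sd `sd` and correlation time `tau` seconds. The recursion is
# evaluated at C level via stats::filter; the initial state is drawn from
# the stationary distribution so there is no burn-in transient.
ou_noise <- function(n, fs, sd, tau) {
  if (sd == 0) return(numeric(n))
  rho <- exp(-1 / (tau * fs))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  x0 <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive")) +
    x0 * rho^seq_len(n)
}

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
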