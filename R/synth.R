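#' Per-subject physiological parameters
#'
#' Baseline autonomic parameters and effect gains for one simulated
#' volunteer. The effect gains are dimensionless multipliers that convert
#' the (normalized) pharmacokinetic effect into a fractional change of the
#' corresponding physiological quantity: `alpha_ecg` scales heart rate,
#' `beta_eda_tonic` the tonic skin-conductance level, `gamma_scr` the
#' skin-conductance-response rate, and `delta_resp` the breathing rate.
#' Noise parameters control measurement and slow physiological noise; set
#' them (and `hrv_sd`) to zero for noise-free synthesis.
#'
#' @param subject_id Identifier string.
#' @param hr_baseline Resting heart rate, beats/min (40-200).
#' @param hrv_sd Standard deviation of RR-interval jitter, ms (>= 0).
#' @param eda_tonic Tonic skin conductance level, microsiemens (>= 0).
#' @param scr_rate Baseline skin-conductance-response rate, events/min.
#' @param resp_rate Baseline breathing rate, breaths/min (6-30).
#' @param effect_gains Named numeric vector with elements `alpha_ecg`,
#'   `beta_eda_tonic`, `gamma_scr`, `delta_resp`; all >= 0.
#' @param ecg_noise_sd White measurement noise on the ECG, mV.
#' @param eda_drift_sd Stationary standard deviation of the slow
#'   mean-reverting tonic wander, as a fraction of `eda_tonic`.
#' @param eda_noise_sd White measurement noise on the EDA, microsiemens.
#' @param resp_amp_sd Stationary standard deviation of the slow amplitude
#'   modulation of the respiration trace (fraction of unit amplitude).
#' @param resp_noise_sd White measurement noise on the respiration trace.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S01",
                           hr_baseline = 70, hrv_sd = 35,
                           eda_tonic = 4, scr_rate = 8, resp_rate = 15,
                           effect_gains = c(alpha_ecg = 0.15,
                                            beta_eda_tonic = 0.15,
                                            gamma_scr = 0.1,
                                            delta_resp = 0.05),
                           ecg_noise_sd = 0.03,
                           eda_drift_sd = 0.015, eda_noise_sd = 0.01,
                           resp_amp_sd = 0.25, resp_noise_sd = 0.3) {
  need <- c("alpha_ecg", "beta_eda_tonic", "gamma_scr", "delta_resp")
  if (!all(need %in% names(effect_gains)))
    stop("subject_params: effect_gains must name ",
         paste(need, collapse = ", "), call. = FALSE)
  effect_gains <- effect_gains[need]
  if (hr_baseline < 40 || hr_baseline > 200)
    stop("subject_params: hr_baseline must lie in [40, 200] bpm",
         call. = FALSE)
  if (resp_rate < 6 || resp_rate > 30)
    stop("subject_params: resp_rate must lie in [6, 30] breaths/min",
         call. = FALSE)
  if (eda_tonic < 0 || scr_rate < 0 || hrv_sd < 0)
    stop("subject_params: eda_tonic, scr_rate and hrv_sd must be >= 0",
         call. = FALSE)
  if (any(effect_gains < 0))
    stop("subject_params: effect gains must be >= 0", call. = FALSE)
  if (ecg_noise_sd < 0 || eda_drift_sd < 0 || eda_noise_sd < 0 ||
      resp_amp_sd < 0 || resp_noise_sd < 0)
    stop("subject_params: noise parameters must be >= 0", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 hr_baseline = hr_baseline, hrv_sd = hrv_sd,
                 eda_tonic = eda_tonic, scr_rate = scr_rate,
                 resp_rate = resp_rate, effect_gains = effect_gains,
                 ecg_noise_sd = ecg_noise_sd,
                 eda_drift_sd = eda_drift_sd, eda_noise_sd = eda_noise_sd,
                 resp_amp_sd = resp_amp_sd, resp_noise_sd = resp_noise_sd),
            class = "subject_params")
}

#' Synthetic cohort configuration
#'
#' Describes a full simulated study: cohort size, session duration,
#' sampling rate, the caffeine release profile, per-modality scaling of
#' the effect gains, the optional end-of-session electrode-removal
#' artifact on the EDA channel, and the master seed. The same
#' configuration and seed always reproduce the cohort bit-exactly.
#'
#' @param n_subjects Number of volunteers (>= 2). Default 13.
#' @param duration Session length in minutes (>= 10). Default 50, which
#'   yields ten 5-minute analysis segments.
#' @param fs Sampling rate in Hz; must be at least 60 so that the default
#'   1-30 Hz ECG band fits under Nyquist. Default 1000.
#' @param pk A [pk_profile()] for the caffeine condition. The placebo
#'   condition always uses the zero-dose version of the same profile.
#' @param modality_effect_scaling Named multipliers (`ecg`, `eda`, `rf`)
#'   applied on top of the subjects' effect gains.
#' @param artifact_final_segment If `TRUE`, a high-amplitude noise burst is
#'   added to the final 5 minutes of every EDA record, emulating electrodes
#'   being pulled off at the end of the session.
#' @param seed Master seed (integer). All per-record substreams are derived
#'   from it deterministically.
#' @param effect_ref Reference effect amplitude used to normalize the
#'   pharmacokinetic effect inside the simulators; the default 1 means an
#'   effect value of 1 produces the full gain (e.g. a 15 percent heart-rate
#'   rise with `alpha_ecg = 0.15`).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 13, duration = 50, fs = 1000,
                          pk = pk_profile(),
                          modality_effect_scaling = c(ecg = 1, eda = 1,
                                                      rf = 1),
                          artifact_final_segment = FALSE,
                          seed = 42, effect_ref = 1) {
  stopifnot(inherits(pk, "pk_profile"))
  if (n_subjects < 2)
    stop("cohort_config: n_subjects must be >= 2", call. = FALSE)
  if (duration < 10)
    stop("cohort_config: duration must be >= 10 min", call. = FALSE)
  if (fs < 60)
    stop("cohort_config: fs must be >= 60 Hz (twice the highest default ",
         "filter cutoff of 30 Hz)", call. = FALSE)
  need <- c("ecg", "eda", "rf")
  if (!all(need %in% names(modality_effect_scaling)))
    stop("cohort_config: modality_effect_scaling must name ecg, eda, rf",
         call. = FALSE)
  if (any(modality_effect_scaling < 0))
    stop("cohort_config: modality_effect_scaling must be >= 0",
         call. = FALSE)
  if (effect_ref <= 0)
    stop("cohort_config: effect_ref must be positive", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), duration = duration,
                 fs = fs, pk = pk,
                 modality_effect_scaling = modality_effect_scaling[need],
                 artifact_final_segment = isTRUE(artifact_final_segment),
                 seed = as.integer(seed), effect_ref = effect_ref),
            class = "cohort_config")
}

# Shared argument checks for the three simulators.
check_sim_args <- function(duration, fs, subject, effect) {
  stopifnot(inherits(subject, "subject_params"))
  n <- round(duration * 60 * fs)
  if (abs(duration * 60 * fs - n) > 1e-6)
    stop("simulate: duration * 60 * fs must be a whole sample count",
         call. = FALSE)
  if (length(effect) != n)
    stop(sprintf(paste0("simulate: effect array has %d values but the ",
                        "duration grid has %d samples"),
                 length(effect), n), call. = FALSE)
  if (any(effect < 0))
    stop("simulate: effect must be nonnegative", call. = FALSE)
  n
}

# PQRST template: one Gaussian bump per wave, offsets/widths in seconds
# relative to the R peak, amplitudes in mV.
ecg_template <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             offset = c(-0.180, -0.022, 0, 0.024, 0.230),
             width = c(0.030, 0.009, 0.011, 0.009, 0.045),
             amp = c(0.12, -0.12, 1.1, -0.18, 0.35))
}

#' Simulate an electrocardiogram record
#'
#' Template-based PQRST synthesis: beats are placed on an RR grid derived
#' from the instantaneous heart rate
#' `HR(t) = hr_baseline * (1 + alpha_ecg * effect(t) / effect_ref)`, each
#' beat is a fixed sum of five Gaussian bumps (P, Q, R, S, T), beat times
#' receive Gaussian jitter so that RR intervals have standard deviation
#' `hrv_sd`, and white measurement noise is added.
#'
#' @param duration Record length, minutes.
#' @param fs Sampling rate, Hz. `duration * 60 * fs` must be whole.
#' @param subject A [subject_params()].
#' @param effect Per-sample nonnegative effect array of length
#'   `duration * 60 * fs`.
#' @param seed Integer seed for this record's random stream.
#' @param condition Condition label stored on the record.
#' @param effect_ref Reference effect amplitude (see [cohort_config()]).
#' @return A [signal_record()] with `modality = "ECG"`, units mV.
#' @export
simulate_ecg <- function(duration, fs, subject, effect, seed,
                         condition = "placebo", effect_ref = 1) {
  n <- check_sim_args(duration, fs, subject, effect)
  set.seed(seed)
  e <- effect / effect_ref
  hr <- subject$hr_baseline * (1 + subject$effect_gains[["alpha_ecg"]] * e)
  beats_elapsed <- cumsum(hr / 60) / fs
  n_beats <- floor(beats_elapsed[n])
  x <- numeric(n)
  if (n_beats >= 1) {
    # sample index where the k-th beat boundary is crossed
    idx <- findInterval(seq_len(n_beats), beats_elapsed) + 1
    beat_t <- idx / fs
    if (subject$hrv_sd > 0) {
      # independent jitter on beat times; RR sd = hrv_sd
      beat_t <- beat_t +
        stats::rnorm(n_beats, 0, subject$hrv_sd / 1000 / sqrt(2))
    }
    tmpl <- ecg_template()
    for (w in seq_len(nrow(tmpl))) {
      # beats are farther apart than one bump's support, so within a
      # bump type all sample indices are distinct and can be written in
      # one vectorized assignment
      mu <- beat_t + tmpl$offset[w]
      sg <- tmpl$width[w]
      half <- ceiling(4 * sg * fs)
      ctr <- round(mu * fs)
      off <- -half:half
      if (n_beats > 1 && min(diff(ctr)) <= 2 * half) {
        # very short RR intervals: neighboring bumps overlap, accumulate
        # beat by beat
        for (k in seq_len(n_beats)) {
          idx <- ctr[k] + off
          ok <- idx >= 1 & idx <= n
          x[idx[ok]] <- x[idx[ok]] + tmpl$amp[w] *
            exp(-0.5 * ((idx[ok] / fs - mu[k]) / sg)^2)
        }
      } else {
        idx <- rep(ctr, each = length(off)) + off
        tt <- idx / fs
        val <- tmpl$amp[w] *
          exp(-0.5 * ((tt - rep(mu, each = length(off))) / sg)^2)
        ok <- idx >= 1 & idx <= n
        x[idx[ok]] <- x[idx[ok]] + val[ok]
      }
    }
  }
  if (subject$ecg_noise_sd > 0)
    x <- x + stats::rnorm(n, 0, subject$ecg_noise_sd)
  signal_record(x, fs, "ECG", subject$subject_id, condition, units = "mV")
}

# Biexponential SCR kernel (fast rise, slow decay), peak-normalized to 1.
scr_kernel <- function(fs, tau_rise = 0.75, tau_decay = 2.5, amp = 1) {
  t <- seq(0, 6 * tau_decay, by = 1 / fs)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  amp * k / max(k)
}

#' Simulate an electrodermal activity record
#'
#' Skin conductance is modelled as a tonic level (a slow mean-reverting
#' wander around `eda_tonic`, raised multiplicatively by
#' `beta_eda_tonic * effect`) plus
#' phasic skin-conductance responses: event times drawn from an
#' inhomogeneous Poisson process of rate
#' `scr_rate * (1 + gamma_scr * effect)` and convolved with a
#' biexponential fast-rise/slow-decay kernel. White measurement noise is
#' added and the result is clipped at zero (conductance is nonnegative).
#' With `artifact_final_segment = TRUE`, a high-amplitude noise burst is
#' added to the final five minutes, emulating electrode removal.
#'
#' The number of SCR events drawn (before convolution) is attached to the
#' returned record as attribute `n_scr`.
#'
#' @inheritParams simulate_ecg
#' @param artifact_final_segment Add the terminal noise burst.
#' @return A [signal_record()] with `modality = "EDA"`, units microsiemens.
#' @export
simulate_eda <- function(duration, fs, subject, effect, seed,
                         condition = "placebo", effect_ref = 1,
                         artifact_final_segment = FALSE) {
  n <- check_sim_args(duration, fs, subject, effect)
  set.seed(seed)
  e <- effect / effect_ref
  tonic <- subject$eda_tonic *
    (1 + subject$effect_gains[["beta_eda_tonic"]] * e)
  if (subject$eda_drift_sd > 0)
    tonic <- tonic + ou_noise(n, fs, subject$eda_tonic *
                                subject$eda_drift_sd, tau = 300)
  # inhomogeneous Poisson SCR events by thinning
  rate <- subject$scr_rate * (1 + subject$effect_gains[["gamma_scr"]] * e) / 60
  rmax <- max(rate)
  n_scr <- 0L
  phasic <- numeric(n)
  if (rmax > 0) {
    dur_s <- n / fs
    n_cand <- stats::rpois(1, rmax * dur_s)
    if (n_cand > 0) {
      cand_t <- sort(stats::runif(n_cand, 0, dur_s))
      cand_i <- pmin(floor(cand_t * fs) + 1L, n)
      keep <- stats::runif(n_cand) < rate[cand_i] / rmax
      ev_i <- cand_i[keep]
      n_scr <- length(ev_i)
      if (n_scr > 0) {
        amps <- stats::rlnorm(n_scr, meanlog = log(0.5), sdlog = 0.3)
        imp <- numeric(n)
        for (j in seq_len(n_scr)) imp[ev_i[j]] <- imp[ev_i[j]] + amps[j]
        phasic <- fft_conv(imp, scr_kernel(fs))[seq_len(n)]
      }
    }
  }
  x <- tonic + phasic
  if (subject$eda_noise_sd > 0)
    x <- x + stats::rnorm(n, 0, subject$eda_noise_sd)
  if (isTRUE(artifact_final_segment)) {
    burst_n <- min(n, round(300 * fs))
    idx <- (n - burst_n + 1):n
    x[idx] <- x[idx] + stats::rnorm(burst_n, 0, 3 * subject$eda_tonic)
  }
  x <- pmax(x, 0)
  rec <- signal_record(x, fs, "EDA", subject$subject_id, condition,
                       units = "uS")
  attr(rec, "n_scr") <- n_scr
  rec
}

#' Simulate a respiration record
#'
#' Thoracic-band respiration is modelled as a quasi-sinusoid whose
#' instantaneous frequency is
#' `resp_rate * (1 + delta_resp * effect(t) / effect_ref) / 60` Hz, with
#' slow random amplitude modulation and additive white measurement noise.
#'
#' @inheritParams simulate_ecg
#' @return A [signal_record()] with `modality = "RF"`, arbitrary units.
#' @export
simulate_resp <- function(duration, fs, subject, effect, seed,
                          condition = "placebo", effect_ref = 1) {
  n <- check_sim_args(duration, fs, subject, effect)
  set.seed(seed)
  e <- effect / effect_ref
  f_inst <- subject$resp_rate *
    (1 + subject$effect_gains[["delta_resp"]] * e) / 60
  phase <- 2 * pi * cumsum(f_inst) / fs
  amp <- 1 + ou_noise(n, fs, subject$resp_amp_sd, tau = 60)
  x <- amp * sin(phase)
  if (subject$resp_noise_sd > 0)
    x <- x + stats::rnorm(n, 0, subject$resp_noise_sd)
  signal_record(x, fs, "RF", subject$subject_id, condition, units = "a.u.")
}

# Draw one subject's parameters from the cohort priors (seeded from the
# master seed and the subject index only, so adding a subject never
# perturbs existing subjects). Gains get mild lognormal between-subject
# variability around the defaults.
draw_subject_params <- function(k, master_seed) {
  m <- 2147483647
  set.seed(as.integer(((master_seed %% m) * 69069 + k * 2654435) %% m))
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  g <- c(alpha_ecg = 0.15, beta_eda_tonic = 0.15,
         gamma_scr = 0.1, delta_resp = 0.05) *
    stats::rlnorm(4, 0, 0.15)
  subject_params(
    subject_id = sprintf("S%02d", k),
    hr_baseline = clamp(stats::rnorm(1, 70, 6), 50, 95),
    hrv_sd = clamp(stats::rnorm(1, 35, 8), 5, 80),
    eda_tonic = clamp(stats::rnorm(1, 4, 0.4), 2.5, 6),
    scr_rate = clamp(stats::rnorm(1, 8, 2), 3, 14),
    resp_rate = clamp(stats::rnorm(1, 15, 1.5), 8, 25),
    effect_gains = g)
}

#' Generate a full synthetic cohort
#'
#' For each subject, parameters are drawn from documented priors (seeded),
#' then all three modalities are simulated under both conditions: the
#' caffeine condition uses the configured [pk_profile()], the placebo
#' condition its zero-dose version. Every record's random stream is an
#' independent substream derived from the master seed, the subject index,
#' the modality and the condition, so the cohort is bit-reproducible and
#' adding subjects never changes existing records.
#'
#' @param config A [cohort_config()].
#' @return A list of `n_subjects * 6` [signal_record()] objects, named
#'   `<subject>_<modality>_<condition>`.
#' @examples
#' cfg <- cohort_config(n_subjects = 2, duration = 10, fs = 100)
#' cohort <- generate_cohort(cfg)
#' length(cohort)  # 12
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- round(config$duration * 60 * config$fs)
  t_min <- (seq_len(n) - 1) / (config$fs * 60)
  eff_caf <- effect_profile(t_min, config$pk)
  pk0 <- pk_profile(0, 0, config$pk$ka_free, config$pk$ka_encapsulated,
                    config$pk$ke, config$pk$lag)
  eff_plc <- effect_profile(t_min, pk0)
  scal <- config$modality_effect_scaling
  out <- list()
  for (k in seq_len(config$n_subjects)) {
    subj <- draw_subject_params(k, config$seed)
    for (cond in c("caffeine", "placebo")) {
      eff <- if (cond == "caffeine") eff_caf else eff_plc
      for (mod in c("ECG", "EDA", "RF")) {
        sj <- subj
        sc <- scal[[switch(mod, ECG = "ecg", EDA = "eda", RF = "rf")]]
        sj$effect_gains <- sj$effect_gains *
          c(alpha_ecg = if (mod == "ECG") sc else 1,
            beta_eda_tonic = if (mod == "EDA") sc else 1,
            gamma_scr = if (mod == "EDA") sc else 1,
            delta_resp = if (mod == "RF") sc else 1)
        sseed <- substream_seed(config$seed, k, mod, cond)
        rec <- switch(mod,
          ECG = simulate_ecg(config$duration, config$fs, sj, eff, sseed,
                             condition = cond,
                             effect_ref = config$effect_ref),
          EDA = simulate_eda(config$duration, config$fs, sj, eff, sseed,
                             condition = cond,
                             effect_ref = config$effect_ref,
                             artifact_final_segment =
                               config$artifact_final_segment),
          RF = simulate_resp(config$duration, config$fs, sj, eff, sseed,
                             condition = cond,
                             effect_ref = config$effect_ref))
        out[[sprintf("%s_%s_%s", subj$subject_id, mod, cond)]] <- rec
      }
    }
  }
  out
}
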