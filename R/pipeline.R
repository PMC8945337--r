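#' Full study configuration
#'
#' Bundles every stage's settings: the synthetic cohort, the per-modality
#' filters, the feature settings, the classification settings, and an
#' optional output directory. One master seed (the cohort's) governs the
#' whole run.
#'
#' @param cohort A [cohort_config()].
#' @param filters Named list of [filter_spec()] per modality; defaults to
#'   the protocol filters.
#' @param normalization_mode Passed to [normalize_amplitude()]. The
#'   pipeline default is `"literal"` (divide by the total energy): unlike
#'   the unit-energy form it preserves each record's between-condition
#'   energy ratio as a uniform shift of the segment-energy profile, which
#'   is what makes the group curves separable by every classifier; see
#'   the methods vignette.
#' @param segment_min,window_s Feature settings in minutes / seconds.
#' @param zscore_sd `"population"` or `"sample"` (see [zscore_joint()]).
#' @param sample_unit `"group_point"` (default: each classification sample
#'   is one z-scored per-segment group-mean energy, 10 points per class
#'   for a 50-minute session) or `"subject_point"` (one sample per subject
#'   and segment, for sensitivity analysis).
#' @param output_dir Directory for persisted outputs, or `NULL` to keep
#'   the run in memory only.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         filters = list(ECG = filter_spec("ECG"),
                                        EDA = filter_spec("EDA"),
                                        RF = filter_spec("RF")),
                         normalization_mode = "literal",
                         segment_min = 5, window_s = 5,
                         zscore_sd = "population",
                         sample_unit = c("group_point", "subject_point"),
                         output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  sample_unit <- match.arg(sample_unit)
  for (mod in c("ECG", "EDA", "RF"))
    if (!inherits(filters[[mod]], "filter_spec"))
      stop("study_config: filters$", mod, " must be a filter_spec",
           call. = FALSE)
  structure(list(cohort = cohort, filters = filters,
                 normalization_mode = normalization_mode,
                 segment_min = segment_min, window_s = window_s,
                 zscore_sd = zscore_sd, sample_unit = sample_unit,
                 output_dir = output_dir),
            class = "study_config")
}

# Deterministic hash of a configuration (md5 of its serialization).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run a complete study
#'
#' Executes the whole pipeline: cohort synthesis, per-modality FIR
#' filtering, amplitude normalization and mean removal, 5-minute
#' segmentation with windowed power-energy features, group-mean profile
#' formation with joint z-scoring, and leave-one-out evaluation of the
#' classifier bank. Identical configurations reproduce results bit
#' exactly.
#'
#' @param config A [study_config()].
#' @param verbose Print per-stage progress messages.
#' @return An object of class `study_result`: `profiles` (data frame of
#'   raw and z-scored group-mean energies per modality/group/segment),
#'   `table` (the classifier accuracy table), `points` (the
#'   [labeled_points()] fed to the bank, per modality) and `provenance`
#'   (config hash, seed, package and R versions). If
#'   `config$output_dir` is set, `profiles.csv`, `results.csv` and
#'   `provenance.json` are written there.
#' @examples
#' \donttest{
#' cfg <- study_config(cohort_config(n_subjects = 3, duration = 10,
#'                                   fs = 100, seed = 7))
#' res <- run_study(cfg)
#' res$table
#' }
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("synth: generating %d-subject cohort at %g Hz",
      config$cohort$n_subjects, config$cohort$fs)
  cohort <- generate_cohort(config$cohort)

  say("preprocess + features: %d records", length(cohort))
  seg_energies <- lapply(cohort, function(rec) {
    rec <- filter_signal(rec, config$filters[[rec$modality]])
    rec <- normalize_amplitude(rec, config$normalization_mode)
    suppressMessages(
      record_segment_energies(rec, config$segment_min, config$window_s))
  })

  modalities <- c("ECG", "EDA", "RF")
  profiles <- list()
  points <- list()
  prof_rows <- list()
  for (mod in modalities) {
    per_cond <- lapply(c("caffeine", "placebo"), function(cond) {
      keys <- grep(sprintf("_%s_%s$", mod, cond), names(seg_energies),
                   value = TRUE)
      do.call(rbind, seg_energies[keys])
    })
    names(per_cond) <- c("caffeine", "placebo")
    n_seg <- min(vapply(per_cond, ncol, integer(1)))
    raw_caf <- group_mean_profile(per_cond$caffeine[, seq_len(n_seg),
                                                    drop = FALSE],
                                  "caffeine", mod)
    raw_plc <- group_mean_profile(per_cond$placebo[, seq_len(n_seg),
                                                   drop = FALSE],
                                  "placebo", mod)
    z <- zscore_joint(raw_caf, raw_plc, config$zscore_sd)
    profiles[[mod]] <- list(caffeine = z[[1]], placebo = z[[2]],
                            caffeine_raw = raw_caf, placebo_raw = raw_plc)
    if (config$sample_unit == "group_point") {
      points[[mod]] <- labeled_points(
        c(z[[1]]$points, z[[2]]$points),
        rep(c("caffeine", "placebo"), each = n_seg))
    } else {
      subj_mat <- rbind(per_cond$caffeine[, seq_len(n_seg), drop = FALSE],
                        per_cond$placebo[, seq_len(n_seg), drop = FALSE])
      labs <- rep(c("caffeine", "placebo"),
                  c(nrow(per_cond$caffeine), nrow(per_cond$placebo)))
      vals <- as.numeric(t(subj_mat))
      zvals <- (vals - mean(vals)) /
        (if (config$zscore_sd == "population") sd_pop(vals)
         else stats::sd(vals))
      points[[mod]] <- labeled_points(zvals, rep(labs, each = n_seg))
    }
    prof_rows[[mod]] <- data.frame(
      segment_index = rep(seq_len(n_seg) - 1, 2),
      group = rep(c("caffeine", "placebo"), each = n_seg),
      modality = mod,
      mean_energy = c(raw_caf$points, raw_plc$points),
      zscored_energy = c(z[[1]]$points, z[[2]]$points))
  }

  say("classify: leave-one-out over the %d-classifier bank",
      length(classifier_bank()))
  table <- run_classifier_bank(points)

  provenance <- list(
    config_hash = config_hash(config),
    seed = config$cohort$seed,
    n_subjects = config$cohort$n_subjects,
    duration_min = config$cohort$duration,
    fs_hz = config$cohort$fs,
    package_version = as.character(utils::packageVersion("filmsense")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  result <- structure(list(profiles = profiles,
                           table = table,
                           points = points,
                           profile_table = do.call(rbind, prof_rows),
                           provenance = provenance),
                      class = "study_result")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result$profile_table,
                     file.path(config$output_dir, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(table, file.path(config$output_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(config$output_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  cat(sprintf("  seed %d | %d subjects | %g min @ %g Hz\n",
              x$provenance$seed, x$provenance$n_subjects,
              x$provenance$duration_min, x$provenance$fs_hz))
  cat("  classifier accuracy table (%):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Mean bank accuracy per modality
#'
#' Column means of the accuracy table of a [run_study()] result —
#' a one-number summary of how discriminable each modality is.
#'
#' @param result A `study_result` (or the accuracy table itself).
#' @return Named numeric vector of mean accuracies (percent) per modality.
#' @export
bank_mean_accuracy <- function(result) {
  tab <- if (inherits(result, "study_result")) result$table else result
  cols <- grep("^acc_", names(tab), value = TRUE)
  out <- colMeans(tab[cols])
  names(out) <- sub("^acc_", "", cols)
  out
}
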