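# Synthetic tremor cohort generator.
#
# The signal model is an amplitude-modulated stack of phase-coupled
# harmonics of a per-subject fundamental, plus sub-1 Hz postural drift,
# a 50 Hz mains sinusoid and white sensor noise, distributed over three
# accelerometer axes along a fixed per-subject direction.  The per-group
# distribution parameters (fundamental frequency, log tremor intensity)
# default to published clinical cohort summary statistics shipped in
# `inst/extdata/reference_group_stats.csv`.

# Evaluate `code` under a private RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-(subject, posture) substream seed, kept below 2^31.
# Keyed on (subgroup, within-subgroup index) so growing one subgroup
# leaves every other subject's stream untouched.
derive_seed <- function(seed, subgroup, within_index, posture) {
  sg <- match(subgroup, c("PD1", "PD2", "ET1", "ET2"))
  off <- if (posture == "P1") 0 else 499979
  as.integer((as.numeric(seed) %% 65011 * 32749 +
              (sg * 4096 + within_index) * 1009 + off) %% 2147483629 + 1)
}

#' Published cohort summary statistics used for calibration
#'
#' Group-level means and standard deviations of ln(MAV) and dominant
#' frequency (under both spectrum estimates) for PD and ET cohorts and
#' their stage subgroups, under the arm-stretching (P1) and arm-rested
#' (P2) postures.  These are the calibration targets of the synthetic
#' generator and the inputs of the worked-example discrimination
#' statistics.
#'
#' @return A data.frame with columns `feature, posture, group, mean, sd`.
#' @export
reference_group_stats <- function() {
  path <- system.file("extdata", "reference_group_stats.csv",
                      package = "tremordiff", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

ref_stat <- function(stats, feature, posture, group) {
  row <- stats[stats$feature == feature & stats$posture == posture &
               stats$group == group, ]
  if (nrow(row) != 1) stop("no unique reference row for ", feature, "/",
                           posture, "/", group)
  c(mean = row$mean, sd = row$sd)
}

#' Per-group tremor signal model
#'
#' Distribution and nuisance parameters for one (cohort, posture) cell of
#' the generator.
#'
#' @param tremor_freq_mean,tremor_freq_sd Between-subject distribution of
#'   the tremor fundamental, Hz.  Subject fundamentals are drawn from
#'   this normal truncated to (1.5, 15) Hz.
#' @param ln_mav_mean,ln_mav_sd Between-subject distribution of the
#'   post-pipeline log tremor intensity, ln(m/s^2).
#' @param harmonic_amplitudes Amplitude ratios of harmonics 1..H relative
#'   to the fundamental (first element must be 1).  Harmonic phases are
#'   fully coupled (phase of harmonic h = h x fundamental phase), which
#'   is what makes the bispectrum diagonal non-degenerate.
#' @param freq_jitter_sd Stationary SD of the slow first-order
#'   autoregressive wander of the instantaneous frequency, Hz.
#' @param freq_jitter_tau Time constant of that wander, s.
#' @param amp_mod_depth Depth of the slow sinusoidal amplitude
#'   modulation, in [0, 1).
#' @param drift_amp SD of the sub-1 Hz postural drift per axis, m/s^2.
#' @param mains_amp Amplitude of the 50 Hz mains component, m/s^2.
#' @param noise_sd SD of the white sensor noise per axis, m/s^2.
#' @return An object of class `group_signal_model`.
#' @export
group_signal_model <- function(tremor_freq_mean, tremor_freq_sd,
                               ln_mav_mean, ln_mav_sd,
                               harmonic_amplitudes = c(1, 0.4, 0.15),
                               freq_jitter_sd = 0.15,
                               freq_jitter_tau = 10,
                               amp_mod_depth = 0.3,
                               drift_amp = 0.2,
                               mains_amp = 0.05,
                               noise_sd = 0.02) {
  stopifnot(tremor_freq_mean > 1, tremor_freq_mean < 20,
            tremor_freq_sd >= 0, ln_mav_sd >= 0,
            length(harmonic_amplitudes) >= 1,
            harmonic_amplitudes[1] == 1,
            amp_mod_depth >= 0, amp_mod_depth < 1,
            freq_jitter_sd >= 0, freq_jitter_tau > 0,
            drift_amp >= 0, mains_amp >= 0, noise_sd >= 0)
  structure(list(tremor_freq_mean = tremor_freq_mean,
                 tremor_freq_sd = tremor_freq_sd,
                 ln_mav_mean = ln_mav_mean, ln_mav_sd = ln_mav_sd,
                 harmonic_amplitudes = harmonic_amplitudes,
                 freq_jitter_sd = freq_jitter_sd,
                 freq_jitter_tau = freq_jitter_tau,
                 amp_mod_depth = amp_mod_depth,
                 drift_amp = drift_amp, mains_amp = mains_amp,
                 noise_sd = noise_sd),
            class = "group_signal_model")
}

#' Default per-(group, posture) signal models
#'
#' Calibrated to the published cohort statistics: the fundamental
#' frequency targets come from the bispectrum dominant-frequency rows and
#' the intensity targets from the ln(MAV) rows of
#' [reference_group_stats()].
#'
#' @param stats A calibration table as returned by
#'   [reference_group_stats()].
#' @param ... Further arguments passed to [group_signal_model()] (shared
#'   across all four models, e.g. `noise_sd`).
#' @return Nested list: `models[[group]][[posture]]`.
#' @export
default_group_models <- function(stats = reference_group_stats(), ...) {
  build <- function(group, posture) {
    fq <- ref_stat(stats, "domfreq_bispec", posture, group)
    lm <- ref_stat(stats, "ln_mav", posture, group)
    group_signal_model(tremor_freq_mean = unname(fq["mean"]),
                       tremor_freq_sd = unname(fq["sd"]),
                       ln_mav_mean = unname(lm["mean"]),
                       ln_mav_sd = unname(lm["sd"]), ...)
  }
  list(PD = list(P1 = build("PD", "P1"), P2 = build("PD", "P2")),
       ET = list(P1 = build("ET", "P1"), P2 = build("ET", "P2")))
}

#' Cohort generation configuration
#'
#' @param n_per_subgroup Named counts for the four subgroups
#'   (incipient/progressed PD and ET).
#' @param models Per-(group, posture) signal models, as from
#'   [default_group_models()].
#' @param recording_duration Recording length per posture, s.
#' @param sampling_rate Acquisition rate, Hz.
#' @param postures Postures to record (default both).
#' @param seed Master seed; every subject derives an independent
#'   substream from it, so adding a subject does not perturb the others.
#' @param fspec [filter_spec()] the intensity calibration assumes
#'   downstream.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_subgroup = c(PD1 = 13, PD2 = 13,
                                             ET1 = 12, ET2 = 12),
                          models = default_group_models(),
                          recording_duration = 300,
                          sampling_rate = 1000,
                          postures = c("P1", "P2"),
                          seed = 1,
                          fspec = filter_spec()) {
  stopifnot(all(n_per_subgroup >= 0), recording_duration > 0,
            sampling_rate > 0,
            all(postures %in% c("P1", "P2")))
  n_per_subgroup <- n_per_subgroup[c("PD1", "PD2", "ET1", "ET2")]
  if (any(is.na(n_per_subgroup))) stop("n_per_subgroup must name PD1, PD2, ET1, ET2")
  structure(list(n_per_subgroup = n_per_subgroup, models = models,
                 recording_duration = recording_duration,
                 sampling_rate = sampling_rate, postures = postures,
                 seed = seed, fspec = fspec),
            class = "cohort_config")
}

new_tremor_recording <- function(subject_id, group, stage, posture,
                                 sampling_rate, axes, trial_bounds) {
  stopifnot(is.matrix(axes), ncol(axes) == 3,
            is.matrix(trial_bounds), ncol(trial_bounds) == 2)
  n <- nrow(axes)
  stopifnot(all(trial_bounds >= 1), all(trial_bounds <= n),
            all(trial_bounds[, 2] >= trial_bounds[, 1]))
  if (nrow(trial_bounds) > 1) {
    stopifnot(all(diff(trial_bounds[, 1]) > 0),
              all(trial_bounds[-1, 1] > trial_bounds[-nrow(trial_bounds), 2]))
  }
  structure(list(subject_id = subject_id, group = group, stage = stage,
                 posture = posture, sampling_rate = sampling_rate,
                 axes = axes, trial_bounds = trial_bounds),
            class = "tremor_recording")
}

#' @export
print.tremor_recording <- function(x, ...) {
  cat(sprintf("<tremor_recording> %s (%s/%s) %s: %d samples @ %g Hz, %d trial(s)\n",
              x$subject_id, x$group, x$stage, x$posture,
              nrow(x$axes), x$sampling_rate, nrow(x$trial_bounds)))
  invisible(x)
}

rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v > lower && v < upper) return(v)
  }
}

# AR(1) process with stationary sd `sd` and time constant `tau` seconds,
# generated at `fs_coarse` and linearly interpolated onto `t_full`.
ar1_wander <- function(sd, tau, duration_s, fs_coarse, t_full) {
  if (sd == 0) return(numeric(length(t_full)))
  n <- ceiling(duration_s * fs_coarse) + 1L
  rho <- exp(-1 / (tau * fs_coarse))
  innov_sd <- sd * sqrt(1 - rho^2)
  z <- numeric(n)
  z[1] <- stats::rnorm(1, 0, sd)
  e <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) z[i] <- rho * z[i - 1] + e[i - 1]
  stats::approx(x = (0:(n - 1)) / fs_coarse, y = z, xout = t_full)$y
}

# Amplitude gain of the full preprocessing chain (zero-phase notch
# cascade + zero-phase bandpass) at frequency f, at the acquisition rate.
pipeline_gain <- function(f, sampling_rate, fspec) {
  g <- rep(1, length(f))
  sq <- if (fspec$zero_phase) 2 else 1
  for (f0 in fspec$notch_harmonics[fspec$notch_harmonics < sampling_rate / 2]) {
    d <- iir_notch(f0, sampling_rate, fspec$notch_q)
    g <- g * Mod(filter_response(d$b, d$a, f, sampling_rate))^sq
  }
  d <- butter_bandpass(fspec$bandpass_low, fspec$bandpass_high,
                       sampling_rate, fspec$butter_order)
  g * Mod(filter_response(d$b, d$a, f, sampling_rate))^sq
}

# MAV of one cycle of the unit coupled-harmonic waveform after applying
# the per-harmonic pipeline gains; used to calibrate the tremor amplitude
# analytically rather than by iterative simulation.
unit_waveform_mav <- function(f0, harmonic_amplitudes, sampling_rate, fspec) {
  h <- seq_along(harmonic_amplitudes)
  gains <- pipeline_gain(h * f0, sampling_rate, fspec)
  theta <- 2 * pi * (0:4095) / 4096
  wave <- colSums(harmonic_amplitudes * gains *
                  cos(outer(h, theta)))
  mean(abs(wave))
}

#' Generate one synthetic subject recording
#'
#' Draws the subject's fundamental frequency and target log intensity
#' from the group model, synthesises the amplitude-modulated
#' phase-coupled harmonic stack plus drift, mains and sensor noise, and
#' distributes it over the three axes along a random fixed direction.
#' The tremor amplitude is calibrated analytically so the expected
#' post-pipeline ln(MAV) equals the subject's drawn target.
#'
#' @param model A [group_signal_model()].
#' @param posture `"P1"` (arm-stretching; five trials) or `"P2"`
#'   (arm-rested; one continuous trial).
#' @param duration_s Total recorded seconds (default 300).
#' @param sampling_rate Acquisition rate in Hz (default 1000).
#' @param seed Integer substream seed.
#' @param subject_id,group,stage Metadata carried on the recording.
#' @param fspec Downstream [filter_spec()] assumed by the calibration.
#' @return A `tremor_recording`.
#' @export
generate_subject <- function(model, posture = "P2", duration_s = 300,
                             sampling_rate = 1000, seed = 1,
                             subject_id = "S01", group = "PD", stage = "S1",
                             fspec = filter_spec()) {
  stopifnot(inherits(model, "group_signal_model"), duration_s > 0,
            posture %in% c("P1", "P2"))
  H <- length(model$harmonic_amplitudes)
  if (sampling_rate < 2 * H * 15)
    stop("sampling_rate below twice the highest modeled harmonic frequency")
  if (model$mains_amp > 0 && sampling_rate < 2 * 50)
    stop("sampling_rate below twice the mains frequency")
  fs <- sampling_rate
  n <- as.integer(round(duration_s * fs))
  t <- (0:(n - 1)) / fs
  with_seed(seed, {
    f0 <- rtruncnorm1(model$tremor_freq_mean, model$tremor_freq_sd, 1.5, 15)
    ln_target <- stats::rnorm(1, model$ln_mav_mean, model$ln_mav_sd)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    f_am <- stats::runif(1, 0.05, 0.2)
    psi_am <- stats::runif(1, 0, 2 * pi)
    phi0 <- stats::runif(1, 0, 2 * pi)
    jitter <- ar1_wander(model$freq_jitter_sd, model$freq_jitter_tau,
                         duration_s, 50, t)
    phase <- phi0 + 2 * pi * cumsum(f0 + jitter) / fs
    env <- 1 + model$amp_mod_depth * sin(2 * pi * f_am * t + psi_am)
    hh <- seq_len(H)
    s <- numeric(n)
    for (h in hh) s <- s + model$harmonic_amplitudes[h] * cos(h * phase)
    s <- env * s
    amp <- exp(ln_target) /
      unit_waveform_mav(f0, model$harmonic_amplitudes, fs, fspec)
    axes <- outer(amp * s, u)
    if (model$mains_amp > 0) {
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      psi_m <- stats::runif(1, 0, 2 * pi)
      axes <- axes + outer(model$mains_amp * sin(2 * pi * 50 * t + psi_m), v)
    }
    if (model$drift_amp > 0) {
      for (j in 1:3) {
        d <- ar1_wander(1, 2, duration_s, 2, t)
        axes[, j] <- axes[, j] + model$drift_amp * d
      }
    }
    if (model$noise_sd > 0) {
      axes <- axes + matrix(stats::rnorm(3 * n, 0, model$noise_sd), n, 3)
    }
    n_trials <- if (posture == "P1") 5L else 1L
    len <- n %/% n_trials
    tb <- cbind(start = (0:(n_trials - 1L)) * len + 1L,
                end = (1:n_trials) * len)
    new_tremor_recording(subject_id, group, stage, posture, fs, axes, tb)
  })
}

#' Generate a labelled synthetic cohort
#'
#' One recording per subject per posture, with per-subject independent
#' RNG substreams derived from the master seed.
#'
#' @param config A [cohort_config()].
#' @return A list with `recordings` (list of `tremor_recording`) and
#'   `labels` (one data.frame row per subject).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  plan <- cohort_plan(config)
  recordings <- vector("list", nrow(plan) * length(config$postures))
  k <- 0L
  for (i in seq_len(nrow(plan))) {
    for (posture in config$postures) {
      k <- k + 1L
      recordings[[k]] <- generate_cohort_recording(config, plan, i, posture)
    }
  }
  list(recordings = recordings,
       labels = plan[, c("subject_id", "group", "stage")])
}

# Subject roster for a cohort config: one row per subject.
cohort_plan <- function(config) {
  n <- config$n_per_subgroup
  defs <- data.frame(subgroup = c("PD1", "PD2", "ET1", "ET2"),
                     group = c("PD", "PD", "ET", "ET"),
                     stage = c("S1", "S2", "S1", "S2"),
                     stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(defs)), function(j) {
    cnt <- n[[defs$subgroup[j]]]
    if (cnt == 0) return(NULL)
    data.frame(subject_id = sprintf("%s-%02d", defs$subgroup[j], seq_len(cnt)),
               subgroup = defs$subgroup[j],
               within_index = seq_len(cnt),
               group = defs$group[j], stage = defs$stage[j],
               stringsAsFactors = FALSE)
  })
  plan <- do.call(rbind, rows)
  if (is.null(plan)) {
    plan <- data.frame(subject_id = character(0), subgroup = character(0),
                       within_index = integer(0), group = character(0),
                       stage = character(0), stringsAsFactors = FALSE)
  }
  plan
}

generate_cohort_recording <- function(config, plan, i, posture) {
  model <- config$models[[plan$group[i]]][[posture]]
  generate_subject(model, posture = posture,
                   duration_s = config$recording_duration,
                   sampling_rate = config$sampling_rate,
                   seed = derive_seed(config$seed, plan$subgroup[i],
                                      plan$within_index[i], posture),
                   subject_id = plan$subject_id[i],
                   group = plan$group[i], stage = plan$stage[i],
                   fspec = config$fspec)
}

#' Write recordings to a directory (CSV + JSON sidecar)
#'
#' Each recording is stored as `<subject>_<posture>.csv` with header
#' `time_s,ax,ay,az` plus a sidecar `<subject>_<posture>.json` carrying
#' the metadata (subject, group, stage, posture, sampling rate, trial
#' bounds, seed provenance).  A `labels.csv` ground-truth table is
#' written alongside.
#'
#' @param recordings List of `tremor_recording` objects.
#' @param dir Output directory (created if missing).
#' @param labels Optional ground-truth table to write as `labels.csv`.
#' @return `dir`, invisibly.
#' @export
write_recordings <- function(recordings, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in recordings) {
    stem <- file.path(dir, paste0(rec$subject_id, "_", rec$posture))
    n <- nrow(rec$axes)
    df <- data.frame(time_s = (0:(n - 1)) / rec$sampling_rate,
                     ax = rec$axes[, 1], ay = rec$axes[, 2],
                     az = rec$axes[, 3])
    utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
    meta <- list(subject_id = rec$subject_id, group = rec$group,
                 stage = rec$stage, posture = rec$posture,
                 sampling_rate_hz = rec$sampling_rate,
                 trial_bounds = unname(apply(rec$trial_bounds, 1, as.list)))
    jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  }
  if (!is.null(labels)) {
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  }
  invisible(dir)
}
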