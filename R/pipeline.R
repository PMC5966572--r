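#' Experiment configuration
#'
#' Bundles the cohort source, preprocessing spec, analysis plan and the
#' recording-length sweep into one deterministic, serialisable object.
#'
#' @param cohort Either a [cohort_config()] (synthetic source) or a
#'   directory path of recordings (see [read_recordings()]).
#' @param fspec A [filter_spec()].
#' @param segment_length_s Primary segment length, s (default 30).
#' @param sweep_lengths Segment lengths for the recording-length sweep,
#'   s.
#' @param features Feature columns to analyse.
#' @param postures,pairs Analysis plan; `pairs` is a list of group
#'   pairs.
#' @param welch_window_s,welch_overlap,max_lag Feature-extraction
#'   parameters (see [psd_welch()] and [bispectrum_diag()]).
#' @param positive Positive class for ROC analyses.
#' @param level Differentiation level for the discrimination
#'   coefficient.
#' @param seed Master seed (forwarded to a synthetic cohort source).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              fspec = filter_spec(),
                              segment_length_s = 30,
                              sweep_lengths = c(5, 10, 20, 30, 60, 150, 300),
                              features = c("ln_mav", "domfreq_psd",
                                           "domfreq_bispec"),
                              postures = c("P1", "P2"),
                              pairs = list(c("PD1", "ET1"),
                                           c("PD2", "ET2"),
                                           c("PD", "ET")),
                              welch_window_s = 10, welch_overlap = 0.5,
                              max_lag = 100,
                              positive = "ET", level = 0.7,
                              seed = NULL) {
  stopifnot(all(sweep_lengths > 0), segment_length_s > 0)
  if (!is.null(seed) && inherits(cohort, "cohort_config")) cohort$seed <- seed
  structure(list(cohort = cohort, fspec = fspec,
                 segment_length_s = segment_length_s,
                 sweep_lengths = sweep_lengths,
                 features = features, postures = postures, pairs = pairs,
                 welch_window_s = welch_window_s,
                 welch_overlap = welch_overlap, max_lag = max_lag,
                 positive = positive, level = level,
                 seed = if (inherits(cohort, "cohort_config")) cohort$seed else seed),
            class = "experiment_config")
}

# Iterate over the cohort source one recording at a time (keeps memory
# flat: raw 3-axis streams are dropped as soon as they are reduced to
# features).  `fun(recording)` is called per recording; results are
# collected in a list.
map_recordings <- function(config, fun, log_level = "info") {
  src <- config$cohort
  if (inherits(src, "cohort_config")) {
    plan <- cohort_plan(src)
    out <- list()
    k <- 0L
    for (i in seq_len(nrow(plan))) {
      for (posture in src$postures) {
        rec <- generate_cohort_recording(src, plan, i, posture)
        k <- k + 1L
        out[[k]] <- fun(rec)
      }
    }
    out
  } else if (is.character(src)) {
    recs <- read_recordings(src)
    lapply(recs, fun)
  } else if (is.list(src) && all(vapply(src, inherits, TRUE, "tremor_recording"))) {
    lapply(src, fun)
  } else {
    stop("invalid cohort source: expected cohort_config, directory or recording list")
  }
}

#' Compute the per-segment feature table for a whole cohort
#'
#' Streams over the cohort source, preprocesses each recording at the
#' given segment length and extracts the feature rows.
#'
#' @param config An [experiment_config()].
#' @param segment_length_s Segment length (defaults to the config's
#'   primary length).
#' @return A feature table (see [extract_features()]).
#' @export
cohort_features <- function(config, segment_length_s = config$segment_length_s) {
  tabs <- map_recordings(config, function(rec) {
    segs <- preprocess_pipeline(rec, segment_length_s, config$fspec)
    if (!length(segs)) return(NULL)
    extract_features(segs, welch_window_s = config$welch_window_s,
                     welch_overlap = config$welch_overlap,
                     max_lag = config$max_lag)
  })
  tabs <- Filter(Negate(is.null), tabs)
  if (!length(tabs)) return(NULL)
  do.call(rbind, tabs)
}

#' Run the full differentiation experiment
#'
#' Simulates (or ingests) the cohort, preprocesses at the primary
#' segment length, extracts features and runs every configured
#' (feature, posture, group-pair) analysis cell.  Deterministic given
#' the config and seed.  Cells whose analysis fails (e.g. an empty
#' selection) are marked failed with the reason rather than aborting the
#' run.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, the report JSON and
#'   the summary CSVs are written there.
#' @return Object of class `experiment_report`: the feature table, a
#'   `cells` list and a `summary` data.frame (one row per cell: group
#'   means/SDs, alpha, pass flag, AUC, cut-off, TPR/FPR/ACC).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  ft <- cohort_features(config)
  if (is.null(ft)) stop("cohort produced no segments")
  cells <- list()
  rows <- list()
  for (feat in config$features) {
    for (posture in config$postures) {
      for (pair in config$pairs) {
        key <- paste(feat, posture, paste(pair, collapse = "-"), sep = "|")
        res <- tryCatch(
          analyze_pair(ft, feat, pair, posture,
                       positive = config$positive, level = config$level),
          error = function(e) structure(list(failed = TRUE,
                                             reason = conditionMessage(e)),
                                        class = "failed_cell"))
        cells[[key]] <- res
        rows[[key]] <- cell_summary_row(res, feat, posture, pair)
      }
    }
  }
  report <- structure(list(config = config, feature_table = ft,
                           cells = cells,
                           summary = do.call(rbind, rows),
                           counts = list(
                             recordings = length(unique(paste(ft$subject_id, ft$posture))),
                             segments = nrow(ft),
                             cells = length(cells))),
                      class = "experiment_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

cell_summary_row <- function(res, feat, posture, pair) {
  if (inherits(res, "failed_cell")) {
    return(data.frame(feature = feat, posture = posture,
                      group_a = pair[1], group_b = pair[2],
                      mean_a = NA, sd_a = NA, mean_b = NA, sd_b = NA,
                      alpha = NA, passes_level = NA, auc = NA,
                      cutoff = NA, tpr = NA, fpr = NA, acc = NA,
                      failed = TRUE, reason = res$reason,
                      stringsAsFactors = FALSE))
  }
  d <- res$discrimination; r <- res$roc
  data.frame(feature = feat, posture = posture,
             group_a = pair[1], group_b = pair[2],
             mean_a = d$mean_a, sd_a = d$sd_a,
             mean_b = d$mean_b, sd_b = d$sd_b,
             alpha = d$alpha, passes_level = d$passes_level,
             auc = r$auc, cutoff = r$youden_cutoff_feature,
             tpr = r$tpr, fpr = r$fpr, acc = r$acc,
             failed = FALSE, reason = "",
             stringsAsFactors = FALSE)
}

#' Recording-length sweep
#'
#' Re-segments the cohort at each requested length, re-extracts the
#' dominant-frequency features and recomputes the PD-ET discrimination
#' coefficient per posture and spectrum estimate.  Lengths longer than a
#' posture's continuous trial duration yield no segments (segments never
#' span trial boundaries) and are marked unavailable.  The ROC analysis
#' at the longest available length per posture (bispectrum estimate) is
#' returned alongside.
#'
#' @param config An [experiment_config()].
#' @param lengths Segment lengths in seconds (defaults to the config's
#'   sweep).
#' @return List of class `length_sweep` with `alpha_table` (one row per
#'   length x posture x spectrum) and `roc_max_length` (per posture).
#' @export
length_sweep <- function(config, lengths = config$sweep_lengths) {
  stopifnot(inherits(config, "experiment_config"))
  # one streaming pass: per recording, features at every length
  per_rec <- map_recordings(config, function(rec) {
    lapply(lengths, function(L) {
      segs <- preprocess_pipeline(rec, L, config$fspec)
      if (!length(segs)) return(NULL)
      extract_features(segs, welch_window_s = config$welch_window_s,
                       welch_overlap = config$welch_overlap,
                       max_lag = config$max_lag)
    })
  })
  rows <- list()
  roc_max <- list()
  for (li in seq_along(lengths)) {
    tabs <- Filter(Negate(is.null), lapply(per_rec, `[[`, li))
    ft <- if (length(tabs)) do.call(rbind, tabs) else NULL
    for (posture in config$postures) {
      for (feat in c("domfreq_psd", "domfreq_bispec")) {
        key <- paste(lengths[li], posture, feat, sep = "|")
        ok <- !is.null(ft) && any(ft$posture == posture & ft$group == "PD") &&
          any(ft$posture == posture & ft$group == "ET")
        if (!ok) {
          rows[[key]] <- data.frame(length_s = lengths[li], posture = posture,
                                    feature = feat, alpha = NA_real_,
                                    n_instances = 0L, available = FALSE)
          next
        }
        res <- analyze_pair(ft, feat, c("PD", "ET"), posture,
                            positive = config$positive, level = config$level)
        rows[[key]] <- data.frame(length_s = lengths[li], posture = posture,
                                  feature = feat,
                                  alpha = res$discrimination$alpha,
                                  n_instances = res$roc$n_instances,
                                  available = TRUE)
        if (feat == "domfreq_bispec") roc_max[[posture]] <- list(
          length_s = lengths[li], roc = res$roc)
      }
    }
  }
  structure(list(alpha_table = do.call(rbind, rows),
                 roc_max_length = roc_max),
            class = "length_sweep")
}

#' Read recordings from a directory of CSV + JSON-sidecar files
#'
#' Expects the format written by [write_recordings()]: per recording a
#' CSV with header `time_s,ax,ay,az` and a sidecar JSON with the
#' metadata.  Per-file problems (missing sidecar, inconsistent sampling
#' rate, non-monotone time, short columns) are collected and reported
#' together.
#'
#' @param directory Path containing the files.
#' @return List of `tremor_recording` objects.
#' @export
read_recordings <- function(directory) {
  csvs <- sort(list.files(directory, pattern = "\\.csv$", full.names = TRUE))
  csvs <- csvs[basename(csvs) != "labels.csv"]
  if (!length(csvs)) stop("no recording CSV files in ", directory)
  errors <- character(0)
  recs <- list()
  for (path in csvs) {
    stem <- sub("\\.csv$", "", path)
    meta_path <- paste0(stem, ".json")
    rec <- tryCatch({
      if (!file.exists(meta_path)) stop("missing sidecar ", basename(meta_path))
      meta <- jsonlite::read_json(meta_path)
      df <- utils::read.csv(path,
                            colClasses = c("numeric", "numeric",
                                           "numeric", "numeric"))
      if (!identical(names(df), c("time_s", "ax", "ay", "az")))
        stop("unexpected columns: ", paste(names(df), collapse = ","))
      nas <- vapply(df, function(col) sum(is.na(col)), 0L)
      if (any(nas > 0))
        stop("missing values in column ", names(df)[which(nas > 0)[1]])
      dt <- diff(df$time_s)
      if (any(dt <= 0)) stop("non-monotone time column")
      fs_meta <- meta$sampling_rate_hz
      fs_obs <- 1 / stats::median(dt)
      if (abs(fs_obs - fs_meta) / fs_meta > 0.001)
        stop(sprintf("sampling-rate mismatch: sidecar %g Hz, time deltas imply %.4g Hz",
                     fs_meta, fs_obs))
      tb <- do.call(rbind, lapply(meta$trial_bounds,
                                  function(b) c(b[[1]], b[[2]])))
      new_tremor_recording(meta$subject_id, meta$group, meta$stage,
                           meta$posture, fs_meta,
                           as.matrix(df[, c("ax", "ay", "az")]), tb)
    }, error = function(e) {
      errors <<- c(errors, paste0(basename(path), ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  if (length(errors)) {
    stop("failed to read ", length(errors), " recording(s):\n  ",
         paste(errors, collapse = "\n  "))
  }
  recs
}

#' Write an experiment report to disk
#'
#' Emits `report.json` (config echo, per-cell results, counts), a
#' `summary.csv` mirroring the discrimination-coefficient tables (group
#' means, SDs, alpha, pass flag) and `features.csv`.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  write_feature_table(report$feature_table, file.path(dir, "features.csv"))
  cells <- lapply(report$cells, function(res) {
    if (inherits(res, "failed_cell")) return(list(failed = TRUE,
                                                  reason = res$reason))
    list(discrimination = unclass(res$discrimination),
         roc = res$roc[c("beta0", "beta1", "converged",
                         "separation_detected", "auc",
                         "youden_cutoff_feature", "youden_cutoff_prob",
                         "direction", "tpr", "fpr", "acc",
                         "positive_class", "n_instances")])
  })
  prov <- list(seed = report$config$seed,
               segment_length_s = report$config$segment_length_s,
               package_version = as.character(utils::packageVersion("tremordiff")))
  jsonlite::write_json(list(provenance = prov, counts = report$counts,
                            cells = cells),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d segments, %d analysis cells\n",
              x$counts$segments, x$counts$cells))
  print(x$summary[, c("feature", "posture", "group_a", "group_b",
                      "alpha", "passes_level", "auc", "tpr", "fpr", "acc")],
        digits = 3)
  invisible(x)
}
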