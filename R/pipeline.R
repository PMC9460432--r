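# End-to-end orchestration: preprocess -> labeling -> closure estimation
# -> wavelet features -> classification -> vote, with a reproducible
# manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with the published defaults: 1-40 Hz
#' band-pass, 1.8 s epochs, db5/5 wavelet, closure model 1.56 / -31.37,
#' Bi-GRU with [train_config()] defaults, 7 folds.
#'
#' @param band_low,band_high band-pass edges (Hz).
#' @param window_s epoch length (seconds).
#' @param section_s state-section length (seconds).
#' @param ecd an [ecd_model()].
#' @param model classifier name.
#' @param train a [train_config()].
#' @param n_folds cross-validation folds.
#' @param seed pipeline seed.
#' @export
pipeline_config <- function(band_low = 1, band_high = 40, window_s = 1.8,
                            section_s = 180, ecd = ecd_model(),
                            model = "bigru", train = train_config(),
                            n_folds = 7, seed = 1) {
  structure(list(band_low = band_low, band_high = band_high,
                 window_s = window_s, section_s = section_s, ecd = ecd,
                 model = model, train = train, n_folds = n_folds,
                 seed = seed),
            class = "pipeline_config")
}

#' Fused feature table for one subject
#'
#' Band-passes the recording, selects the alert/middle/fatigue sections
#' from the RT log (minimum / lower-median / maximum RT orders), computes
#' the per-epoch occipital closure estimate (normalized per subject over
#' all three sections), extracts the 19 wavelet features from each
#' frontal-channel epoch, and fuses everything into three channel rows
#' per sample.
#'
#' @param recording an [eeg_recording()] with FP1, FP2, FZ, O2.
#' @param rt_log the subject's RT log data frame.
#' @param config a [pipeline_config()].
#' @return fused feature table: `subject, sample_id, channel, ecd,
#'   A1..F3, label` — unstandardized (scaling is fit on training splits).
#' @export
build_subject_rows <- function(recording, rt_log, config = pipeline_config()) {
  check_required_channels(recording)
  rec_f <- bandpass(recording, config$band_low, config$band_high)
  spans <- select_state_sections(rec_f, rt_log, section_s = config$section_s)
  sections <- lapply(spans, function(sp) crop_recording(rec_f, sp["start"],
                                                        sp["end"]))
  # occipital closure estimate, normalized per subject across all sections
  raw_ecd <- lapply(sections, eecd_series, model = config$ecd,
                    window_s = config$window_s)
  norm_ecd <- normalize_eecd(unlist(raw_ecd))
  n_per <- lengths(raw_ecd)
  offsets <- c(0, cumsum(n_per))[1:3]
  subject <- recording$subject_id
  out <- vector("list", 3L)
  for (s in 1:3) {
    sec <- sections[[s]]
    frontal <- lapply(c(FP1 = "FP1", FP2 = "FP2", FZ = "FZ"), function(ch)
      lapply(segment_epochs(sec, ch, window_s = config$window_s),
             extract_features))
    n_epochs <- length(frontal$FP1)
    rows <- lapply(seq_len(n_epochs), function(i) {
      fuse(sample_id = sprintf("%s_st%d_e%03d", subject, s, i),
           ecd = norm_ecd[offsets[s] + i],
           channel_features = lapply(frontal, `[[`, i),
           label = s)
    })
    out[[s]] <- do.call(rbind, rows)
  }
  tab <- do.call(rbind, out)
  cbind(data.frame(subject = subject, stringsAsFactors = FALSE), tab)
}

#' Fused feature table for a cohort
#'
#' @param subjects list of `synth_subject` (or lists with `recording` and
#'   `rt_log`).
#' @param config a [pipeline_config()].
#' @return row-bound feature table over all subjects.
#' @export
build_cohort_rows <- function(subjects, config = pipeline_config()) {
  do.call(rbind, lapply(subjects, function(s)
    build_subject_rows(s$recording, s$rt_log, config)))
}

#' Should the operator be relieved? RT-based fatigue flag
#'
#' Flags a reaction time strictly above the threshold (default 2.2 s, the
#' mean of the fatigue-state RT interval); the recommendation attached to
#' the flag is to replace the shift in time.
#'
#' @param rt reaction time(s), seconds (> 0).
#' @param threshold flag threshold, seconds.
#' @return logical vector.
#' @export
report_fatigue_flag <- function(rt, threshold = 2.2) {
  stopifnot(all(rt > 0))
  rt > threshold
}

#' Run the full fatigue-classification pipeline
#'
#' Either on files (`eeg_paths` + `rt_paths`, one per subject) or on a
#' synthetic cohort (`synthetic = TRUE`). Executes preprocessing, state
#' labeling (pooled RT k-means), closure estimation, wavelet features,
#' subject-wise cross-validated classification and the three-channel
#' vote, and writes the feature table, the per-row prediction table, the
#' per-fold metrics, the confusion matrix and a run manifest to
#' `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param eeg_paths,rt_paths parallel file-path vectors (ignored when
#'   `synthetic`).
#' @param synthetic generate a cohort with [generate_cohort()] instead of
#'   reading files.
#' @param synth a [synth_config()] for the synthetic route.
#' @param out_dir output directory, created if needed (NULL: no files).
#' @param folds optional subset of cross-validation folds to run.
#' @return list: `rows`, `partition`, `cv` (see [cross_validate()]),
#'   `confusion`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), eeg_paths = NULL,
                         rt_paths = NULL, synthetic = FALSE,
                         synth = synth_config(seed = config$seed),
                         out_dir = NULL, folds = NULL) {
  if (synthetic) {
    cohort <- generate_cohort(synth)
    subjects <- cohort
  } else {
    if (is.null(eeg_paths) || is.null(rt_paths))
      stop("eeg_paths and rt_paths are required unless synthetic = TRUE")
    if (length(eeg_paths) != length(rt_paths))
      stop("eeg_paths and rt_paths must be parallel")
    missing_in <- c(eeg_paths, rt_paths)[!file.exists(c(eeg_paths, rt_paths))]
    if (length(missing_in))
      stop("input file(s) not found: ", paste(missing_in, collapse = ", "))
    subjects <- lapply(seq_along(eeg_paths), function(i) {
      list(recording = read_recording(eeg_paths[i]),
           rt_log = read_rt_log(rt_paths[i]))
    })
  }
  all_rts <- do.call(rbind, lapply(subjects, `[[`, "rt_log"))
  partition <- cluster_rts(all_rts, seed = config$seed)
  rows <- build_cohort_rows(subjects, config)
  cv <- cross_validate(rows, model = config$model, config = config$train,
                       plan = make_cv_plan(unique(rows$subject),
                                           n_folds = config$n_folds,
                                           seed = config$seed),
                       folds = folds)
  conf <- confusion_matrix(cv$predictions$real_label[!duplicated(cv$predictions$sample_id)],
                           cv$predictions$vote_label[!duplicated(cv$predictions$sample_id)])
  manifest <- list(
    seed = config$seed, model = config$model,
    band = c(config$band_low, config$band_high),
    window_s = config$window_s, section_s = config$section_s,
    ecd_model = unclass(config$ecd), train = unclass(config$train),
    n_folds = config$n_folds, n_subjects = length(subjects),
    synthetic = synthetic,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("fatigueEEG")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(rows, file.path(out_dir, "feature_table.csv"))
    utils::write.csv(cv$predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(cv$fold_metrics, file.path(out_dir, "fold_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame.matrix(conf$matrix),
                     file.path(out_dir, "confusion_matrix.csv"))
    utils::write.csv(data.frame(center = partition$centers),
                     file.path(out_dir, "rt_cluster_centers.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(rows = rows, partition = partition, cv = cv, confusion = conf,
       manifest = manifest)
}
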