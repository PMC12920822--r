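# End-to-end orchestration: preprocessed cohort -> rotated groups ->
# cropped/isotropically-resampled lesions -> long feature table.

#' Extract features for a whole rotated cohort
#'
#' For every rotation group and patient: crop to the mask bounding box with
#' the configured margin, resample to the isometric target spacing (modal
#' spacing of the cohort by default), apply the filter bank and extract the
#' 93 + 14 features. Returns the long-format interchange table used by the
#' stability and modeling modules.
#'
#' @param rotated named list `R<label>` -> list of [volume_pair()] (from
#'   [build_rotated_cohort()]).
#' @param pre_cfg a [preprocess_config()].
#' @param filter_cfg a [filter_config()].
#' @param target_spacing optional explicit isometric spacing; defaults to
#'   the modal spacing of the R0 group.
#' @param verbose print per-group progress.
#' @return `data.table` with columns patient_id, rotation, channel,
#'   category, feature, value, is_wd.
#' @export
extract_cohort_features <- function(rotated,
                                    pre_cfg = preprocess_config(),
                                    filter_cfg = filter_config(),
                                    target_spacing = NULL,
                                    verbose = FALSE) {
  if (is.null(target_spacing)) {
    target_spacing <- if (identical(pre_cfg$resample_spacing_policy, "explicit") &&
                          !is.null(pre_cfg$explicit_spacing)) {
      pre_cfg$explicit_spacing
    } else {
      modal_spacing(rotated[["R0"]])
    }
  }
  out <- list()
  for (key in names(rotated)) {
    lab <- as.integer(sub("^R", "", key))
    if (verbose) message("extracting ", key, " (", length(rotated[[key]]),
                         " patients)")
    for (pair in rotated[[key]]) {
      cropped <- crop_to_bbox(pair, pre_cfg$crop_margin)
      iso <- resample_isotropic(cropped, target_spacing)
      fv <- extract_all(iso, bin_width = pre_cfg$bin_width,
                        filter_cfg = filter_cfg)
      fv$rotation <- lab
      out[[length(out) + 1L]] <- fv
    }
  }
  data.table::rbindlist(out)
}

#' Run the full rotation-robustness study on a synthetic cohort
#'
#' Convenience wrapper: simulate, preprocess, rotate, extract, then feature
#' stability and (optionally) the repeated-CV protocol.
#'
#' @param n_patients cohort size.
#' @param seed global seed (fans out to per-stage streams).
#' @param labels rotation labels.
#' @param pre_cfg,filter_cfg,model_cfg module configurations.
#' @param run_model run the repeated-CV protocol as well.
#' @param verbose progress messages.
#' @return list with `features` (long table), `stability` records,
#'   `subgroups`, and if requested `cv_records` and `trend`.
#' @export
run_study <- function(n_patients = 30L, seed = 1L,
                      labels = c(0L, seq(5L, 80L, 5L)),
                      pre_cfg = preprocess_config(),
                      filter_cfg = filter_config(),
                      model_cfg = pipeline_config(seed = seed),
                      run_model = FALSE, verbose = FALSE) {
  cohort <- make_cohort(n_patients, seed = derive_seed(seed, "cohort"))
  cohort <- lapply(cohort, preprocess_pair, config = pre_cfg)
  rotated <- build_rotated_cohort(cohort, seed = derive_seed(seed, "rotation"),
                                  labels = labels)
  feats <- extract_cohort_features(rotated, pre_cfg, filter_cfg,
                                   verbose = verbose)
  recs <- feature_stability(feats)
  res <- list(features = feats, stability = recs,
              subgroups = aggregate_subgroups(recs),
              manifest = attr(rotated, "manifest"))
  if (run_model) {
    y <- stats::setNames(vapply(cohort, function(p) p$class_label, 1L),
                         vapply(cohort, function(p) p$patient_id, ""))
    res$cv_records <- run_repeated_cv(feats, y, model_cfg)
    res$trend <- performance_trend(res$cv_records)
  }
  res
}
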