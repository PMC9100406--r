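# End-to-end glue: cohort -> feature table -> prune -> rank -> incremental
# top-k search -> evaluation report.

#' Extract the per-cycle feature table from a cohort
#'
#' Runs [preprocess_recording()] on every recording and computes the
#' per-channel feature vectors on each accepted stance segment: the
#' 19-feature time-domain bank for EMG channels, the 195-feature
#' TD/FD/TFD bank for GRF components. One row per accepted segment, with
#' `subject_id`, `label`, `cycle` provenance columns.
#'
#' @param cohort A `gait_cohort` from [generate_cohort()] or [read_cohort()].
#' @param channels Channels to extract features for.
#' @param grf_sets GRF feature families to compute (subset of
#'   `c("td", "fd", "tfd")`).
#' @param wavelet Wavelet for the TFD bank.
#' @param ... Passed to [preprocess_recording()].
#' @return Data frame: metadata columns plus channel-qualified feature
#'   columns (19 per EMG channel, 195 per GRF component with all sets).
#' @export
extract_features <- function(cohort, channels = gait_channels(),
                             grf_sets = c("td", "fd", "tfd"),
                             wavelet = "db4", ...) {
  stopifnot(inherits(cohort, "gait_cohort"))
  rows <- lapply(cohort, function(rec) {
    pp <- preprocess_recording(rec, channels = unique(c(channels, "GRFz")), ...)
    if (!length(pp$segments)) return(NULL)
    do.call(rbind, lapply(pp$segments, function(seg) {
      feats <- unlist(lapply(channels, function(ch) {
        if (is_emg_channel(ch)) {
          emg_feature_vector(seg[[ch]], ch)
        } else {
          grf_feature_vector(seg[[ch]], rec$fs, ch, wavelet, grf_sets)
        }
      }))
      cbind(data.frame(subject_id = rec$subject_id, label = rec$label,
                       cycle = rec$cycle),
            as.data.frame(t(feats)))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full selection + classification pipeline on a feature table
#'
#' Correlation pruning, feature ranking, and the incremental top-k forward
#' search under subject-wise (or supplied) cross-validation with per-fold
#' SMOTE and the distance-weighted KNN. By default features are pruned
#' *before* ranking so collinear duplicates cannot distort the ranking;
#' `prune_first = FALSE` reverses the order (rank on the full table, then
#' prune the ranked list).
#'
#' @param table Feature table from [extract_features()].
#' @param ranker One of `"chi2"`, `"mrmr"`, `"relieff"`, `"nca"`.
#' @param folds Fold assignment; defaults to [subject_wise_folds()] on the
#'   table's subjects with `seed`.
#' @param config A [knn_config()].
#' @param prune_threshold Correlation threshold for [drop_correlated()].
#' @param prune_first Prune before ranking (default) or after.
#' @param max_k Cap on the incremental search depth.
#' @param smote Balance training folds with SMOTE.
#' @param seed Seed for folds and SMOTE.
#' @return List with `report` (best `eval_report`), `best_k`, `trace`,
#'   `ranking`, `dropped`, and `folds`.
#' @export
run_pipeline <- function(table, ranker = "chi2", folds = NULL,
                         config = knn_config(), prune_threshold = 0.9,
                         prune_first = TRUE, max_k = NULL, smote = TRUE,
                         seed = 1L) {
  if (is.null(folds)) {
    subj <- tapply(as.character(table$label),
                   as.character(table$subject_id), `[`, 1)
    folds <- subject_wise_folds(as.list(subj), seed = seed)
  }
  if (prune_first) {
    pruned <- drop_correlated(table, prune_threshold)
    work <- pruned$table
    ranked <- rank_features(work, work$label, ranker)
  } else {
    ranked_full <- rank_features(table, table$label, ranker)
    pruned <- drop_correlated(table, prune_threshold)
    keep <- ranked_full$names %in% names(pruned$table)
    ranked <- ranked_features(ranked_full$method, ranked_full$names[keep],
                              ranked_full$scores[keep])
    work <- pruned$table
  }
  search <- incremental_feature_search(ranked, work, folds, config,
                                       max_k = max_k, smote = smote,
                                       seed = seed)
  list(report = search$best_report, best_k = search$best_k,
       trace = search$trace, ranking = ranked, dropped = pruned$dropped,
       folds = folds)
}
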