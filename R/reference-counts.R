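#' Published per-fold confusion counts of the original five-fold study
#'
#' The per-fold true/false positive/negative counts reported for the
#' two-detector hand-joint ensemble on its clinical five-fold
#' cross-validation: one block for the subluxation/dislocation task and one
#' for the ankylosis task. The positive totals (`tp + fn`) are 60
#' subluxation/dislocation joints and 157 ankylosis joints. These counts
#' serve as reference input for validating the metric arithmetic
#' ([metrics()] and [average_folds()]) against the study's printed averages.
#'
#' @return A tibble with columns `task`, `fold`, `tp`, `fp`, `tn`, `fn`.
#' @export
reference_fold_counts <- function() {
  dplyr::bind_rows(
    tibble::tibble(task = "subluxation", fold = 1:5,
                   tp = c(6, 9, 17, 8, 8),
                   fp = c(2, 2, 3, 5, 0),
                   tn = c(887, 889, 880, 882, 889),
                   fn = c(5, 1, 0, 3, 3)),
    tibble::tibble(task = "ankylosis", fold = 1:5,
                   tp = c(24, 24, 28, 27, 24),
                   fp = c(1, 0, 1, 1, 0),
                   tn = c(965, 967, 969, 969, 969),
                   fn = c(8, 8, 3, 4, 7)))
}
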