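#' Fuse two detections of the same joint
#'
#' Both members must overlap with IoU at or above the merge threshold. The
#' fused detection keeps the geometry and confidence of the higher-confidence
#' member (ties favour the ankylosis detector), and carries both detectors'
#' class probabilities as the two finding labels.
#'
#' @param a Ankylosis-detector detection (one-row tibble).
#' @param b Subluxation-detector detection (one-row tibble).
#' @param t_iou2 Merge threshold; the pair's IoU must be `>=` it.
#' @return A one-row fused-detection tibble (see [ensemble()]).
#' @export
fuse_pair <- function(a, b, t_iou2 = 0.45) {
  if (box_iou(a, b)[1, 1] < t_iou2) {
    stop("fuse_pair() requires IoU >= t_iou2", call. = FALSE)
  }
  keep <- if (b$confidence > a$confidence) b else a
  tibble::tibble(
    cx = keep$cx, cy = keep$cy, w = keep$w, h = keep$h,
    confidence = max(a$confidence, b$confidence),
    ank_present = a$p_present, ank_absent = a$p_absent,
    sub_present = b$p_present, sub_absent = b$p_absent,
    sources = "ankylosis+subluxation")
}

c_neg <- c(present = 0, absent = 1)

#' Ensemble merge of the two task detectors' outputs
#'
#' Cross-detector box fusion: detections from the ankylosis detector (`b1`)
#' and subluxation detector (`b2`) that overlap with IoU `>= t_iou2` are
#' assumed to mark the same finger joint and merge into one fused detection
#' carrying both finding labels. Matching is greedy in descending combined
#' confidence and one-to-one. Unmatched detections pass through with the
#' negative-class placeholder (finding-absent probability 1) for the task
#' whose detector did not propose them. If `m1 + 1` or more candidates
#' remain, the `m1` highest-confidence ones are kept.
#'
#' @param b1 Ankylosis-detector detections (at most `m1` rows).
#' @param b2 Subluxation-detector detections.
#' @param t_iou2 Cross-detector merge threshold (default 0.45).
#' @param m1 Final cap on fused detections (default 20).
#' @return A fused-detection tibble: box columns, fused `confidence`,
#'   `ank_present`/`ank_absent` and `sub_present`/`sub_absent` label
#'   probabilities, and `sources`; sorted by descending confidence.
#' @export
ensemble <- function(b1, b2, t_iou2 = 0.45, m1 = 20L) {
  empty <- tibble::tibble(
    cx = numeric(), cy = numeric(), w = numeric(), h = numeric(),
    confidence = numeric(), ank_present = numeric(), ank_absent = numeric(),
    sub_present = numeric(), sub_absent = numeric(), sources = character())
  n1 <- if (is.null(b1)) 0L else nrow(b1)
  n2 <- if (is.null(b2)) 0L else nrow(b2)
  fused <- empty
  used1 <- logical(n1); used2 <- logical(n2)
  if (n1 > 0 && n2 > 0) {
    iou <- box_iou(b1, b2)
    cand <- which(iou >= t_iou2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      comb <- b1$confidence[cand[, 1]] + b2$confidence[cand[, 2]]
      cand <- cand[order(-comb, cand[, 1], cand[, 2]), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used1[i] || used2[j]) next
        used1[i] <- TRUE; used2[j] <- TRUE
        fused <- dplyr::bind_rows(fused, fuse_pair(b1[i, ], b2[j, ], t_iou2))
      }
    }
  }
  lone1 <- if (n1 > 0) {
    tibble::tibble(
      cx = b1$cx, cy = b1$cy, w = b1$w, h = b1$h,
      confidence = b1$confidence,
      ank_present = b1$p_present, ank_absent = b1$p_absent,
      sub_present = c_neg[["present"]], sub_absent = c_neg[["absent"]],
      sources = "ankylosis")[!used1, ]
  } else empty
  lone2 <- if (n2 > 0) {
    tibble::tibble(
      cx = b2$cx, cy = b2$cy, w = b2$w, h = b2$h,
      confidence = b2$confidence,
      ank_present = c_neg[["present"]], ank_absent = c_neg[["absent"]],
      sub_present = b2$p_present, sub_absent = b2$p_absent,
      sources = "subluxation")[!used2, ]
  } else empty
  out <- dplyr::bind_rows(fused, lone1, lone2)
  out <- out[order(-out$confidence), , drop = FALSE]
  # final cut applies only when at least m1 + 1 candidates remain
  if (nrow(out) >= m1 + 1) out <- out[seq_len(m1), , drop = FALSE]
  out
}

#' Run the full two-detector ensemble pipeline on one image
#'
#' @param image A `hand_phantom` or grayscale matrix.
#' @param det_ank,det_sub The ankylosis and subluxation detectors
#'   (`joint_detector` or `oracle_spec`).
#' @param params Pipeline parameters, see [run_config()].
#' @param plan Optional shared `window_plan`.
#' @return A fused-detection tibble (see [ensemble()]).
#' @export
predict_ensemble <- function(image, det_ank, det_sub, params = run_config(),
                             plan = NULL) {
  b1 <- predict_single(image, det_ank, params, plan)
  b2 <- predict_single(image, det_sub, params, plan)
  ensemble(b1, b2, params$t_iou2, params$m1)
}
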