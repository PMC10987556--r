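#' Match predicted boxes to ground-truth joints
#'
#' Greedy one-to-one matching by descending IoU: the globally best
#' prediction/ground-truth pair is matched first, both are removed, and the
#' process repeats. A ground-truth joint counts as detected when its matched
#' IoU is strictly above `iou_success` (default 0.45).
#'
#' @param preds Prediction tibble (boxes; fused detections work as-is).
#' @param gts Ground-truth box tibble (e.g. the `joints` of a phantom).
#' @param iou_success Detection success threshold (strict `>`).
#' @return A tibble with one row per ground-truth joint: `gt`, `pred`
#'   (matched prediction row or NA), `iou`, `detected`.
#' @export
match_to_ground_truth <- function(preds, gts, iou_success = 0.45) {
  ng <- nrow(gts); np <- nrow(preds)
  out <- tibble::tibble(gt = seq_len(ng), pred = NA_integer_, iou = 0)
  if (np > 0 && ng > 0) {
    iou <- box_iou(preds, gts)
    repeat {
      best <- which.max(iou)
      if (length(best) == 0 || iou[best] <= 0) break
      i <- (best - 1) %% np + 1
      j <- (best - 1) %/% np + 1
      out$pred[j] <- i
      out$iou[j] <- iou[i, j]
      iou[i, ] <- -1
      iou[, j] <- -1
      if (all(iou < 0)) break
    }
  }
  dplyr::mutate(out, detected = .data$iou > iou_success)
}

#' Joint-region detection rate over a set of images
#'
#' @param assignments A list of (or single) match tibbles from
#'   [match_to_ground_truth()], one per image.
#' @return Percentage of annotated joints detected, `100 * detected / total`.
#' @export
detection_rate <- function(assignments) {
  if (is.data.frame(assignments)) assignments <- list(assignments)
  all <- dplyr::bind_rows(assignments)
  if (nrow(all) == 0) stop("no annotated joints in assignment", call. = FALSE)
  100 * mean(all$detected)
}

#' Confusion counts for one finding task over detected joints
#'
#' Standard 2x2 counts of predicted versus annotated binary finding labels.
#' Only joints that were successfully detected enter the counts; undetected
#' ground-truth joints are excluded entirely (detection and classification
#' performance are reported separately, so a missed joint is a detection
#' failure, not a classification false negative).
#'
#' @param assignment Match tibble from [match_to_ground_truth()].
#' @param pred_labels Logical vector per prediction row (finding present).
#' @param gt_labels Logical vector per ground-truth row; `NA` rows (joints
#'   without an annotation slot for this task) are skipped.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(assignment, pred_labels, gt_labels) {
  det <- assignment[assignment$detected & !is.na(gt_labels[assignment$gt]), ,
                    drop = FALSE]
  p <- pred_labels[det$pred]
  g <- gt_labels[det$gt]
  tibble::tibble(tp = sum(p & g), fp = sum(p & !g),
                 tn = sum(!p & !g), fn = sum(!p & g))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, specificity and F-value from 2x2 counts.
#' Ratios with zero denominator (0/0) are reported as `NA` and excluded
#' from fold averages.
#'
#' @param counts A data frame with columns `tp`, `fp`, `tn`, `fn` (one row
#'   per fold; vectorised).
#' @return The input with metric columns appended: `accuracy`, `precision`,
#'   `recall`, `specificity`, `f_value`.
#' @export
metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tot <- counts$tp + counts$fp + counts$tn + counts$fn
  if (any(tot == 0)) stop("all-zero confusion counts", call. = FALSE)
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(tibble::as_tibble(counts),
    accuracy = (.data$tp + .data$tn) / tot,
    precision = safe(.data$tp, .data$tp + .data$fp),
    recall = safe(.data$tp, .data$tp + .data$fn),
    specificity = safe(.data$tn, .data$tn + .data$fp),
    f_value = safe(2 * .data$precision * .data$recall,
                   .data$precision + .data$recall))
}

#' Average per-fold metrics
#'
#' Unweighted arithmetic mean of each metric across folds, with undefined
#' (NA) fold values excluded, rounded half-up to `digits` decimals to match
#' the reporting convention.
#'
#' @param fold_metrics Tibble from [metrics()], one row per fold.
#' @param digits Decimals for half-up rounding; `NULL` for no rounding.
#' @return A one-row tibble of averaged metrics.
#' @export
average_folds <- function(fold_metrics,
                          digits = 2) {
  if (nrow(fold_metrics) == 0) stop("no folds to average", call. = FALSE)
  cols <- intersect(c("accuracy", "precision", "recall", "specificity",
                      "f_value", "mean_iou"), names(fold_metrics))
  out <- dplyr::summarise(fold_metrics, dplyr::across(
    dplyr::all_of(cols), ~ mean(.x, na.rm = TRUE)))
  if (!is.null(digits)) out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(), ~ round_half_up(.x, digits)))
  out
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Evaluate the ensemble pipeline on a set of annotated images
#'
#' Runs detection-rate and per-task confusion/metric computation for fused
#' predictions against phantom ground truth. Predicted finding labels are
#' positive when the task's present-probability exceeds its
#' absent-probability.
#'
#' @param preds_list List of fused-detection tibbles, one per image.
#' @param images List of annotated images (`hand_phantom`).
#' @param iou_success Detection success threshold.
#' @return A list with `detection_rate`, `mean_iou` (over detected joints),
#'   `counts` (per-task confusion tibble), and `assignments`.
#' @export
evaluate_predictions <- function(preds_list, images, iou_success = 0.45) {
  stopifnot(length(preds_list) == length(images))
  assigns <- purrr::map2(preds_list, images,
                         ~ match_to_ground_truth(.x, .y$joints, iou_success))
  counts <- purrr::map_dfr(c("ankylosis", "subluxation"), function(task) {
    per_img <- purrr::pmap_dfr(list(preds_list, images, assigns),
      function(pr, im, as) {
        gt_lab <- if (task == "ankylosis") im$joints$ankylosis else
          im$joints$subluxation
        pred_lab <- if (task == "ankylosis") {
          pr$ank_present > pr$ank_absent
        } else pr$sub_present > pr$sub_absent
        confusion(as, pred_lab, gt_lab)
      })
    dplyr::summarise(per_img, task = task, dplyr::across(
      c("tp", "fp", "tn", "fn"), sum))
  })
  det_iou <- dplyr::bind_rows(assigns)
  list(detection_rate = detection_rate(assigns),
       mean_iou = mean(det_iou$iou[det_iou$detected]),
       counts = counts[, c("task", "tp", "fp", "tn", "fn")],
       assignments = assigns)
}

#' Stratified five-fold split keeping patient pairs together
#'
#' Partitions a two-timepoint dataset into `k` folds at the patient level
#' (both images of a patient land in the same fold) while spreading
#' finding-positive patients as evenly as integer counts allow. Each fold's
#' test set is trimmed to `test_size` images by moving deterministically
#' chosen finding-negative patients of that fold into its training set, so
#' a 260-image dataset yields the 210-train / 50-test splits of the study
#' protocol.
#'
#' @param dataset A `phantom_dataset` (or list of annotated images with
#'   `patient_id`).
#' @param k Number of folds.
#' @param test_size Test images per fold (`NULL` keeps whole folds).
#' @param seed Integer seed; the split is deterministic given it.
#' @return A tibble with `fold`, `test` (list of image ids), `train`
#'   (list of image ids).
#' @export
stratified_five_fold <- function(dataset, k = 5L, test_size = 50L, seed = 1L) {
  joints <- dataset_joints(dataset)
  imgs <- dataset_images(dataset)
  if (length(imgs) < k) stop("fewer images than folds", call. = FALSE)
  pat <- joints |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(positive = any(.data$ankylosis, na.rm = TRUE) |
                       any(.data$subluxation, na.rm = TRUE))
  img_ids <- tibble::tibble(
    image_id = seq_along(imgs),
    patient_id = vapply(imgs, function(x) as.integer(x$patient_id), 1L))
  folds <- local_seed(seed, {
    assign_group <- function(ids) {
      ids <- sample(ids)
      split(ids, rep_len(seq_len(k), length(ids)))
    }
    pos <- assign_group(pat$patient_id[pat$positive])
    neg <- assign_group(pat$patient_id[!pat$positive])
    purrr::map(seq_len(k), ~ sort(c(pos[[.x]], neg[[.x]])))
  })
  purrr::imap_dfr(folds, function(pids, f) {
    test_imgs <- sort(img_ids$image_id[img_ids$patient_id %in% pids])
    if (!is.null(test_size) && length(test_imgs) > test_size) {
      # demote finding-negative patients (lowest ids first) until it fits
      negs <- sort(intersect(pids, pat$patient_id[!pat$positive]))
      for (pd in negs) {
        if (length(test_imgs) <= test_size) break
        test_imgs <- setdiff(test_imgs,
                             img_ids$image_id[img_ids$patient_id == pd])
      }
      test_imgs <- sort(test_imgs)
    }
    tibble::tibble(fold = f,
                   test = list(test_imgs),
                   train = list(setdiff(img_ids$image_id, test_imgs)))
  })
}
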