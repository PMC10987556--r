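test_that("ground-truth matching handles perfect, shifted and oracle cases", {
  gts <- boxes(cx = c(20, 50, 80), cy = 30, w = 10, h = 10)
  m <- match_to_ground_truth(gts, gts)
  expect_true(all(m$detected))
  expect_equal(m$iou, rep(1, 3))
  expect_equal(detection_rate(m), 100)
  # every IoU around 0.3: nothing detected
  shifted <- dplyr::mutate(gts, cx = cx + 5.2)
  m2 <- match_to_ground_truth(shifted, gts)
  expect_true(all(m2$iou < 0.45) && all(!m2$detected))
  expect_equal(detection_rate(m2), 0)
  # random instances equal the exhaustive greedy oracle
  set.seed(19)
  for (rep in 1:60) {
    np <- sample(1:6, 1); ng <- sample(1:6, 1)
    preds <- random_boxes(np, 60)
    gt <- random_boxes(ng, 60)
    got <- match_to_ground_truth(preds, gt)
    want <- match_oracle(preds, gt, 0.45)
    expect_equal(got$pred, want$pred)
    expect_equal(got$iou, want$iou)
    expect_equal(got$detected, want$detected)
  }
})

test_that("confusion counts detected joints only and matches enumeration", {
  gts <- boxes(cx = seq(10, 100, by = 10), cy = 20, w = 8, h = 8)
  asg <- match_to_ground_truth(gts, gts)
  gt_lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  pred_lab <- gt_lab
  pred_lab[c(2, 5)] <- !pred_lab[c(2, 5)]  # one flip each way
  cc <- confusion(asg, pred_lab, gt_lab)
  # 3 positives; flipping gt-positive joint 2 and gt-negative joint 5 gives
  # tp {1,6}, fn {2}, fp {5}, tn the remaining 6
  expect_equal(as.data.frame(cc), data.frame(tp = 2, fp = 1, tn = 6, fn = 1))
  # all-correct positives and the all-negative fold
  expect_equal(confusion(asg, gt_lab, gt_lab)$fn, 0)
  expect_equal(confusion(asg, gt_lab, gt_lab)$fp, 0)
  neg <- rep(FALSE, 10)
  expect_equal(as.data.frame(confusion(asg, neg, neg)),
               data.frame(tp = 0, fp = 0, tn = 10, fn = 0))
  # NA-labelled joints (no annotation slot) are excluded
  gt_na <- gt_lab; gt_na[1] <- NA
  expect_equal(sum(unlist(confusion(asg, pred_lab, gt_na))), 9)
  # undetected joints never enter the counts
  asg2 <- asg; asg2$detected[1:3] <- FALSE
  expect_equal(sum(unlist(confusion(asg2, pred_lab, gt_lab))), 7)
})

test_that("metric formulas reproduce the published fold examples", {
  m5 <- metrics(data.frame(tp = 8, fp = 0, tn = 889, fn = 3))
  expect_equal(m5$precision, 1)
  expect_equal(m5$recall, 8 / 11)
  m1 <- metrics(data.frame(tp = 24, fp = 1, tn = 965, fn = 8))
  expect_equal(m1$precision, 24 / 25)
  perfect <- metrics(data.frame(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_equal(unlist(perfect[, c("accuracy", "precision", "recall",
                                  "specificity", "f_value")]),
               c(accuracy = 1, precision = 1, recall = 1, specificity = 1,
                 f_value = 1))
  # 0/0 ratios are undefined, not zero
  nopos <- metrics(data.frame(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(nopos$precision) && is.na(nopos$recall))
  expect_error(metrics(data.frame(tp = 0, fp = 0, tn = 0, fn = 0)),
               "all-zero")
  # F-value identity 2PR/(P+R)
  set.seed(2)
  cc <- data.frame(tp = sample(1:30, 10, TRUE), fp = sample(0:10, 10, TRUE),
                   tn = sample(100:900, 10, TRUE), fn = sample(0:10, 10, TRUE))
  mm <- metrics(cc)
  expect_equal(mm$f_value, 2 * mm$precision * mm$recall /
                 (mm$precision + mm$recall))
})

test_that("fold averaging reproduces the published study averages", {
  rc <- reference_fold_counts()
  sub <- average_folds(metrics(rc[rc$task == "subluxation", ]))
  expect_equal(sub$precision, 0.81)
  expect_equal(sub$recall, 0.78)
  expect_equal(sub$f_value, 0.78)
  ank <- average_folds(metrics(rc[rc$task == "ankylosis", ]))
  expect_equal(ank$precision, 0.98)
  expect_equal(ank$recall, 0.81)
  expect_equal(ank$f_value, 0.88)
  # positives totals across folds
  expect_equal(sum(rc$tp[rc$task == "subluxation"]) +
                 sum(rc$fn[rc$task == "subluxation"]), 60)
  expect_equal(sum(rc$tp[rc$task == "ankylosis"]) +
                 sum(rc$fn[rc$task == "ankylosis"]), 157)
  # identical folds average to any fold; empty input errors
  one <- metrics(rc[rc$task == "ankylosis", ][c(1, 1), ])
  avg <- average_folds(one, digits = NULL)
  expect_equal(avg$precision, one$precision[1])
  expect_error(average_folds(one[0, ]), "no folds")
})

test_that("metrics of constructed folds equal a one-pass enumeration oracle", {
  set.seed(23)
  for (rep in 1:20) {
    n <- 30
    gt <- runif(n) < 0.3
    pred <- ifelse(runif(n) < 0.8, gt, !gt)
    cc <- data.frame(tp = sum(pred & gt), fp = sum(pred & !gt),
                     tn = sum(!pred & !gt), fn = sum(!pred & gt))
    m <- metrics(cc)
    expect_equal(m$accuracy, mean(pred == gt))
    if (any(pred)) expect_equal(m$precision, mean(gt[pred]))
    if (any(gt)) expect_equal(m$recall, mean(pred[gt]))
  }
})

test_that("the stratified split keeps patients together and balances positives", {
  pp <- tiny_params(prev_ankylosis = 0.01, prev_subluxation = 0.005)
  ds <- generate_dataset(40L, pp, seed = 77, render = FALSE)
  split <- stratified_five_fold(ds, k = 5, test_size = 6, seed = 3)
  expect_equal(nrow(split), 5)
  expect_true(all(lengths(split$test) == 6))
  expect_true(all(lengths(split$train) == 34))
  jt <- dataset_joints(ds)
  pat_of <- function(ids) unique(jt$patient_id[jt$image_id %in% ids])
  for (f in 1:5) {
    # no patient straddles train and test
    expect_length(intersect(pat_of(split$test[[f]]), pat_of(split$train[[f]])),
                  0)
    # test plus train covers all images
    expect_equal(sort(c(split$test[[f]], split$train[[f]])), 1:40)
  }
  # deterministic given the seed
  split2 <- stratified_five_fold(ds, k = 5, test_size = 6, seed = 3)
  expect_identical(split, split2)
  # positives spread as evenly as integer counts allow
  pos_pat <- unique(jt$patient_id[jt$ankylosis |
                                    (!is.na(jt$subluxation) & jt$subluxation)])
  per_fold <- vapply(split$test, function(ids) {
    length(intersect(pat_of(ids), pos_pat))
  }, 1L)
  expect_lte(max(per_fold) - min(per_fold), 1 + sum(per_fold) %% 5)
  expect_error(stratified_five_fold(generate_dataset(4L, pp, seed = 1,
                                                     render = FALSE)),
               "fewer images")
})
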