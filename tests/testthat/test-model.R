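toy_grid <- function() {
  default_box_grid(list(window = 100, maps = list(
    list(size = 2, scale = 40, aspects = NULL))))
}

test_that("matching forces a best default for every ground truth", {
  grid <- toy_grid()
  gt <- grid[2, c("cx", "cy", "w", "h")]
  gt$positive <- TRUE
  m <- match_defaults(gt, grid)
  expect_equal(m$gt_index[2], 1L)
  expect_gte(m$n_matched, 1)
  expect_equal(m$class[2], 1L)
  # empty ground truth: everything negative
  m0 <- match_defaults(gt[0, ], grid)
  expect_equal(m0$n_matched, 0)
  expect_equal(m0$neg, 1:4)
})

test_that("matching equals an exhaustive argmax oracle on a toy grid", {
  set.seed(21)
  grid <- toy_grid()
  for (rep in 1:20) {
    gt <- boxes(cx = runif(2, 20, 80), cy = runif(2, 20, 80),
                w = runif(2, 20, 50), h = runif(2, 20, 50))
    m <- match_defaults(gt, grid, match_iou = 0.5)
    iou <- box_iou(grid, gt)
    expected <- rep(NA_integer_, 4)
    for (i in 1:4) {
      j <- which.max(iou[i, ])
      if (iou[i, j] >= 0.5) expected[i] <- j
    }
    for (j in 1:2) expected[which.max(iou[, j])] <- j
    expect_equal(m$gt_index, expected)
  }
})

test_that("smooth L1 matches its closed form and is continuous at 1", {
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(0.5), 0.125)
  expect_equal(smooth_l1(2), 1.5)
  expect_equal(smooth_l1(-2), 1.5)
  eps <- 1e-9
  expect_equal(smooth_l1(1 - eps), smooth_l1(1 + eps), tolerance = 1e-6)
})

test_that("localisation loss is zero at the targets and counts single terms", {
  grid <- toy_grid()
  gt <- grid[1, c("cx", "cy", "w", "h")]
  m <- match_defaults(gt, grid)
  pred <- matrix(0, 4, 4)
  targ <- matrix(0, 4, 4)
  expect_equal(localization_loss(m, pred, targ), 0)
  pred[m$pos[1], 2] <- 0.5
  expect_equal(localization_loss(m, pred, targ), 0.125)
  empty <- match_defaults(gt[0, ], grid)
  expect_equal(localization_loss(empty, pred, targ), 0)
  expect_error(localization_loss(m, pred, targ[, 1:3]), "shape|identical")
})

test_that("confidence loss reproduces ln 3 and the 3:1 negative ratio", {
  grid <- toy_grid()
  gt <- grid[1, c("cx", "cy", "w", "h")]
  m <- match_defaults(gt, grid)
  logits <- matrix(0, 4, 3)
  # keep only the positive box: force zero negatives
  m_nopos <- m
  m_nopos$neg <- integer(0)
  expect_equal(confidence_loss(m_nopos, logits), log(3))
  # confident correct predictions drive the loss to zero
  big <- matrix(-50, 4, 3)
  big[cbind(1:4, m$class)] <- 50
  expect_lt(confidence_loss(m, big), 1e-10)
  # 2 positives + 6 negatives at ratio 3 counts all 6 negatives
  grid8 <- default_box_grid(list(window = 80, maps = list(
    list(size = 2, scale = 30, extra_scale = 60, aspects = NULL))))
  gt2 <- grid8[c(1, 3), c("cx", "cy", "w", "h")]
  m2 <- match_defaults(gt2, grid8)
  expect_equal(length(m2$pos), 2)
  expect_equal(length(m2$neg), 6)
  expect_equal(confidence_loss(m2, matrix(0, 8, 3)), 8 * log(3))
})

test_that("total loss normalises by match count and handles N = 0", {
  expect_equal(total_loss(2, 1, 2), 1.5)
  expect_equal(total_loss(5, 5, 0), 0)
  expect_equal(total_loss(0, 0, 3), 0)
})

test_that("the loss is invariant to ground-truth ordering", {
  det <- new_joint_detector("ankylosis", detector_config_tiny(), seed = 3)
  win <- matrix(runif(64 * 64), 64, 64)
  gt <- boxes(cx = c(20, 45), cy = c(25, 40), w = c(18, 20), h = c(18, 22))
  gt$positive <- c(TRUE, FALSE)
  x <- handjoint:::windows_to_input(win, 64)
  l1 <- handjoint:::multibox_batch_loss(det, x, list(gt), grads = FALSE)$loss
  l2 <- handjoint:::multibox_batch_loss(det, x, list(gt[2:1, ]),
                                        grads = FALSE)$loss
  expect_equal(l1, l2)
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(42)
  det <- new_joint_detector("ankylosis", detector_config_tiny(), seed = 7)
  win <- matrix(runif(64 * 64), 64, 64)
  gt <- boxes(cx = 30, cy = 35, w = 20, h = 22)
  gt$positive <- TRUE
  x <- handjoint:::windows_to_input(win, 64)
  res <- handjoint:::multibox_batch_loss(det, x, list(gt))
  eps <- 1e-5
  for (nm in names(res$grads)) {
    for (f in c("W", "b")) {
      idx <- sample(length(det$params[[nm]][[f]]), 2)
      for (i in idx) {
        d1 <- det
        d1$params[[nm]][[f]][i] <- d1$params[[nm]][[f]][i] + eps
        lp <- handjoint:::multibox_batch_loss(d1, x, list(gt),
                                              grads = FALSE)$loss
        d1$params[[nm]][[f]][i] <- d1$params[[nm]][[f]][i] - 2 * eps
        lm <- handjoint:::multibox_batch_loss(d1, x, list(gt),
                                              grads = FALSE)$loss
        num <- (lp - lm) / (2 * eps)
        ana <- res$grads[[nm]][[f]][i]
        expect_equal(ana, num, tolerance = 1e-4)
      }
    }
  }
})

test_that("compiled convolution kernels agree with the pure-R reference", {
  set.seed(9)
  for (stride in c(1L, 2L)) {
    x <- array(rnorm(12 * 12 * 2 * 3), c(12, 12, 2, 3))
    W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
    b <- rnorm(4)
    f1 <- handjoint:::conv_forward(x, W, b, stride, 1L)
    f2 <- handjoint:::conv_forward_ref(x, W, b, stride, 1L)
    expect_equal(f1$out, f2$out, tolerance = 1e-12)
    dout <- array(rnorm(length(f1$out)), dim(f1$out))
    b1 <- handjoint:::conv_backward(dout, f1, W)
    b2 <- handjoint:::conv_backward_ref(dout, f2, W)
    expect_equal(b1$dx, b2$dx, tolerance = 1e-12)
    expect_equal(b1$dW, b2$dW, tolerance = 1e-12)
    expect_equal(b1$db, b2$db, tolerance = 1e-12)
  }
})

test_that("forward pass is deterministic, grid-sized, and shape-checked", {
  det <- new_joint_detector("subluxation", detector_config_tiny(), seed = 2)
  win <- matrix(runif(64 * 64), 64, 64)
  o1 <- detector_forward(det, win)
  o2 <- detector_forward(det, win)
  expect_identical(o1, o2)
  expect_equal(nrow(o1), nrow(det$grid))
  expect_equal(rowSums(as.matrix(o1[, c("p_present", "p_absent",
                                        "p_background")])),
               rep(1, nrow(o1)), tolerance = 1e-6)
  expect_true(all(o1$confidence >= 0 & o1$confidence <= 1))
  expect_error(detector_forward(det, matrix(0, 32, 32)), "64x64")
})

test_that("augmentation transforms boxes consistently", {
  win <- matrix(runif(64 * 64), 64, 64)
  b <- boxes(cx = 20, cy = 30, w = 10, h = 12)
  # all-pass probability 0: identity
  set.seed(1)
  a0 <- augment_window(win, b, p = 0)
  expect_identical(a0$window, win)
  expect_identical(a0$boxes, b)
  # deterministic flip: p = 1 applies all four; test flip alone via helper
  flipped <- win[, 64:1]
  expect_equal(flipped[, 64:1], win)
  # rotation helper: (cx, cy) -> (H - cy, cx), sizes swap
  r <- handjoint:::rot90_boxes_cw(b, 64)
  expect_equal(unlist(r[, c("cx", "cy", "w", "h")]),
               c(cx = 64 - 30, cy = 20, w = 12, h = 10))
  # a pixel known bright follows the rotation
  m <- matrix(0, 64, 64); m[30, 20] <- 1  # x ~ 19.5, y ~ 29.5
  rm_ <- handjoint:::rot90_cw(m)
  expect_equal(rm_[20, 64 - 30 + 1], 1)
})

test_that("training on a tiny set reduces the loss deterministically", {
  pp <- tiny_params()
  ds <- generate_dataset(4L, pp, seed = 31)
  det <- train_detector(ds, "ankylosis", epochs = 2L, seed = 5)
  expect_lt(det$loss_log$loss[2], det$loss_log$loss[1])
  det2 <- train_detector(ds, "ankylosis", epochs = 2L, seed = 5)
  expect_identical(det$params, det2$params)
  expect_identical(det$loss_log, det2$loss_log)
  expect_error(train_detector(list(), "ankylosis"), "empty")
})
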