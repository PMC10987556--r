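test_that("window planning follows the stride-grid rule", {
  p <- plan_windows(1005, 835, 300, 150)
  expect_equal(nrow(p), 7 * 6)
  expect_equal(sort(unique(p$origin_x)), seq(0, 900, 150))
  expect_equal(sort(unique(p$origin_y)), seq(0, 750, 150))
  p2 <- plan_windows(300, 300, 300, 150)
  expect_equal(nrow(p2), 4)
  expect_equal(as.data.frame(p2[order(p2$origin_y, p2$origin_x), ]),
               data.frame(origin_x = c(0, 150, 0, 150),
                          origin_y = c(0, 0, 150, 150)),
               ignore_attr = TRUE)
  # image smaller than the window: one fully padded window
  expect_equal(nrow(plan_windows(100, 80, 300, 150)), 1)
  expect_error(plan_windows(0, 100), "non-positive")
  expect_error(plan_windows(100, 100, window = 100, stride = 120), "stride")
})

test_that("window union covers the image and phantom joints fit one window", {
  pp <- tiny_params()
  ph <- generate_hand(pp, seed = 3)
  win <- 64L; stride <- 32L
  p <- plan_windows(ph$width, ph$height, win, stride)
  covered <- matrix(FALSE, ph$height, ph$width)
  for (i in seq_len(nrow(p))) {
    rs <- (p$origin_y[i] + 1):min(ph$height, p$origin_y[i] + win)
    cs <- (p$origin_x[i] + 1):min(ph$width, p$origin_x[i] + win)
    covered[rs, cs] <- TRUE
  }
  expect_true(all(covered))
  # each joint box (side < window - stride) lies fully inside some window
  jb <- box_corners(ph$joints)
  expect_true(all(jb$x1 - jb$x0 < win - stride))
  for (i in seq_len(nrow(jb))) {
    inside <- any(p$origin_x <= jb$x0[i] & jb$x1[i] <= p$origin_x + win &
                    p$origin_y <= jb$y0[i] & jb$y1[i] <= p$origin_y + win)
    expect_true(inside)
  }
})

test_that("confidence filtering is strict and order-preserving", {
  d <- boxes(cx = 1:3 * 10, cy = 10, w = 5, h = 5,
             confidence = c(0.95, 0.9, 0.5))
  kept <- filter_confidence(d, 0.9)
  expect_equal(kept$confidence, 0.95)
  expect_equal(filter_confidence(d, 0)$confidence, d$confidence)
  expect_equal(nrow(filter_confidence(d[0, ], 0.9)), 0)
})

test_that("NMS keeps the higher-confidence duplicate and all disjoint boxes", {
  dup <- boxes(cx = c(10, 10), cy = 10, w = 6, h = 6,
               confidence = c(0.99, 0.95))
  expect_equal(nms(dup, 0.15)$confidence, 0.99)
  far <- boxes(cx = c(10, 50, 90), cy = 10, w = 6, h = 6,
               confidence = c(0.5, 0.9, 0.7))
  expect_equal(nrow(nms(far, 0.15)), 3)
})

test_that("NMS equals the brute-force greedy oracle on random instances", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    d <- boxes(cx = runif(n, 0, 60), cy = runif(n, 0, 60),
               w = runif(n, 5, 25), h = runif(n, 5, 25),
               confidence = runif(n))
    t_iou <- sample(c(0.15, 0.3, 0.5), 1)
    got <- nms(d, t_iou)
    want <- nms_oracle(d, t_iou)
    expect_equal(as.data.frame(got[order(got$confidence), ]),
                 as.data.frame(want[order(want$confidence), ]),
                 ignore_attr = TRUE)
    # idempotence and the no-surviving-overlap postcondition
    expect_equal(as.data.frame(nms(got, t_iou)), as.data.frame(got))
    if (nrow(got) > 1) {
      m <- box_iou(got, got)
      expect_true(all(m[upper.tri(m)] < t_iou))
    }
  }
})

test_that("top-M selection sorts, caps, and validates", {
  set.seed(3)
  d <- boxes(cx = runif(25, 0, 100), cy = runif(25, 0, 100), w = 5, h = 5,
             confidence = runif(25))
  top <- select_top_m(d, 20)
  expect_equal(top$confidence, sort(d$confidence, decreasing = TRUE)[1:20])
  expect_equal(nrow(select_top_m(d, 50)), 25)
  expect_equal(nrow(select_top_m(d, 0)), 0)
  expect_error(select_top_m(d, -1), "non-negative")
  # idempotence
  expect_identical(select_top_m(top, 20), top)
})

test_that("scan translates window-local detections into image coordinates", {
  pp <- tiny_params()
  ph <- generate_hand(pp, seed = 9)
  det <- new_joint_detector("ankylosis", detector_config_tiny(), seed = 4)
  plan <- plan_windows(ph$width, ph$height, 64L, 32L)[1:4, ]
  full <- scan_image(ph$image, det, plan)
  nb <- nrow(det$grid)
  expect_equal(nrow(full), 4 * nb)
  # recompute window 2 by hand: local decode + origin shift
  o <- plan[2, ]
  crop <- handjoint:::crop_with_pad(ph$image, o$origin_x, o$origin_y, 64, 64)
  out <- detector_forward(det, crop)
  dec <- decode_boxes(out[, c("t_cx", "t_cy", "t_w", "t_h")], det$grid)
  rows <- full[full$origin_x == o$origin_x & full$origin_y == o$origin_y, ]
  expect_equal(rows$cx, dec$cx + o$origin_x)
  expect_equal(rows$cy, dec$cy + o$origin_y)
  expect_equal(rows$w, dec$w)
})

test_that("oracle-driven single prediction recovers every joint at the cap", {
  ph <- positive_phantom(13)
  cfg <- run_config()
  b1 <- predict_single(ph, oracle_predictor("ankylosis", seed = 2), cfg)
  expect_equal(nrow(b1), 20)
  asg <- match_to_ground_truth(b1, ph$joints)
  expect_true(all(asg$detected))
  expect_equal(mean(asg$iou), 1)
  b2 <- predict_single(ph, oracle_predictor("subluxation", seed = 2), cfg)
  expect_equal(nrow(b2), 18)
  # duplicate emissions collapse to one box per joint
  dup <- dplyr::bind_rows(b1, b1)
  expect_equal(nrow(nms(dup, cfg$t_iou1)), 20)
})
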