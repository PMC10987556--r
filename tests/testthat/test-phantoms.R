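test_that("a phantom carries 20 boxes, 18 subluxation slots, inside the raster", {
  ph <- generate_hand(tiny_params(), seed = 2)
  expect_s3_class(ph, "hand_phantom")
  expect_equal(nrow(ph$joints), 20)
  expect_equal(sum(!is.na(ph$joints$subluxation)), 18)
  expect_equal(sum(ph$joints$joint_type == "IP"), 2)
  expect_equal(sum(ph$joints$joint_type == "MP"), 10)
  jb <- box_corners(ph$joints)
  expect_true(all(jb$x0 >= 0 & jb$x1 <= ph$width &
                    jb$y0 >= 0 & jb$y1 <= ph$height))
  expect_equal(dim(ph$image), c(256, 320))
  expect_true(all(ph$image >= 0 & ph$image <= 1))
})

test_that("forced prevalences drive the flags", {
  none <- generate_hand(tiny_params(prev_ankylosis = 0, prev_subluxation = 0),
                        seed = 5)
  expect_false(any(none$joints$ankylosis))
  expect_false(any(none$joints$subluxation, na.rm = TRUE))
  all_ank <- generate_hand(tiny_params(prev_ankylosis = 1), seed = 5)
  expect_true(all(all_ank$joints$ankylosis))
  all_sub <- generate_hand(tiny_params(prev_subluxation = 1), seed = 5)
  expect_equal(sum(all_sub$joints$subluxation, na.rm = TRUE), 18)
})

test_that("findings change the rendered appearance as specified", {
  pp <- tiny_params(noise_sd = 0)
  none <- generate_hand(pp, seed = 8)
  ank <- generate_hand(utils::modifyList(pp, list(prev_ankylosis = 1),
                                         keep.null = TRUE), seed = 8)
  # ankylosis fills the joint-space gap to bone intensity at the box center
  j <- none$joints[3, ]
  expect_lt(none$image[round(j$cy), round(j$cx)], pp$bone_intensity - 0.1)
  j2 <- ank$joints[3, ]
  expect_equal(ank$image[round(j2$cy), round(j2$cx)], pp$bone_intensity)
  # subluxation shifts distal segments: with both joints subluxed, the PIP
  # box center sits one full offset (>= 40% of finger width) lateral of MP
  sub <- generate_hand(utils::modifyList(pp, list(prev_subluxation = 1),
                                         keep.null = TRUE), seed = 8)
  pip <- sub$joints[sub$joints$joint_type == "PIP", ]
  mp <- sub$joints[sub$joints$joint_type == "MP" & sub$joints$finger > 1, ]
  shift <- abs(pip$cx - mp$cx[match(paste(pip$hand, pip$finger),
                                    paste(mp$hand, mp$finger))])
  expect_true(all(shift >= 0.4 * pp$finger_width - 1e-9))
})

test_that("generation is seed-deterministic and rejects bad sizes", {
  pp <- tiny_params()
  a <- generate_hand(pp, seed = 4)
  b <- generate_hand(pp, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$image, generate_hand(pp, seed = 5)$image))
  expect_error(generate_hand(phantom_params(image_width = 40,
                                            image_height = 30), seed = 1),
               "too small")
})

test_that("dataset arithmetic matches the study cohort shape", {
  pp <- tiny_params()
  ds <- generate_dataset(10L, pp, seed = 6, render = FALSE)
  expect_equal(length(ds$images), 10)
  jt <- dataset_joints(ds)
  expect_equal(nrow(jt), 200)
  expect_equal(sum(!is.na(jt$subluxation)), 180)
  expect_equal(unique(table(jt$patient_id)), 40)  # 2 images x 20 joints
  # both timepoints of a patient share finding flags
  for (p in 1:2) {
    t1 <- jt[jt$patient_id == p & jt$timepoint == 1, ]
    t2 <- jt[jt$patient_id == p & jt$timepoint == 2, ]
    expect_equal(t1$ankylosis, t2$ankylosis)
    expect_equal(t1$subluxation, t2$subluxation)
    # geometry drifts between timepoints
    expect_false(identical(t1$cx, t2$cx))
  }
  expect_error(generate_dataset(9L, pp), "even")
  # reproducible: same seed, identical annotations
  ds2 <- generate_dataset(10L, pp, seed = 6, render = FALSE)
  expect_identical(dataset_joints(ds2), jt)
})

test_that("positive counts stay inside the binomial band at study prevalence", {
  pp <- tiny_params()
  counts <- vapply(1:6, function(s) {
    jt <- dataset_joints(generate_dataset(60L, pp, seed = 100 + s,
                                          render = FALSE))
    sum(jt$ankylosis)
  }, 1L)
  n <- 60 * 20
  p <- 157 / 5200
  # flags are drawn per patient and shared by both timepoints, which doubles
  # the count variance relative to independent per-joint draws
  band <- 2 * sqrt(2 * n * p * (1 - p) / 6)
  expect_gt(mean(counts), n * p - band)
  expect_lt(mean(counts), n * p + band)
})

test_that("the oracle detector spans the jitter/dropout contract", {
  ph <- positive_phantom(17)
  exact <- oracle_detector(ph, "ankylosis", seed = 3)
  expect_equal(nrow(exact), 20)
  asg <- match_to_ground_truth(exact, ph$joints)
  expect_equal(asg$iou, rep(1, 20))
  expect_true(all(exact$confidence > 0.9))
  # label probabilities encode the ground-truth flags
  m <- asg$pred
  expect_equal(exact$p_present[m] > exact$p_absent[m], ph$joints$ankylosis)
  expect_equal(nrow(oracle_detector(ph, "ankylosis", dropout_rate = 1)), 0)
  expect_equal(nrow(oracle_detector(ph, "subluxation", seed = 2)), 18)
  # moderate jitter keeps every joint above the 0.45 success threshold
  jit <- oracle_detector(ph, "ankylosis", box_jitter = 0.1, seed = 9)
  aj <- match_to_ground_truth(jit, ph$joints)
  expect_true(all(aj$detected))
  expect_true(all(aj$iou < 1))
  # determinism
  expect_identical(oracle_detector(ph, "ankylosis", box_jitter = 0.2, seed = 4),
                   oracle_detector(ph, "ankylosis", box_jitter = 0.2, seed = 4))
})
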