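test_that("confusion counts match a brute-force per-voxel loop", {
  set.seed(19)
  pred <- random_binary(c(10, 10, 10))
  truth <- random_binary(c(10, 10, 10))
  cc <- confusion(pred, truth)
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  expect_equal(cc$TP, tp); expect_equal(cc$TN, tn)
  expect_equal(cc$FP, fp); expect_equal(cc$FN, fn)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 1000L)

  expect_equal(confusion(truth, truth)$FP, 0L)
  expect_equal(confusion(truth, truth)$FN, 0L)
  inv <- confusion(1L - truth, truth)
  expect_equal(inv$TP, 0L); expect_equal(inv$TN, 0L)
  expect_error(confusion(pred, random_binary(c(5, 5, 5))), "shape")
  expect_error(confusion(pred * 2L, truth), "binary")
})

test_that("metrics follow their closed forms and encode undefined cases as NA", {
  mk <- function(TP, TN, FP, FN)
    structure(list(TP = TP, TN = TN, FP = FP, FN = FN), class = "confusion_counts")
  m <- seg_metrics(mk(3, 10, 1, 1))
  expect_equal(m$precision, 0.75); expect_equal(m$recall, 0.75)
  expect_equal(m$dice, 0.75)

  m0 <- seg_metrics(mk(0, 10, 0, 0))
  expect_true(is.na(m0$precision) && is.na(m0$recall) && is.na(m0$dice))

  m2 <- seg_metrics(mk(2, 10, 4, 1))
  expect_equal(m2$precision, 1 / 3); expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$dice, 4 / 9)
  expect_equal(m2$dice, 2 * m2$precision * m2$recall / (m2$precision + m2$recall))
})

test_that("the Dice-IoU identity holds to 1e-12 on random counts", {
  set.seed(23)
  for (i in 1:50) {
    cc <- structure(as.list(c(TP = sample(0:500, 1), TN = 100,
                              FP = sample(0:200, 1), FN = sample(0:200, 1))),
                    class = "confusion_counts")
    m <- seg_metrics(cc)
    if (!is.na(m$dice))
      expect_equal(m$dice, 2 * m$foreground_iou / (1 + m$foreground_iou),
                   tolerance = 1e-12)
  }
})

test_that("tongue volume is voxel count times voxel volume in cm^3", {
  mask <- array(0L, c(4, 4, 4)); mask[1:2, 1, 1] <- 1L; mask[1:2, 2, 1] <- 1L
  mask[1:2, 1, 2] <- 1L; mask[1:2, 2, 2] <- 1L           # 8 voxels
  expect_equal(tongue_volume(mask, 0.5), 0.001)
  expect_equal(tongue_volume(array(0L, c(4, 4, 4)), 0.5), 0)
  # 763,800 voxels at 0.5 mm --> 95.475 cm^3: the scale of adult tongue volumes
  expect_equal(763800 * 0.5^3 / 1000, 95.475)
  expect_error(tongue_volume(mask + 1L, 0.5), "binary")
  expect_error(tongue_volume(mask, 0), "spacing")
})

test_that("overlay colours encode the confusion classes exactly", {
  set.seed(29)
  pred <- random_binary(c(12, 12))
  truth <- random_binary(c(12, 12))
  img <- matrix(runif(144), 12, 12)
  ov <- overlay_slice(pred, truth, img)
  is_col <- function(rgb) sum(ov[, , 1] == rgb[1] & ov[, , 2] == rgb[2] &
                                ov[, , 3] == rgb[3])
  cc <- confusion(pred, truth)
  expect_equal(is_col(c(1, 0, 1)), cc$TP)
  expect_equal(is_col(c(0, 0, 1)), cc$FP)
  expect_equal(is_col(c(1, 1, 0)), cc$FN)

  perfect <- overlay_slice(truth, truth, img)
  expect_equal(sum(perfect[, , 1] == 0 & perfect[, , 2] == 0 & perfect[, , 3] == 1), 0)
  miss <- overlay_slice(truth * 0L, truth, img)
  expect_equal(sum(miss[, , 1] == 1 & miss[, , 2] == 1 & miss[, , 3] == 0),
               sum(truth))
})

test_that("paired comparison gates on normality and handles degenerate input", {
  x <- c(104.547, 109.554, 90.624, 96.957, 108.887, 109.253, 95.679, 118.27,
         101.821, 111.964, 94.389, 93.441)
  y <- c(108.691, 111.452, 94.305, 98.044, 111.581, 108.682, 90.855, 118.725,
         105.634, 115.448, 96.593, 92.944)
  cmp <- compare_paired(y, x)
  expect_equal(cmp$test_name, "paired t")
  expect_equal(cmp$statistic, 1.973643400816, tolerance = 1e-9)
  expect_equal(cmp$p_value, 7.406946806748e-02, tolerance = 1e-9)

  same <- compare_paired(x, x)
  expect_match(same$test_name, "zero-variance")
  expect_false(same$significant)

  shifted <- compare_paired(x + 3, x)
  expect_match(shifted$test_name, "zero-variance")
  expect_error(compare_paired(x, x[1:3]), "length mismatch")
})

test_that("two-group comparison selects the test by the Shapiro-Wilk gate", {
  a <- c(110.811, 114.714, 103.606, 101.521, 108.908, 97.282, 122.088, 108.389,
         115.435, 98.468, 102.898, 116.616, 105.989, 110.33, 111.334, 91.748,
         116.672, 99.451, 100.349)
  b <- c(102.46, 80.296, 125.086, 86.6, 66.41, 77.521, 99.804, 108.615, 89.145,
         83.886, 95.377, 106.993, 112.284, 83.647, 75.649, 85.526, 50.863,
         87.186, 93.636)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$test_name, "unpaired t")
  expect_equal(cmp$statistic, 3.939528607292, tolerance = 1e-9)
  expect_equal(cmp$p_value, 3.595401274653e-04, tolerance = 1e-9)
  expect_true(cmp$significant)

  # an extreme outlier defeats normality and fires the Mann-Whitney gate
  heavy <- c(a[1:18], 500)
  cmp2 <- compare_groups(heavy, b)
  expect_equal(cmp2$test_name, "Mann-Whitney U")
  expect_lt(shapiro.test(heavy)$p.value, 0.05)

  same <- compare_groups(a, a)
  expect_gt(same$p_value, 0.99)
  expect_error(compare_groups(a[1:2], b), "at least 3")
})

test_that("two-group p-values equal the reference implementations to 1e-8", {
  a <- c(110.811, 114.714, 103.606, 101.521, 108.908, 97.282, 122.088, 108.389,
         115.435, 98.468, 102.898, 116.616, 105.989, 110.33, 111.334, 91.748,
         116.672, 99.451, 100.349)
  b <- c(102.46, 80.296, 125.086, 86.6, 66.41, 77.521, 99.804, 108.615, 89.145,
         83.886, 95.377, 106.993, 112.284, 83.647, 75.649, 85.526, 50.863,
         87.186, 93.636)
  heavy <- c(a[1:18], 500)
  mw <- compare_groups(heavy, b)
  ref <- wilcox.test(heavy, b, exact = FALSE)
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("strategy summaries aggregate per-subject metrics, not pooled counts", {
  rows <- rbind(
    data.frame(subject = "s1", strategy = "softmax", TP = 90, TN = 800, FP = 10,
               FN = 10, precision = 0.9, recall = 0.9, dice = 0.9),
    data.frame(subject = "s2", strategy = "softmax", TP = 1, TN = 890, FP = 9,
               FN = 9, precision = 0.1, recall = 0.1, dice = 0.1))
  t1 <- table1_report(rows)
  expect_equal(t1$dice_mean, 0.5)
  # pooled-count dice differs from the mean of per-subject dice
  pooled <- 2 * 91 / (2 * 91 + 19 + 19)
  expect_false(isTRUE(all.equal(pooled, t1$dice_mean)))

  single <- table1_report(rows[1, ])
  expect_equal(single$dice_sd, 0)

  bad <- rbind(rows, data.frame(subject = "s3", strategy = "union", TP = 1,
                                TN = 1, FP = 1, FN = 1, precision = 0.5,
                                recall = 0.5, dice = 0.5))
  expect_error(table1_report(bad), "inconsistent")
})
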