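test_that("weighted fold averaging reproduces hand-computed values", {
  p1 <- array(0.6, c(2, 2, 2)); p2 <- array(0.9, c(2, 2, 2))
  expect_equal(ensemble_softmax(list(p1, p2), c(1, 1)), (p1 + p2) / 2)
  expect_equal(ensemble_softmax(list(p1, p2), c(0.5, 1.0))[1], 0.8)
  expect_equal(ensemble_softmax(list(p1), 2), p1)
  expect_error(ensemble_softmax(list(p1, p2), 1), "length mismatch")
  expect_error(ensemble_softmax(list(p1, p2), c(1, -1)), "positive")
  expect_error(ensemble_softmax(list(p1, array(0, c(1, 1, 1))), c(1, 1)), "shape")
})

test_that("voting rules equal the brute-force truth table on all 8 hard patterns", {
  patterns <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  votes <- rowSums(patterns)
  preds <- lapply(c("a", "b", "c"), function(k) array(patterns[[k]], c(8, 1, 1)))
  for (s in c("union", "majority", "unanimous")) {
    need <- c(union = 1, majority = 2, unanimous = 3)[[s]]
    got <- merge_consensus(preds, consensus_config(s))
    expect_equal(as.vector(got), as.integer(votes >= need), info = s)
  }
  # softmax averaging with equal weights == majority voting on hard inputs
  expect_equal(merge_consensus(preds, consensus_config("softmax")),
               merge_consensus(preds, consensus_config("majority")))
})

test_that("softmax/majority equivalence holds on random hard grids but not soft ones", {
  set.seed(5)
  for (i in 1:20) {
    preds <- lapply(1:3, function(k) random_binary(c(6, 6, 6)) * 1.0)
    expect_identical(merge_consensus(preds, consensus_config("softmax")),
                     merge_consensus(preds, consensus_config("majority")))
  }
  # boundary of the equivalence: one confident vote, two weak ones
  soft <- lapply(c(0.9, 0.3, 0.3), function(v) array(v, c(1, 1, 1)))
  sm <- merge_consensus(soft, consensus_config("softmax"))    # mean 0.5 -> tie -> 1
  mj <- merge_consensus(soft, consensus_config("majority"))   # votes (1,0,0) -> 0
  expect_equal(as.integer(sm), 1L)
  expect_equal(as.integer(mj), 0L)
})

test_that("hardening applies the >= tie rule and the complement identity", {
  expect_equal(as.integer(harden(array(0.5, c(1, 1, 1)), 0.5)), 1L)
  expect_true(all(harden(array(0, c(3, 3, 3)), 0.5) == 0L))
  set.seed(7)
  p <- array(runif(4^3, 0.01, 0.99), c(4, 4, 4))
  p <- round(p, 3) + 1e-4          # keep values away from exact ties
  expect_identical(harden(1 - p, 1 - 0.3), 1L - harden(p, 0.3))
  expect_error(harden(p, 0), "threshold")
})

test_that("unanimous is contained in majority is contained in union, with monotone recall", {
  set.seed(11)
  truth <- random_binary(c(8, 8, 8), p = 0.3)
  for (i in 1:100) {
    preds <- lapply(1:3, function(k) array(runif(512), c(8, 8, 8)))
    m <- lapply(c("unanimous", "majority", "union"), function(s)
      merge_consensus(preds, consensus_config(s)))
    expect_true(all(m[[1]] <= m[[2]]))
    expect_true(all(m[[2]] <= m[[3]]))
    rec <- vapply(m, function(mask) {
      cc <- confusion(mask, truth)
      if (cc$TP + cc$FN == 0) NA_real_ else cc$TP / (cc$TP + cc$FN)
    }, numeric(1))
    expect_true(rec[1] <= rec[2] && rec[2] <= rec[3])
  }
})

test_that("identical orientation predictions collapse all strategies to one mask", {
  set.seed(3)
  p <- array(runif(6^3), c(6, 6, 6))
  preds <- list(p, p, p)
  masks <- lapply(c("softmax", "union", "majority", "unanimous"), function(s)
    merge_consensus(preds, consensus_config(s)))
  for (k in 2:4) expect_identical(masks[[1]], masks[[k]])
  expect_error(merge_consensus(preds[1:2], consensus_config("union")), "three")
})

# A handmade two-fold ensemble around tiny networks: lets us check the
# fold-ensembling and restacking logic without training.
mock_ensemble <- function(seed_a = 1L, seed_b = 2L, w = c(0.6, 0.9)) {
  cfg <- unet_config(c(2, 4), dropout_rate = 0, input_size = 16, seed = seed_a)
  ma <- build_unet(cfg)
  cfgb <- cfg; cfgb$seed <- seed_b
  mb <- build_unet(cfgb)
  folds <- list(
    structure(list(weights = unet_weights(ma), w = w[1], history = NULL,
                   val_subjects = "s1", best_epoch = 1L, seed = seed_a),
              class = "fold_result"),
    structure(list(weights = unet_weights(mb), w = w[2], history = NULL,
                   val_subjects = "s2", best_epoch = 1L, seed = seed_b),
              class = "fold_result"))
  structure(list(folds = folds, unet_config = cfg, train_config = NULL,
                 norm_stats = NULL, grid = grid_spec(16, 8)),
            class = "ensemble_model")
}

test_that("orientation prediction restacks slices onto the input grid", {
  ens <- mock_ensemble()
  vol <- generate_phantom(tiny_spec(seed = 51L))
  pred <- predict_orientation(ens, vol, "axial")
  expect_equal(dim(pred$score), dim(vol$intensity))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  wrong <- generate_phantom(tiny_spec(seed = 51L, grid = 32L))
  expect_error(predict_orientation(ens, wrong, "axial"), "grid")
})

test_that("an ensemble of identical folds equals the single model, and fold order is irrelevant", {
  ens_same <- mock_ensemble(seed_a = 4L, seed_b = 4L, w = c(0.5, 1.0))
  vol <- generate_phantom(tiny_spec(seed = 52L))
  pred <- predict_orientation(ens_same, vol, "sagittal")
  cfg <- ens_same$unet_config
  single <- build_unet(cfg)
  sb <- extract_slices(vol, "sagittal")
  p <- predict_batch(single, sb$images)
  manual <- reassemble_slices(p[, , 2, ], "sagittal")
  expect_equal(pred$score, manual, tolerance = 1e-6)

  ens <- mock_ensemble()
  flipped <- ens
  flipped$folds <- rev(flipped$folds)
  expect_equal(predict_orientation(ens, vol, "coronal")$score,
               predict_orientation(flipped, vol, "coronal")$score,
               tolerance = 1e-7)
})

test_that("subject prediction returns the seven Table-style variants", {
  ens <- mock_ensemble()
  vol <- generate_phantom(tiny_spec(seed = 53L))
  pred <- predict_subject(ens, vol)
  expect_named(pred$masks, c("axial", "sagittal", "coronal", "softmax",
                             "union", "majority", "unanimous"))
  for (m in pred$masks) expect_true(all(m %in% c(0L, 1L)))
  # inclusion chain holds on real predictions too
  expect_true(all(pred$masks$unanimous <= pred$masks$majority))
  expect_true(all(pred$masks$majority <= pred$masks$union))
})
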