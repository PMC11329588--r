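test_that("slice extraction counts, shapes and round trips are exact", {
  vol <- generate_phantom(tiny_spec(seed = 41L))
  for (ori in c("axial", "sagittal", "coronal")) {
    sb <- extract_slices(vol, ori)
    expect_equal(dim(sb$images), c(16L, 16L, 16L))
    expect_equal(dim(sb$labels), dim(sb$images))
    expect_identical(reassemble_slices(sb$images, ori), vol$intensity)
    expect_identical(reassemble_slices(sb$labels, ori), vol$mask)
  }
  expect_error(extract_slices(vol, "oblique"), "unknown orientation")
})

test_that("a single-voxel mask appears in exactly one axial slice", {
  arr <- array(0, c(16, 16, 16))
  mask <- array(0L, c(16, 16, 16))
  mask[5, 9, 12] <- 1L
  vol <- labeled_volume(arr, mask, spacing_mm = 8)
  sb <- extract_slices(vol, "axial")   # slices along the IS axis (axis 3)
  with_fg <- which(apply(sb$labels, 3, sum) > 0)
  expect_identical(with_fg, 12L)
  expect_equal(sum(apply(extract_slices(vol, "sagittal")$labels, 3, sum) > 0), 1L)
})

test_that("triplanar pooling yields 3NL slices with faithful provenance", {
  vols <- tiny_cohort(n = 3L)
  ds <- build_triplanar_dataset(vols)
  expect_equal(dim(ds$images)[3], 3 * 3 * 16)
  expect_equal(nrow(ds$provenance), 3 * 3 * 16)
  ax <- ds$provenance[ds$provenance$orientation == "axial", ]
  expect_equal(nrow(ax), 3 * 16)
  # provenance positions index the pooled arrays correctly
  row <- ds$provenance[ds$provenance$subject == "s02" &
                         ds$provenance$orientation == "coronal" &
                         ds$provenance$slice_index == 7, ]
  expect_identical(ds$images[, , row$pos],
                   extract_slices(vols$s02, "coronal")$images[, , 7])
  expect_error(build_triplanar_dataset(list()), "empty")
  bad <- c(vols, list(x = generate_phantom(tiny_spec(grid = 32L))))
  expect_error(build_triplanar_dataset(bad), "mixed")
})

test_that("mean IoU matches hand-enumerated cases", {
  m <- matrix(0L, 4, 4)
  truth <- m; truth[2:3, 2:3] <- 1L
  pred <- m; pred[2:3, 3:4] <- 1L
  # foreground IoU 2/6, background IoU 10/14, mean = 11/21
  expect_equal(mean_iou(pred, truth), 11 / 21)
  expect_equal(mean_iou(truth, truth), 1)
  # complementary masks share no class anywhere
  expect_equal(mean_iou(1L - truth, truth), 0)
  expect_error(mean_iou(matrix(0L, 2, 2), truth), "shape mismatch")
})

test_that("cross-validation splits at subject level without leakage", {
  vols <- tiny_cohort(n = 5L)
  cfg <- unet_config(c(2, 4), dropout_rate = 0.2, input_size = 16, seed = 1L)
  tc <- train_config(max_epochs = 2, early_stop_patience = 1, batch_size = 16,
                     learning_rate = 1e-3, n_folds = 5, seed = 11L)
  ens <- train_cv(vols, cfg, tc)
  expect_s3_class(ens, "ensemble_model")
  expect_length(ens$folds, 5)
  val_sets <- lapply(ens$folds, function(f) f$val_subjects)
  expect_true(all(lengths(val_sets) == 1))                  # 5 subjects, 5 folds
  expect_setequal(unlist(val_sets), names(vols))            # union = cohort
  for (f in ens$folds) {
    expect_length(intersect(f$val_subjects, setdiff(names(vols), f$val_subjects)), 0)
    expect_lte(nrow(f$history), tc$max_epochs)
    expect_equal(f$history$val_loss[f$best_epoch], min(f$history$val_loss))
    expect_true(is.finite(f$w) && f$w > 0)
  }
  expect_error(train_cv(vols[1:3], cfg, tc), "fewer subjects than folds")
})

test_that("training is reproducible for a fixed seed", {
  vols <- tiny_cohort(n = 5L)
  cfg <- unet_config(c(2, 4), dropout_rate = 0.2, input_size = 16, seed = 1L)
  tc <- train_config(max_epochs = 2, early_stop_patience = 1, batch_size = 16,
                     learning_rate = 1e-3, n_folds = 5, seed = 13L)
  e1 <- train_cv(vols, cfg, tc)
  e2 <- train_cv(vols, cfg, tc)
  expect_identical(vapply(e1$folds, function(f) f$w, numeric(1)),
                   vapply(e2$folds, function(f) f$w, numeric(1)))
  expect_identical(e1$folds[[1]]$history, e2$folds[[1]]$history)
})

test_that("training loss decreases over epochs on an easy task", {
  vols <- tiny_cohort(n = 5L, grid = 16L)
  # normalize so the network sees zero-centered inputs
  prep <- preprocess_cohort(vols, grid_spec(16, 8), grid_spec(16, 8), grid_spec(8, 8))
  cfg <- unet_config(c(4, 8), dropout_rate = 0, input_size = 16, seed = 2L)
  tc <- train_config(max_epochs = 4, early_stop_patience = 3, batch_size = 16,
                     learning_rate = 2e-3, n_folds = 5, seed = 17L)
  ens <- train_cv(prep$vols, cfg, tc)
  h <- ens$folds[[1]]$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})
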