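#' Extract 2-D slices along an anatomical orientation
#'
#' Slices are taken perpendicular to the named anatomical axis (axial:
#' inferior-superior; sagittal: left-right; coronal: anterior-posterior) in
#' ascending index order, with per-pixel class labels from the mask when
#' present.
#'
#' @param vol A [labeled_volume()] on a cubic grid.
#' @param orientation One of `"axial"`, `"sagittal"`, `"coronal"`.
#' @param subject Optional subject id recorded in the provenance.
#' @return A `slice_batch`: list with `images` `(H, W, n)`, `labels`
#'   (integer, same shape, or `NULL`), `orientation`, `slice_index`,
#'   `subject`.
#' @export
extract_slices <- function(vol, orientation, subject = NA_character_) {
  stopifnot(inherits(vol, "labeled_volume"))
  axis <- orientation_axis(orientation, vol$axis_labels)
  images <- slices_along(vol$intensity, axis)
  labels <- if (!is.null(vol$mask)) slices_along(vol$mask, axis) else NULL
  if (!is.null(labels)) storage.mode(labels) <- "integer"
  structure(list(images = images, labels = labels, orientation = orientation,
                 slice_index = seq_len(dim(images)[3]), subject = subject),
            class = "slice_batch")
}

orientation_axis <- function(orientation, axis_labels = c("AP", "LR", "IS")) {
  label <- switch(orientation,
                  axial = "IS", sagittal = "LR", coronal = "AP",
                  stop(sprintf("unknown orientation '%s'", orientation)))
  match(label, axis_labels)
}

slices_along <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  keep <- d[-axis]
  out <- array(a[1] * 0L, dim = c(keep, n))
  for (i in seq_len(n)) {
    out[, , i] <- switch(axis, a[i, , ], a[, i, ], a[, , i])
  }
  out
}

#' Reassemble slices into a 3-D volume
#'
#' Exact inverse of the slice extraction of [extract_slices()]: stacking the
#' extracted slices back along the same orientation reproduces the original
#' array bit for bit.
#'
#' @param slices Array `(H, W, n)` of slices in ascending index order.
#' @param orientation One of `"axial"`, `"sagittal"`, `"coronal"`.
#' @param axis_labels Axis labels of the target volume.
#' @return A 3-D array.
#' @export
reassemble_slices <- function(slices, orientation, axis_labels = c("AP", "LR", "IS")) {
  axis <- orientation_axis(orientation, axis_labels)
  d <- dim(slices)
  n <- d[3]
  full <- switch(axis, c(n, d[1], d[2]), c(d[1], n, d[2]), c(d[1], d[2], n))
  out <- array(slices[1] * 0L, dim = full)
  for (i in seq_len(n)) {
    if (axis == 1L) out[i, , ] <- slices[, , i]
    else if (axis == 2L) out[, i, ] <- slices[, , i]
    else out[, , i] <- slices[, , i]
  }
  out
}

#' Pool triplanar slices from a cohort into one training set
#'
#' Slices from all three orientations of all subjects are pooled into a
#' single collection (the reason all volumes must share one cubic grid: all
#' slices then have identical dimensions). Per-slice provenance (subject,
#' orientation, slice index) is retained.
#'
#' @param vols Named list of [labeled_volume()] on a common cubic grid.
#' @param orientations Orientations to include (default all three).
#' @return A `triplanar_dataset`: list with `images` `(L, L, N)`, `labels`
#'   (integer, same shape) and `provenance` data frame.
#' @export
build_triplanar_dataset <- function(vols,
                                    orientations = c("axial", "sagittal", "coronal")) {
  if (length(vols) == 0L) stop("empty subject list")
  if (is.null(names(vols))) names(vols) <- sprintf("subj_%02d", seq_along(vols))
  d0 <- dim(vols[[1]]$intensity)
  if (length(unique(d0)) != 1L) stop("volumes must be cubic")
  for (v in vols)
    if (!identical(dim(v$intensity), d0)) stop("mixed grid shapes in cohort")
  L <- d0[1]
  n_total <- length(vols) * length(orientations) * L
  images <- array(0, dim = c(L, L, n_total))
  labels <- array(0L, dim = c(L, L, n_total))
  prov <- vector("list", length(vols) * length(orientations))
  pos <- 0L; pi <- 0L
  for (sid in names(vols)) {
    for (ori in orientations) {
      sb <- extract_slices(vols[[sid]], ori, subject = sid)
      n <- dim(sb$images)[3]
      images[, , pos + seq_len(n)] <- sb$images
      if (!is.null(sb$labels)) labels[, , pos + seq_len(n)] <- sb$labels
      pi <- pi + 1L
      prov[[pi]] <- data.frame(subject = sid, orientation = ori,
                               slice_index = seq_len(n), pos = pos + seq_len(n))
      pos <- pos + n
    }
  }
  structure(list(images = images, labels = labels,
                 provenance = do.call(rbind, prov)),
            class = "triplanar_dataset")
}

#' Mean intersection over union
#'
#' Per-class IoU (intersection over union of the voxels labelled with that
#' class), averaged over classes; classes absent from both prediction and
#' truth are skipped.
#'
#' @param pred,truth Integer arrays of class labels, same shape.
#' @param n_classes Number of classes.
#' @return Mean IoU in `[0, 1]`.
#' @export
mean_iou <- function(pred, truth, n_classes = 2) {
  if (length(pred) != length(truth) || !identical(dim(pred), dim(truth)))
    stop("shape mismatch")
  ious <- numeric(0)
  for (k in seq_len(n_classes) - 1L) {
    inter <- sum(pred == k & truth == k)
    uni <- sum(pred == k | truth == k)
    if (uni > 0) ious <- c(ious, inter / uni)
  }
  if (length(ious) == 0L) return(NA_real_)
  mean(ious)
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: at most 50 epochs with
#' early stopping after 10 epochs without validation-loss improvement, batch
#' size 16, Adam with learning rate 1e-4 (remaining moment parameters at
#' their conventional defaults), categorical cross-entropy loss, fivefold
#' cross-validation.
#'
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (must be < `max_epochs`).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param n_folds Cross-validation folds (>= 2).
#' @param seed Global seed; per-fold seeds are derived from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 50, early_stop_patience = 10,
                         batch_size = 16, learning_rate = 1e-4,
                         n_folds = 5, seed = 1L) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (early_stop_patience >= max_epochs) stop("patience must be < max_epochs")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "train_config")
}

predict_foreground_chunked <- function(model, images, chunk = 32L) {
  n <- dim(images)[3]
  out <- array(0, dim = dim(images))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- predict_batch(model, images[, , s:e, drop = FALSE])
    out[, , s:e] <- p[, , 2L, ]
  }
  out
}

eval_loss_chunked <- function(model, images, labels, chunk = 32L) {
  n <- dim(images)[3]
  total <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    total <- total + eval_loss(model, images[, , s:e, drop = FALSE],
                               labels[, , s:e, drop = FALSE]) * (e - s + 1L)
  }
  total / n
}

#' Fivefold cross-validated triplanar training
#'
#' Subjects are split into `n_folds` folds at subject level (all slices of a
#' subject stay on one side, preventing leakage). Each fold trains the
#' shared triplanar U-Net on the pooled axial + sagittal + coronal slices of
#' its training subjects, early-stops on the validation loss, restores the
#' best epoch's weights and records the validation mean IoU (computed over
#' the pooled validation pixels of both classes) as the fold weight `w_f`.
#'
#' @param vols Named list of [labeled_volume()] with masks, on the
#'   segmentation grid.
#' @param unet_cfg A [unet_config()] (its `seed` is re-derived per fold).
#' @param train_cfg A [train_config()].
#' @param norm_stats Optional `normalization_stats` carried in the ensemble
#'   so inference can reuse the training-cohort normalization.
#' @param verbose Print per-epoch progress.
#' @return An `ensemble_model`: list of `n_folds` fold results (`weights`,
#'   `w`, `history`, `val_subjects`, `best_epoch`), the shared
#'   [unet_config()], `norm_stats`, and the training `grid` ([grid_spec()]).
#' @export
train_cv <- function(vols, unet_cfg, train_cfg = train_config(),
                     norm_stats = NULL, verbose = FALSE) {
  stopifnot(inherits(unet_cfg, "unet_config"), inherits(train_cfg, "train_config"))
  if (is.null(names(vols))) names(vols) <- sprintf("subj_%02d", seq_along(vols))
  subjects <- names(vols)
  if (length(subjects) < train_cfg$n_folds)
    stop("fewer subjects than folds")
  d0 <- dim(vols[[1]]$intensity)
  if (d0[1] != unet_cfg$input_size)
    stop("volume grid does not match the network input size")
  grid <- grid_spec(d0[1], vols[[1]]$spacing_mm[1])

  assignment <- with_local_seed(train_cfg$seed, {
    perm <- sample(subjects)
    split(perm, rep_len(seq_len(train_cfg$n_folds), length(perm)))
  })
  fold_seeds <- vapply(seq_len(train_cfg$n_folds),
                       function(f) derive_seed(train_cfg$seed, f), integer(1))

  folds <- vector("list", train_cfg$n_folds)
  for (f in seq_len(train_cfg$n_folds)) {
    val_subjects <- assignment[[f]]
    train_subjects <- setdiff(subjects, val_subjects)
    train_ds <- build_triplanar_dataset(vols[train_subjects])
    val_ds <- build_triplanar_dataset(vols[val_subjects])

    cfg_f <- unet_cfg
    cfg_f$seed <- fold_seeds[f]
    model <- build_unet(cfg_f)

    n_train <- dim(train_ds$images)[3]
    best <- list(loss = Inf, weights = NULL, epoch = 0L, miou = NA_real_)
    history <- vector("list", train_cfg$max_epochs)
    stale <- 0L

    with_local_seed(derive_seed(fold_seeds[f], 1L), {
      for (epoch in seq_len(train_cfg$max_epochs)) {
        order <- sample.int(n_train)
        tr_loss <- 0
        nb <- 0L
        for (s in seq(1L, n_train, by = train_cfg$batch_size)) {
          e <- min(s + train_cfg$batch_size - 1L, n_train)
          idx <- order[s:e]
          tr_loss <- tr_loss + train_batch(model,
                                           train_ds$images[, , idx, drop = FALSE],
                                           train_ds$labels[, , idx, drop = FALSE],
                                           train_cfg$learning_rate)
          nb <- nb + 1L
        }
        tr_loss <- tr_loss / nb
        val_loss <- eval_loss_chunked(model, val_ds$images, val_ds$labels)
        fg <- predict_foreground_chunked(model, val_ds$images)
        val_miou <- mean_iou(array(as.integer(fg > 0.5), dim = dim(fg)),
                             val_ds$labels, unet_cfg$n_classes)
        history[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                       val_loss = val_loss, val_miou = val_miou)
        if (verbose)
          message(sprintf("fold %d epoch %d: train %.4f val %.4f miou %.3f",
                          f, epoch, tr_loss, val_loss, val_miou))
        if (val_loss < best$loss) {
          best <- list(loss = val_loss, weights = unet_weights(model),
                       epoch = epoch, miou = val_miou)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= train_cfg$early_stop_patience) break
        }
      }
    })
    set_unet_weights(model, best$weights)
    folds[[f]] <- structure(list(weights = best$weights, w = best$miou,
                                 history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
                                 val_subjects = val_subjects,
                                 best_epoch = best$epoch,
                                 seed = fold_seeds[f]),
                            class = "fold_result")
  }
  ws <- vapply(folds, function(x) x$w, numeric(1))
  if (any(!is.finite(ws)) || any(ws <= 0))
    stop("fold validation IoU weights must all be positive")
  structure(list(folds = folds, unet_config = unet_cfg, train_config = train_cfg,
                 norm_stats = norm_stats, grid = grid),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d folds, weights: %s; grid %d^3 @ %g mm\n",
              length(x$folds),
              paste(sprintf("%.3f", vapply(x$folds, function(f) f$w, numeric(1))),
                    collapse = ", "),
              x$grid$matrix, x$grid$spacing_mm))
  invisible(x)
}

#' Persist a trained ensemble
#'
#' Writes per-fold training-history CSVs, a JSON manifest (fold weights,
#' seeds, configuration) and a weight checkpoint.
#'
#' @param ens An `ensemble_model`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(ens$folds))
    write.csv(ens$folds[[f]]$history,
              file.path(dir, sprintf("fold%d_history.csv", f)), row.names = FALSE)
  manifest <- list(
    fold_weights = vapply(ens$folds, function(x) x$w, numeric(1)),
    fold_seeds = vapply(ens$folds, function(x) x$seed, integer(1)),
    best_epochs = vapply(ens$folds, function(x) x$best_epoch, integer(1)),
    val_subjects = lapply(ens$folds, function(x) x$val_subjects),
    unet_config = unclass(ens$unet_config),
    train_config = unclass(ens$train_config),
    grid = unclass(ens$grid))
  jsonlite::write_json(manifest, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(ens, file.path(dir, "ensemble.rds"))
  invisible(dir)
}
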