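#' Consensus fusion configuration
#'
#' @param strategy One of `"softmax"` (equal-weight averaging of the three
#'   orientation probability grids, then thresholding), `"union"` (voxel
#'   positive in at least one hardened orientation), `"majority"` (at least
#'   two), `"unanimous"` (all three).
#' @param threshold Hard-prediction threshold `t` in `(0, 1)`; a voxel is
#'   positive iff its probability is `>= t` (ties count as positive).
#' @return An object of class `consensus_config`.
#' @export
consensus_config <- function(strategy = c("softmax", "union", "majority", "unanimous"),
                             threshold = 0.5) {
  strategy <- match.arg(strategy)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(strategy = strategy, threshold = threshold),
            class = "consensus_config")
}

#' Validation-IoU-weighted fold ensemble of probability grids
#'
#' Voxel-wise weighted average `s = sum(w_f * p_f) / sum(w_f)` of the fold
#' probability grids with the fixed fold weights (the validation IoU of each
#' fold).
#'
#' @param fold_probs List of equally shaped probability arrays.
#' @param weights Positive fold weights, one per grid.
#' @return The weighted-average probability array.
#' @export
ensemble_softmax <- function(fold_probs, weights) {
  if (length(fold_probs) != length(weights))
    stop("fold_probs and weights length mismatch")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must all be positive")
  d <- dim(fold_probs[[1]])
  for (p in fold_probs)
    if (!identical(dim(p), d)) stop("fold probability grids differ in shape")
  out <- fold_probs[[1]] * weights[1]
  if (length(fold_probs) > 1)
    for (f in 2:length(fold_probs)) out <- out + fold_probs[[f]] * weights[f]
  out / sum(weights)
}

#' Slice-wise triplanar prediction for one orientation
#'
#' Every 2-D slice of the volume along the given orientation is predicted by
#' all folds of the ensemble; the per-fold foreground probabilities are
#' combined with [ensemble_softmax()] using the fixed validation-IoU
#' weights, and the ensembled slices are restacked into a 3-D
#' foreground-probability grid.
#'
#' @param ens An `ensemble_model` from [train_cv()].
#' @param vol A [labeled_volume()] preprocessed onto the ensemble's
#'   segmentation grid (with the ensemble's stored normalization).
#' @param orientation One of `"axial"`, `"sagittal"`, `"coronal"`.
#' @param net Optional live [build_unet()] handle reused across calls (built
#'   from the ensemble's configuration when `NULL`).
#' @return An `orientation_prediction`: list with `orientation` and `score`
#'   (3-D foreground-probability array).
#' @export
predict_orientation <- function(ens, vol, orientation, net = NULL) {
  stopifnot(inherits(ens, "ensemble_model"), inherits(vol, "labeled_volume"))
  if (!vol_matches_grid(vol, ens$grid))
    stop("volume grid does not match the ensemble's segmentation grid")
  sb <- extract_slices(vol, orientation)
  if (is.null(net)) net <- build_unet(ens$unet_config)
  fold_probs <- lapply(ens$folds, function(f) {
    set_unet_weights(net, f$weights)
    predict_foreground_chunked(net, sb$images)
  })
  weights <- vapply(ens$folds, function(f) f$w, numeric(1))
  score2d <- ensemble_softmax(fold_probs, weights)
  score <- reassemble_slices(score2d, orientation, vol$axis_labels)
  structure(list(orientation = orientation, score = score),
            class = "orientation_prediction")
}

#' Threshold a probability grid into a hard binary mask
#'
#' @param p Probability array (values in `[0, 1]`).
#' @param t Threshold in `(0, 1)`; voxels with `p >= t` are positive.
#' @return Integer binary array of the same shape.
#' @export
harden <- function(p, t = 0.5) {
  if (t <= 0 || t >= 1) stop("threshold must be in (0, 1)")
  array(as.integer(p >= t), dim = if (is.null(dim(p))) length(p) else dim(p))
}

#' Merge the three orientation predictions into a consensus mask
#'
#' `softmax`: the three foreground-probability grids are averaged with equal
#' weights and the mean is thresholded. `union` / `majority` / `unanimous`:
#' each orientation is first hardened at the threshold, then a voxel is
#' positive when at least 1 / at least 2 / all 3 orientations voted for it.
#' On hard (0/1) inputs, softmax averaging with equal weights is equivalent
#' to majority voting; the equivalence does not extend to soft inputs.
#'
#' @param preds List of exactly three `orientation_prediction` objects (or
#'   bare probability arrays) of equal shape.
#' @param cfg A [consensus_config()].
#' @return Integer binary consensus mask.
#' @export
merge_consensus <- function(preds, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"))
  if (length(preds) != 3L) stop("exactly three orientation predictions required")
  scores <- lapply(preds, function(p)
    if (inherits(p, "orientation_prediction")) p$score else p)
  d <- dim(scores[[1]])
  for (s in scores) if (!identical(dim(s), d)) stop("prediction shapes differ")
  if (cfg$strategy == "softmax") {
    harden((scores[[1]] + scores[[2]] + scores[[3]]) / 3, cfg$threshold)
  } else {
    votes <- harden(scores[[1]], cfg$threshold) +
      harden(scores[[2]], cfg$threshold) + harden(scores[[3]], cfg$threshold)
    need <- switch(cfg$strategy, union = 1L, majority = 2L, unanimous = 3L)
    array(as.integer(votes >= need), dim = d)
  }
}

#' Predict one subject with all seven strategies
#'
#' Runs the fold-ensembled slice-wise prediction once per orientation and
#' derives the seven Table-style prediction variants: the three hardened
#' single-orientation masks and the four consensus masks (softmax, union,
#' majority, unanimous).
#'
#' @param ens An `ensemble_model`.
#' @param vol A preprocessed [labeled_volume()] on the ensemble grid.
#' @param threshold Hard-prediction threshold.
#' @return List with `orientations` (the three `orientation_prediction`s)
#'   and `masks` (named list of 7 binary masks).
#' @export
predict_subject <- function(ens, vol, threshold = 0.5) {
  oris <- c("axial", "sagittal", "coronal")
  net <- build_unet(ens$unet_config)
  preds <- lapply(oris, function(o) predict_orientation(ens, vol, o, net = net))
  names(preds) <- oris
  masks <- c(
    lapply(preds, function(p) harden(p$score, threshold)),
    lapply(c("softmax", "union", "majority", "unanimous"), function(s)
      merge_consensus(preds, consensus_config(s, threshold))))
  names(masks) <- c(oris, "softmax", "union", "majority", "unanimous")
  list(orientations = preds, masks = masks)
}

#' Write a subject's consensus prediction to disk
#'
#' Writes the fused binary mask as NIfTI-1 (uint8), optionally the three
#' per-orientation probability grids, and a JSON record of the strategy,
#' threshold and fold weights.
#'
#' @param ens The `ensemble_model` used.
#' @param pred Result of [predict_subject()].
#' @param cfg A [consensus_config()] naming the fused mask to write.
#' @param prefix Output path prefix.
#' @param probabilities Also write the per-orientation probability grids.
#' @return Invisibly, the paths written.
#' @export
write_prediction <- function(ens, pred, cfg, prefix, probabilities = FALSE) {
  spacing <- rep(ens$grid$spacing_mm, 3)
  mask <- pred$masks[[cfg$strategy]]
  img <- RNifti::asNifti(structure(array(as.integer(mask), dim = dim(mask)),
                                   pixdim = spacing), datatype = "uint8")
  mpath <- paste0(prefix, "_", cfg$strategy, ".nii")
  RNifti::writeNifti(img, mpath)
  paths <- mpath
  if (probabilities) {
    for (o in names(pred$orientations)) {
      p <- RNifti::asNifti(structure(pred$orientations[[o]]$score,
                                     pixdim = spacing))
      ppath <- paste0(prefix, "_prob_", o, ".nii")
      RNifti::writeNifti(p, ppath)
      paths <- c(paths, ppath)
    }
  }
  jpath <- paste0(prefix, "_prediction.json")
  jsonlite::write_json(list(strategy = cfg$strategy, threshold = cfg$threshold,
                            fold_weights = vapply(ens$folds, function(f) f$w,
                                                  numeric(1))),
                       jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jpath))
}
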