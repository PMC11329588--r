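#' Voxel-level confusion counts
#'
#' @param pred,truth Binary arrays (values 0/1) of identical shape.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`; the four counts always sum to the number of voxels of the
#'   evaluation grid.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth) || !identical(dim(pred), dim(truth)))
    stop("shape mismatch between prediction and truth")
  check_binary(pred); check_binary(truth)
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

check_binary <- function(x) {
  if (!all(x == 0L | x == 1L)) stop("mask must be binary (0/1)")
  invisible(x)
}

#' Segmentation metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, Dice (= F1)
#' `2 TP/(2 TP+FP+FN)` and foreground IoU `TP/(TP+FP+FN)`. Metrics with an
#' undefined (zero) denominator are reported as `NA`, not coerced to 0, so
#' cohort averages stay honest.
#'
#' @param counts A [confusion()] result.
#' @return An object of class `metrics_report` with `precision`, `recall`,
#'   `dice`, `foreground_iou`.
#' @export
seg_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, structure(list(
    precision = rat(TP, TP + FP),
    recall = rat(TP, TP + FN),
    dice = rat(2 * TP, 2 * TP + FP + FN),
    foreground_iou = rat(TP, TP + FP + FN)),
    class = "metrics_report"))
}

#' Tongue volume of a binary mask
#'
#' Positive-voxel count times voxel volume, reported in cubic centimetres.
#'
#' @param mask Binary array, or a [labeled_volume()] (its mask is used).
#' @param spacing_mm Voxel spacing (scalar or length 3); taken from the
#'   volume when a [labeled_volume()] is given.
#' @return Volume in cm^3.
#' @export
tongue_volume <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "labeled_volume")) {
    spacing_mm <- mask$spacing_mm
    mask <- mask$mask
  }
  if (is.null(spacing_mm) || any(spacing_mm <= 0)) stop("positive spacing required")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  check_binary(mask)
  sum(mask == 1L) * prod(spacing_mm) / 1000
}

#' Colour-coded overlay of prediction vs truth on a grayscale slice
#'
#' True positives are painted magenta, false positives blue and false
#' negatives yellow over the grayscale intensity slice, so the coloured
#' pixel counts equal the slice's confusion counts exactly.
#'
#' @param pred,truth Binary matrices (one slice each).
#' @param intensity Numeric matrix with the underlying image slice.
#' @return An `(H, W, 3)` RGB array in `[0, 1]`.
#' @export
overlay_slice <- function(pred, truth, intensity) {
  if (!identical(dim(pred), dim(truth)) || !identical(dim(pred), dim(intensity)))
    stop("shape mismatch")
  check_binary(pred); check_binary(truth)
  rng <- range(intensity)
  gray <- if (diff(rng) > 0) (intensity - rng[1]) / diff(rng) else
    matrix(0.5, nrow(intensity), ncol(intensity))
  img <- array(rep(gray, 3), dim = c(dim(gray), 3))
  p <- pred == 1L; t <- truth == 1L
  paint <- function(img, sel, rgb) {
    for (k in 1:3) {
      ch <- img[, , k]; ch[sel] <- rgb[k]; img[, , k] <- ch
    }
    img
  }
  img <- paint(img, p & t, c(1, 0, 1))    # TP magenta
  img <- paint(img, p & !t, c(0, 0, 1))   # FP blue
  img <- paint(img, !p & t, c(1, 1, 0))   # FN yellow
  img
}

#' Write an overlay image as PNG
#'
#' @param img RGB array from [overlay_slice()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_overlay_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG overlays")
  png::writePNG(img, path)
  invisible(path)
}

new_group_comparison <- function(test_name, normality_p, statistic, p_value,
                                 means, sds, n, alpha = 0.05) {
  structure(list(test_name = test_name, normality_p = normality_p,
                 statistic = statistic, p_value = p_value,
                 means = means, sds = sds, n = n,
                 significant = isTRUE(is.finite(p_value) && p_value < alpha)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g%s\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) " (significant at 0.05)" else ""))
  cat(sprintf("  means: %s; sds: %s\n",
              paste(sprintf("%.2f", x$means), collapse = " vs "),
              paste(sprintf("%.2f", x$sds), collapse = " vs ")))
  invisible(x)
}

#' Paired comparison of predicted vs ground-truth volumes
#'
#' Shapiro-Wilk normality test on the paired differences at 0.05: if normal,
#' a paired Student's t test; otherwise a Wilcoxon signed-rank test (the
#' non-normal fallback is a documented extension of the reference protocol,
#' which states only the paired t path). Zero-variance differences are a
#' degenerate case reported as no difference.
#'
#' @param volumes_pred,volumes_truth Equal-length numeric vectors (>= 3).
#' @return A `group_comparison`.
#' @export
compare_paired <- function(volumes_pred, volumes_truth) {
  if (length(volumes_pred) != length(volumes_truth)) stop("length mismatch")
  if (length(volumes_pred) < 3L) stop("at least 3 pairs required")
  d <- volumes_pred - volumes_truth
  ms <- c(pred = mean(volumes_pred), truth = mean(volumes_truth))
  ss <- c(pred = sd(volumes_pred), truth = sd(volumes_truth))
  if (sd(d) < 1e-12) {
    return(new_group_comparison("none (zero-variance differences)", NA_real_,
                                0, if (all(abs(d) < 1e-12)) 1 else NA_real_,
                                ms, ss, length(d)))
  }
  swp <- shapiro.test(d)$p.value
  if (swp >= 0.05) {
    tt <- t.test(volumes_pred, volumes_truth, paired = TRUE)
    new_group_comparison("paired t", swp, unname(tt$statistic), tt$p.value,
                         ms, ss, length(d))
  } else {
    wt <- wilcox.test(volumes_pred, volumes_truth, paired = TRUE, exact = FALSE)
    new_group_comparison("Wilcoxon signed-rank", swp, unname(wt$statistic),
                         wt$p.value, ms, ss, length(d))
  }
}

#' Two-group comparison of volumes
#'
#' Shapiro-Wilk per group at 0.05: if both groups are compatible with
#' normality, an unpaired Student's t test (pooled variance); otherwise a
#' Mann-Whitney U rank test. Group means and standard deviations are
#' reported alongside the test.
#'
#' @param volumes_a,volumes_b Numeric vectors (>= 3 each).
#' @param labels Group names used for the reported means/sds.
#' @return A `group_comparison`.
#' @export
compare_groups <- function(volumes_a, volumes_b, labels = c("a", "b")) {
  if (length(volumes_a) < 3L || length(volumes_b) < 3L)
    stop("each group needs at least 3 values")
  swa <- shapiro.test(volumes_a)$p.value
  swb <- shapiro.test(volumes_b)$p.value
  ms <- stats::setNames(c(mean(volumes_a), mean(volumes_b)), labels)
  ss <- stats::setNames(c(sd(volumes_a), sd(volumes_b)), labels)
  n <- stats::setNames(c(length(volumes_a), length(volumes_b)), labels)
  if (swa >= 0.05 && swb >= 0.05) {
    tt <- t.test(volumes_a, volumes_b, var.equal = TRUE)
    new_group_comparison("unpaired t", c(swa, swb), unname(tt$statistic),
                         tt$p.value, ms, ss, n)
  } else {
    wt <- wilcox.test(volumes_a, volumes_b, exact = FALSE)
    new_group_comparison("Mann-Whitney U", c(swa, swb), unname(wt$statistic),
                         wt$p.value, ms, ss, n)
  }
}

#' Per-subject, per-strategy metric rows
#'
#' Convenience wrapper evaluating the seven masks of [predict_subject()]
#' against the truth mask of one subject.
#'
#' @param masks Named list of binary masks (e.g. `predict_subject()$masks`).
#' @param truth Binary truth mask.
#' @param spacing_mm Voxel spacing for volume computation.
#' @param subject Subject id recorded in the rows.
#' @return Data frame: one row per strategy with confusion counts, metrics
#'   and predicted volume in cm^3.
#' @export
evaluate_masks <- function(masks, truth, spacing_mm, subject = NA_character_) {
  rows <- lapply(names(masks), function(s) {
    cc <- confusion(masks[[s]], truth)
    m <- seg_metrics(cc)
    data.frame(subject = subject, strategy = s,
               TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               precision = m$precision, recall = m$recall, dice = m$dice,
               foreground_iou = m$foreground_iou,
               volume_cm3 = tongue_volume(masks[[s]], spacing_mm))
  })
  do.call(rbind, rows)
}

strategy_order <- c("axial", "sagittal", "coronal", "softmax", "union",
                    "majority", "unanimous")

#' Strategy-by-metric summary table
#'
#' Aggregates per-subject rows (as produced by [evaluate_masks()]) into a
#' mean +/- sd summary per strategy, reported as per-subject-metric means
#' (not metrics of pooled counts — the two aggregations differ in general).
#'
#' @param rows Data frame of per-subject per-strategy rows; every strategy
#'   must cover the same subject set.
#' @param path Optional CSV output path.
#' @return Data frame: one row per strategy with `<metric>_mean` and
#'   `<metric>_sd` columns.
#' @export
table1_report <- function(rows, path = NULL) {
  needed <- c("subject", "strategy", "TP", "TN", "FP", "FN",
              "precision", "recall", "dice")
  if (!all(needed %in% names(rows))) stop("missing columns in metric rows")
  subj_sets <- tapply(rows$subject, rows$strategy, function(x) paste(sort(x), collapse = "|"))
  if (length(unique(subj_sets)) != 1L)
    stop("inconsistent subject sets across strategies")
  strategies <- intersect(strategy_order, unique(rows$strategy))
  strategies <- c(strategies, setdiff(unique(rows$strategy), strategies))
  metrics <- c("TP", "TN", "FP", "FN", "precision", "recall", "dice",
               if ("volume_cm3" %in% names(rows)) "volume_cm3")
  out <- lapply(strategies, function(s) {
    sub <- rows[rows$strategy == s, , drop = FALSE]
    row <- data.frame(strategy = s)
    for (m in metrics) {
      v <- sub[[m]]
      row[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- if (nrow(sub) > 1) sd(v, na.rm = TRUE) else 0
    }
    row
  })
  out <- do.call(rbind, out)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Serialize a group comparison as JSON
#'
#' @param cmp A `group_comparison`.
#' @param path JSON output path.
#' @return Invisibly, `path`.
#' @export
write_comparison_json <- function(cmp, path) {
  jsonlite::write_json(unclass(cmp), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
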