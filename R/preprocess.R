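#' Cubic grid specification
#'
#' A cubic voxel grid defined by its matrix size and isotropic voxel spacing.
#' Two canonical instances are used throughout the pipeline: the working grid
#' (256^3 voxels at 1.0 mm) on which reorientation and intensity
#' normalization happen, and the segmentation grid (256^3 voxels at 0.5 mm)
#' covering the central half of the working field of view at doubled
#' resolution.
#'
#' @param matrix Voxels per axis.
#' @param spacing_mm Isotropic voxel edge length in mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(matrix = 256, spacing_mm = 1) {
  if (length(matrix) != 1L || matrix < 2) stop("matrix must be a single value >= 2")
  if (length(spacing_mm) != 1L || spacing_mm <= 0) stop("spacing_mm must be positive")
  structure(list(matrix = as.integer(matrix), spacing_mm = as.numeric(spacing_mm)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @export
working_grid <- function() grid_spec(256, 1)

#' @rdname grid_spec
#' @export
segmentation_grid <- function() grid_spec(256, 0.5)

grid_extent_mm <- function(g) g$matrix * g$spacing_mm

vol_matches_grid <- function(vol, g) {
  all(dim(vol$intensity) == g$matrix) &&
    all(abs(vol$spacing_mm - g$spacing_mm) < 1e-9)
}

#' Resample a volume to an isotropic cubic grid
#'
#' Tri-linear interpolation with center-aligned fields of view: the physical
#' center of the input is mapped to the physical center of the target grid,
#' so the field of view is preserved (or symmetrically padded with `fill`)
#' regardless of input anisotropy. The mask is interpolated like the
#' intensity and re-binarized at 0.5 (ties count as foreground).
#'
#' @param vol A [labeled_volume()] with known spacing.
#' @param target A [grid_spec()].
#' @param fill Background value used outside the input field of view.
#' @return A [labeled_volume()] on the target grid.
#' @export
resample_isotropic <- function(vol, target, fill = 0) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(target, "grid_spec"))
  if (target$spacing_mm <= 0) stop("target spacing must be positive")
  if (vol_matches_grid(vol, target)) return(vol)
  dim_out <- rep(target$matrix, 3L)
  sp_out <- rep(target$spacing_mm, 3L)
  intensity <- resample_trilinear_cpp(as.numeric(vol$intensity), dim(vol$intensity),
                                      vol$spacing_mm, dim_out, sp_out, fill)
  mask <- NULL
  if (!is.null(vol$mask)) {
    m <- resample_trilinear_cpp(as.numeric(vol$mask), dim(vol$mask),
                                vol$spacing_mm, dim_out, sp_out, 0)
    mask <- array(as.integer(m >= 0.5), dim = dim_out)
  }
  labeled_volume(intensity, mask, spacing_mm = target$spacing_mm,
                 axis_labels = vol$axis_labels)
}

#' Center a volume on an anatomical landmark
#'
#' Translates the volume by an integer number of voxels so that the supplied
#' landmark (e.g. the palatal tip, or a phantom's mask centroid) lands on the
#' matrix center voxel `floor(dim / 2) + 1`. If `vol$axis_labels` is a
#' permutation of the canonical order (AP, LR, IS), axes are permuted to the
#' canonical order first. Voxels shifted in from outside take `fill`.
#'
#' @param vol A [labeled_volume()].
#' @param landmark Length-3 integer voxel coordinate (1-based) of the
#'   landmark, in the volume's current axis order.
#' @param fill Background fill value for the intensity channel.
#' @return The recentered [labeled_volume()].
#' @export
reorient_center <- function(vol, landmark, fill = 0) {
  stopifnot(inherits(vol, "labeled_volume"))
  landmark <- as.integer(round(landmark))
  d <- dim(vol$intensity)
  if (length(landmark) != 3L || any(landmark < 1L) || any(landmark > d))
    stop("landmark outside grid")
  canonical <- c("AP", "LR", "IS")
  if (!identical(vol$axis_labels, canonical)) {
    perm <- match(canonical, vol$axis_labels)
    if (any(is.na(perm)))
      stop("axis_labels must be a permutation of AP, LR, IS")
    vol$intensity <- aperm(vol$intensity, perm)
    if (!is.null(vol$mask)) vol$mask <- aperm(vol$mask, perm)
    vol$spacing_mm <- vol$spacing_mm[perm]
    vol$axis_labels <- canonical
    landmark <- landmark[perm]
    d <- dim(vol$intensity)
  }
  center <- d %/% 2L + 1L
  shift <- center - landmark
  if (all(shift == 0L)) return(vol)
  vol$intensity <- shift_array(vol$intensity, shift, fill)
  if (!is.null(vol$mask))
    vol$mask <- array(as.integer(shift_array(vol$mask, shift, 0L)), dim = d)
  vol
}

shift_array <- function(a, shift, fill) {
  d <- dim(a)
  out <- array(fill, d)
  dst <- lapply(1:3, function(ax) max(1L, 1L + shift[ax]):min(d[ax], d[ax] + shift[ax]))
  src <- lapply(1:3, function(ax) dst[[ax]] - shift[ax])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Mask centroid in voxel coordinates
#'
#' @param vol A [labeled_volume()] with a mask.
#' @return Length-3 numeric centroid (1-based voxel coordinates).
#' @export
mask_centroid <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"), !is.null(vol$mask))
  idx <- which(vol$mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  colMeans(idx)
}

#' Cohort-level intensity normalization statistics
#'
#' For each subject, the mean intensity over a fixed tongue-centered central
#' region of interest (ROI, canonically 128^3 voxels at 1 mm) is computed;
#' the cohort mean M and sample standard deviation S (n - 1 denominator) of
#' those per-subject means define the z-score normalization applied
#' identically to every subject.
#'
#' @param vols List of [labeled_volume()] on a common working grid, already
#'   centered on the tongue.
#' @param roi A [grid_spec()] giving the ROI extent (default 128^3 at 1 mm).
#' @return An object of class `normalization_stats` with fields
#'   `per_subject_roi_means`, `M`, `S` and `roi_shape`.
#' @export
compute_cohort_stats <- function(vols, roi = grid_spec(128, 1)) {
  if (length(vols) < 2L) stop("at least 2 subjects are required (S undefined)")
  d <- dim(vols[[1]]$intensity)
  sp <- vols[[1]]$spacing_mm
  for (v in vols) {
    if (!identical(dim(v$intensity), d) || any(abs(v$spacing_mm - sp) > 1e-9))
      stop("all volumes must share one working grid")
  }
  roi_vox <- round(grid_extent_mm(roi) / sp)
  if (any(roi_vox > d)) stop("ROI extent exceeds the volume grid")
  start <- (d - roi_vox) %/% 2L + 1L
  idx <- lapply(1:3, function(ax) start[ax]:(start[ax] + roi_vox[ax] - 1L))
  means <- vapply(vols, function(v)
    mean(v$intensity[idx[[1]], idx[[2]], idx[[3]]]), numeric(1))
  M <- mean(means)
  S <- sd(means)
  if (!is.finite(S) || S <= 1e-12)
    stop("cohort standard deviation of ROI means is zero; normalization undefined")
  structure(list(per_subject_roi_means = unname(means), M = M, S = S,
                 roi_shape = roi_vox),
            class = "normalization_stats")
}

#' Apply cohort z-score normalization
#'
#' Every voxel x is mapped to (x - M) / S with the cohort statistics of
#' [compute_cohort_stats()]; the mask is unchanged.
#'
#' @param vol A [labeled_volume()].
#' @param stats A `normalization_stats` object.
#' @return The normalized [labeled_volume()].
#' @export
znormalize <- function(vol, stats) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(stats, "normalization_stats"))
  if (!is.finite(stats$S) || stats$S <= 0) stop("S must be positive")
  vol$intensity <- (vol$intensity - stats$M) / stats$S
  vol
}

#' Persist / restore normalization statistics as JSON
#'
#' @param stats A `normalization_stats` object.
#' @param path JSON file path.
#' @return `write_normalization_stats` returns the path invisibly;
#'   `read_normalization_stats` returns the restored object.
#' @export
write_normalization_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization_stats
#' @export
read_normalization_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_subject_roi_means = as.numeric(x$per_subject_roi_means),
                 M = as.numeric(x$M), S = as.numeric(x$S),
                 roi_shape = as.integer(x$roi_shape)),
            class = "normalization_stats")
}

#' Crop-and-upsample to the segmentation grid
#'
#' Extracts the central region of the working-grid volume whose physical
#' extent equals the segmentation grid's (canonically a 128 mm cube) and
#' resamples it to the segmentation grid. With both canonical grids this
#' doubles the resolution of the central half of the field of view. The
#' inverse mapping is available via [from_segmentation_grid()].
#'
#' @param vol A centered working-grid [labeled_volume()].
#' @param seg Target [grid_spec()] (default the canonical 256^3 at 0.5 mm).
#' @return A [labeled_volume()] on the segmentation grid.
#' @export
to_segmentation_grid <- function(vol, seg = segmentation_grid()) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(seg, "grid_spec"))
  vol_extent <- dim(vol$intensity) * vol$spacing_mm
  if (grid_extent_mm(seg) > min(vol_extent) + 1e-9)
    stop("segmentation extent exceeds working extent")
  resample_isotropic(vol, seg)
}

#' Map a segmentation-grid mask back to the working grid
#'
#' Inverse of [to_segmentation_grid()]: the mask is resampled back onto the
#' working grid (zeros outside the segmentation field of view), so predicted
#' masks can be reported in working-grid physical coordinates.
#'
#' @param mask_vol A [labeled_volume()] on the segmentation grid whose mask
#'   (or intensity, if no mask) is to be mapped back.
#' @param working Target [grid_spec()].
#' @return A [labeled_volume()] on the working grid.
#' @export
from_segmentation_grid <- function(mask_vol, working = working_grid()) {
  resample_isotropic(mask_vol, working, fill = 0)
}
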