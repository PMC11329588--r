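#' Labeled volumetric image
#'
#' Container for a 3-D scalar intensity grid with voxel spacing, anatomical
#' axis labels and an optional binary truth mask. Axes follow the fixed
#' anatomical order anterior-posterior (AP), left-right (LR),
#' inferior-superior (IS).
#'
#' @param intensity 3-D numeric array.
#' @param mask Optional 3-D binary array (0 = background, 1 = foreground) with
#'   the same dimensions as `intensity`.
#' @param spacing_mm Voxel edge lengths in millimetres; a scalar (isotropic)
#'   or length-3 vector.
#' @param axis_labels Character vector naming the anatomical direction of each
#'   grid axis; default `c("AP", "LR", "IS")`.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(intensity, mask = NULL, spacing_mm = 1,
                           axis_labels = c("AP", "LR", "IS")) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("intensity must be a 3-D array")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be positive (scalar or length 3)")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(intensity)))
      stop("mask and intensity dimensions differ")
    vals <- unique(as.vector(mask))
    if (!all(vals %in% c(0, 1)))
      stop("mask values must be 0 or 1")
    storage.mode(mask) <- "integer"
  }
  if (length(axis_labels) != 3L)
    stop("axis_labels must have length 3")
  structure(list(intensity = intensity, mask = mask,
                 spacing_mm = as.numeric(spacing_mm),
                 axis_labels = axis_labels),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<labeled_volume> %d x %d x %d @ (%g, %g, %g) mm [%s]%s\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              paste(x$axis_labels, collapse = ","),
              if (is.null(x$mask)) "" else sprintf(", mask: %d voxels", sum(x$mask))))
  invisible(x)
}

#' Write a labeled volume as NIfTI-1 files
#'
#' Writes `<prefix>.nii` (intensity) and, when a mask is present,
#' `<prefix>_mask.nii` (uint8), with the voxel spacing on the affine diagonal.
#'
#' @param vol A [labeled_volume()].
#' @param prefix Output path prefix (directories must exist).
#' @param compress Write `.nii.gz` instead of plain `.nii`.
#' @return Invisibly, the paths written.
#' @export
write_labeled_volume <- function(vol, prefix, compress = FALSE) {
  stopifnot(inherits(vol, "labeled_volume"))
  ext <- if (compress) ".nii.gz" else ".nii"
  ipath <- paste0(prefix, ext)
  img <- RNifti::asNifti(structure(vol$intensity, pixdim = vol$spacing_mm))
  RNifti::writeNifti(img, ipath)
  paths <- ipath
  if (!is.null(vol$mask)) {
    mpath <- paste0(prefix, "_mask", ext)
    m <- RNifti::asNifti(structure(vol$mask, pixdim = vol$spacing_mm),
                         datatype = "uint8")
    RNifti::writeNifti(m, mpath)
    paths <- c(paths, mpath)
  }
  invisible(paths)
}

#' Read a labeled volume from NIfTI-1 files
#'
#' @param intensity_path Path to the intensity image.
#' @param mask_path Optional path to the binary mask image.
#' @param axis_labels Anatomical axis labels of the stored grid.
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(intensity_path, mask_path = NULL,
                                axis_labels = c("AP", "LR", "IS")) {
  img <- RNifti::readNifti(intensity_path)
  spacing <- attr(img, "pixdim")[1:3]
  arr <- array(as.numeric(img), dim = dim(img))
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.integer(m > 0.5), dim = dim(m))
  }
  labeled_volume(arr, mask, spacing_mm = spacing, axis_labels = axis_labels)
}
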