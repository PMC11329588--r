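#' Synthetic head/tongue phantom specification
#'
#' Describes a synthetic T1-like head volume containing a bright, smoothly
#' deformed ellipsoidal "tongue" with an exact voxel ground-truth mask,
#' surrounded by distractor soft-tissue blobs of near-tongue intensity.
#' Default tongue semi-axes follow the anatomical slice coverage of adult
#' tongues (extents of about 71.5 mm anterior-posterior, 47.5 mm left-right
#' and 60 mm inferior-superior), giving an analytic volume of about
#' 106.7 cm^3.
#'
#' @param grid_shape Voxels per axis (cubic grid).
#' @param spacing_mm Isotropic voxel edge length in mm.
#' @param tongue_semiaxes_mm Three semi-axis lengths in mm, in axis order
#'   (AP, LR, IS).
#' @param deform_amplitude Unitless strength of the smooth low-frequency
#'   radial boundary perturbation (0 = perfect ellipsoid).
#' @param tongue_intensity,background_intensity,distractor_intensity Mean
#'   intensities in arbitrary MR-like units.
#' @param noise_sigma Additive Gaussian noise standard deviation (>= 0).
#' @param volume_scale Multiplicative factor applied to all semi-axes;
#'   models atrophy (volume scales with its cube).
#' @param n_distractors Number of distractor blobs abutting the tongue
#'   (drawn uniformly from this range).
#' @param seed Integer seed making the phantom fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = 64, spacing_mm = 2,
                         tongue_semiaxes_mm = c(35.75, 23.75, 30.0),
                         deform_amplitude = 0.05,
                         tongue_intensity = 100, background_intensity = 20,
                         distractor_intensity = 85, noise_sigma = 5,
                         volume_scale = 1, n_distractors = c(2L, 4L),
                         seed = 1L) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         spacing_mm = spacing_mm,
                         tongue_semiaxes_mm = tongue_semiaxes_mm,
                         deform_amplitude = deform_amplitude,
                         tongue_intensity = tongue_intensity,
                         background_intensity = background_intensity,
                         distractor_intensity = distractor_intensity,
                         noise_sigma = noise_sigma,
                         volume_scale = volume_scale,
                         n_distractors = as.integer(n_distractors),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 1L || spec$grid_shape < 8L)
    stop("grid_shape must be a single value >= 8")
  if (spec$spacing_mm <= 0) stop("spacing_mm must be positive")
  if (length(spec$tongue_semiaxes_mm) != 3L || any(spec$tongue_semiaxes_mm <= 0))
    stop("tongue_semiaxes_mm must be three strictly positive lengths")
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.finite(spec$volume_scale) || spec$volume_scale <= 0)
    stop("volume_scale must be strictly positive (a zero scale is a degenerate tongue)")
  if (spec$deform_amplitude < 0 || spec$deform_amplitude >= 0.5)
    stop("deform_amplitude must be in [0, 0.5)")
  # worst-case deformed boundary must fit inside the grid
  extent <- spec$grid_shape * spec$spacing_mm
  reach <- 2 * spec$tongue_semiaxes_mm * spec$volume_scale * (1 + spec$deform_amplitude)
  if (any(reach > extent))
    stop(sprintf(paste0("tongue exceeds grid: scaled tongue extent (%.1f mm) ",
                        "larger than grid extent (%.1f mm)"),
                 max(reach), extent))
  invisible(spec)
}

#' Analytic tongue volume of a phantom specification
#'
#' Volume of the undeformed scaled ellipsoid, `4/3 * pi * a * b * c`, in
#' cubic centimetres. The smooth boundary deformation is volume-neutral to
#' first order, so this is also the expected volume of a deformed phantom.
#'
#' @param spec A [phantom_spec()].
#' @return Volume in cm^3.
#' @export
phantom_analytic_volume <- function(spec) {
  ax <- spec$tongue_semiaxes_mm * spec$volume_scale
  4 / 3 * pi * prod(ax) / 1000
}

# Low-frequency zero-spherical-mean angular basis used for the boundary
# deformation (degree-2 real harmonics up to normalization).
deform_field <- function(dx, dy, dz, coefs) {
  (coefs[1] * dx * dy + coefs[2] * dx * dz + coefs[3] * dy * dz +
     coefs[4] * (dx^2 - dy^2) + coefs[5] * (dy^2 - dz^2) +
     coefs[6] * (3 * dz^2 - 1) / 2) / sqrt(6)
}

# Ellipsoid boundary radius along the unit direction u, semi-axes ax.
ellipsoid_radius <- function(u, ax) 1 / sqrt(sum((u / ax)^2))

#' Generate a synthetic head/tongue phantom
#'
#' Deterministically (per seed) voxelizes a smoothly deformed ellipsoid
#' centered in the grid as the ground-truth tongue mask, paints the tongue
#' and 2-4 adjacent non-overlapping distractor blobs of near-tongue
#' intensity over a uniform background, and adds Gaussian noise. The mask is
#' computed before noise is applied, so it is exact and independent of
#' `noise_sigma`.
#'
#' @param spec A [phantom_spec()].
#' @param mask_only If `TRUE`, skip intensity synthesis (fast path when only
#'   the truth mask or true volume is needed).
#' @return A [labeled_volume()] with the truth mask; the realized tongue
#'   volume in cm^3 is attached as attribute `true_volume_cm3`.
#' @export
generate_phantom <- function(spec, mask_only = FALSE) {
  validate_phantom_spec(spec)
  n <- spec$grid_shape
  sp <- spec$spacing_mm
  ax <- spec$tongue_semiaxes_mm * spec$volume_scale

  with_local_seed(spec$seed, {
    coefs <- rnorm(6)

    coord <- (seq_len(n) - (n + 1) / 2) * sp
    ux <- array(coord / ax[1], dim = c(n, n, n))
    uy <- aperm(array(coord / ax[2], dim = c(n, n, n)), c(2, 1, 3))
    uz <- aperm(array(coord / ax[3], dim = c(n, n, n)), c(3, 2, 1))
    rho <- sqrt(ux^2 + uy^2 + uz^2)
    rho_safe <- pmax(rho, 1e-12)
    boundary <- 1 + spec$deform_amplitude *
      deform_field(ux / rho_safe, uy / rho_safe, uz / rho_safe, coefs)
    mask <- array(as.integer(rho <= boundary), dim = c(n, n, n))
    rm(ux, uy, uz, rho, rho_safe, boundary)

    if (mask_only) {
      vol <- labeled_volume(array(0, dim = c(n, n, n)), mask, spacing_mm = sp)
    } else {
      intensity <- array(spec$background_intensity, dim = c(n, n, n))
      intensity[mask == 1L] <- spec$tongue_intensity

      nd_range <- range(spec$n_distractors)
      nd <- if (nd_range[1] == nd_range[2]) nd_range[1] else
        sample(seq(nd_range[1], nd_range[2]), 1L)
      for (k in seq_len(nd)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        dax <- runif(3, 0.15, 0.35) * max(ax)
        r_t <- ellipsoid_radius(u, ax) * (1 + spec$deform_amplitude)
        r_d <- ellipsoid_radius(u, dax)
        center <- u * (r_t + r_d + sp)
        dx <- array(coord, dim = c(n, n, n)) - center[1]
        dy <- aperm(array(coord, dim = c(n, n, n)), c(2, 1, 3)) - center[2]
        dz <- aperm(array(coord, dim = c(n, n, n)), c(3, 2, 1)) - center[3]
        dmask <- (dx / dax[1])^2 + (dy / dax[2])^2 + (dz / dax[3])^2 <= 1
        sel <- dmask & mask == 0L
        intensity[sel] <- spec$distractor_intensity
        rm(dx, dy, dz, dmask, sel)
      }
      noise <- rnorm(length(intensity), 0, 1) * spec$noise_sigma
      intensity <- intensity + array(noise, dim = dim(intensity))
      vol <- labeled_volume(intensity, mask, spacing_mm = sp)
    }
    attr(vol, "true_volume_cm3") <- sum(mask) * sp^3 / 1000
    vol
  })
}

#' Synthetic cohort specification
#'
#' Describes one or more subject groups drawn from a shared phantom template,
#' each group with its own `volume_scale` distribution. The defaults emulate
#' a two-group tongue-atrophy study: 19 controls with tongue volumes of about
#' 106 +/- 8 cm^3 and 19 atrophic patients with 91 +/- 16 cm^3.
#'
#' @param groups A data frame with columns `group` (name), `n` (subjects),
#'   `scale_mean` and `scale_sd` (volume_scale distribution). If `NULL`, the
#'   two-group default above is built from `template` via
#'   [volume_to_scale()].
#' @param template A [phantom_spec()] shared by all subjects.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL, template = phantom_spec(), seed = 1L) {
  if (is.null(groups)) {
    ctrl <- volume_to_scale(106, 8, template)
    pat <- volume_to_scale(91, 16, template)
    groups <- data.frame(group = c("control", "patient"), n = c(19L, 19L),
                         scale_mean = c(ctrl[["mean"]], pat[["mean"]]),
                         scale_sd = c(ctrl[["sd"]], pat[["sd"]]))
  }
  stopifnot(is.data.frame(groups),
            all(c("group", "n", "scale_mean", "scale_sd") %in% names(groups)))
  if (any(groups$n < 2L))
    stop("each group needs at least 2 subjects")
  if (any(groups$scale_mean <= 0) || any(groups$scale_sd < 0))
    stop("scale means must be positive and sds non-negative")
  structure(list(groups = groups, template = template, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Convert a target volume distribution to a volume_scale distribution
#'
#' Maps a target tongue volume mean and standard deviation (cm^3) to the
#' `volume_scale` mean and sd that reproduce them for a given template, using
#' the cube-root relation `scale = (V / V0)^(1/3)` and the delta method for
#' the sd.
#'
#' @param mean_cm3,sd_cm3 Target volume mean and sd in cm^3.
#' @param template A [phantom_spec()] providing the base volume `V0`.
#' @return Named numeric vector with elements `mean` and `sd`.
#' @export
volume_to_scale <- function(mean_cm3, sd_cm3, template = phantom_spec()) {
  v0 <- phantom_analytic_volume(template) / template$volume_scale^3
  m <- (mean_cm3 / v0)^(1 / 3)
  c(mean = m, sd = m * (sd_cm3 / mean_cm3) / 3)
}

#' Generate a synthetic cohort of phantoms
#'
#' Per-subject seeds and scale deviates are derived from the master seed and
#' the within-group subject index only, so two groups with identical scale
#' distributions produce pairwise matched subjects (common random numbers
#' across groups).
#'
#' @param cohort A [cohort_spec()].
#' @param volumes If `FALSE`, only the manifest (with true volumes from the
#'   voxelized masks) is returned; intensity volumes are not synthesized.
#' @param mask_only Passed to [generate_phantom()] when `volumes = TRUE`.
#' @return A list with `volumes` (named list of [labeled_volume()], or `NULL`)
#'   and `manifest` (data frame: subject, group, seed, volume_scale,
#'   true_volume_cm3).
#' @export
generate_cohort <- function(cohort, volumes = TRUE, mask_only = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  rows <- list(); vols <- list()
  for (g in seq_len(nrow(cohort$groups))) {
    grp <- cohort$groups[g, ]
    for (i in seq_len(grp$n)) {
      sseed <- derive_seed(cohort$seed, i)
      z <- with_local_seed(sseed, rnorm(1))
      scale <- grp$scale_mean + grp$scale_sd * z
      if (scale <= 0)
        stop("drawn volume_scale not positive; group scale distribution too wide")
      spec_i <- cohort$template
      spec_i$volume_scale <- scale
      spec_i$seed <- derive_seed(sseed, 2L)
      validate_phantom_spec(spec_i)
      sid <- sprintf("%s_%02d", grp$group, i)
      if (volumes) {
        vol <- generate_phantom(spec_i, mask_only = mask_only)
        vols[[sid]] <- vol
        tv <- attr(vol, "true_volume_cm3")
      } else {
        tv <- attr(generate_phantom(spec_i, mask_only = TRUE), "true_volume_cm3")
      }
      rows[[length(rows) + 1L]] <-
        data.frame(subject = sid, group = grp$group, seed = spec_i$seed,
                   volume_scale = scale, true_volume_cm3 = tv)
    }
  }
  manifest <- do.call(rbind, rows)
  list(volumes = if (volumes) vols else NULL, manifest = manifest)
}

#' Write a generated cohort to disk
#'
#' Writes one NIfTI-1 intensity/mask pair per subject plus a `manifest.csv`
#' recording subject id, group, seed, drawn scale and true volume in cm^3.
#'
#' @param cohort_data Result of [generate_cohort()] (with volumes).
#' @param dir Output directory (created if missing).
#' @param compress Write `.nii.gz` instead of `.nii`.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort_data, dir, compress = FALSE) {
  if (is.null(cohort_data$volumes))
    stop("cohort was generated without volumes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort_data$volumes))
    write_labeled_volume(cohort_data$volumes[[sid]], file.path(dir, sid),
                         compress = compress)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(cohort_data$manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
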