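#' 3-D image volume with physical geometry
#'
#' Container for a scalar 3-D grid (CT intensities in HU or dose values in Gy)
#' together with its voxel spacing and origin in mm. Axis order is (x, y, z)
#' with z the slice axis; voxel indices are 0-based in all physical-coordinate
#' computations.
#'
#' @param voxels numeric 3-D array, finite throughout.
#' @param spacing numeric length-3, voxel spacing in mm, strictly positive.
#' @param origin numeric length-3, position of voxel (0,0,0) in mm.
#' @param modality `"CT"` or `"DOSE"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(0.98, 0.98, 5.0),
                         origin = c(0, 0, 0), modality = c("CT", "DOSE")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("volume contains non-finite voxels (NaN/Inf)", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' Binary region-of-interest mask
#'
#' A binary mask sharing the exact grid of its paired [image_volume()]. Any
#' nonzero input value is treated as foreground.
#'
#' @param voxels 3-D array; nonzero entries mark the ROI.
#' @param spacing,origin geometry, as in [image_volume()].
#' @param roi_name label for the structure (e.g. `"CTV"`, `"Bladder"`).
#' @return An object of class `roi_mask` whose voxels are 0/1 integers.
#' @export
roi_mask <- function(voxels, spacing = c(0.98, 0.98, 5.0), origin = c(0, 0, 0),
                     roi_name = "ROI") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("mask contains non-finite voxels", call. = FALSE)
  m <- array(as.integer(voxels != 0), dim = dim(voxels))
  if (sum(m) == 0L)
    stop("empty ROI: mask has no foreground voxels", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)", call. = FALSE)
  structure(list(voxels = m, spacing = spacing, origin = origin,
                 roi_name = as.character(roi_name)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels  spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<roi_mask> '%s'  %d x %d x %d grid, %d foreground voxels\n",
              x$roi_name, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

# shared-geometry contract used across the pipeline
check_same_geometry <- function(a, b, tol = 1e-3) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("geometry error: grid shapes differ (",
         paste(dim(a$voxels), collapse = "x"), " vs ",
         paste(dim(b$voxels), collapse = "x"), ")", call. = FALSE)
  if (any(abs(a$spacing - b$spacing) > tol) || any(abs(a$origin - b$origin) > tol))
    stop("geometry error: spacing/origin differ beyond ", tol, " mm", call. = FALSE)
  invisible(TRUE)
}

# background fill used when resampling pushes voxels out of the field of view
background_value <- function(modality) {
  if (identical(modality, "CT")) -1000 else 0
}
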