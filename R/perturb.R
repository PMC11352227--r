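#' One rigid in-plane perturbation
#'
#' Translations are in pixel units, drawn from \{0, 0.4, 0.8\} per in-plane
#' axis; the rotation is axial (about the volume centre, in the xy plane),
#' from \{-20, 0, 20\} degrees. No motion is applied along z: with 5 mm
#' slices a sub-pixel z shift is meaningless and clinical contouring is
#' slice-by-slice.
#'
#' @param tx,ty in-plane translations, pixels.
#' @param theta axial rotation, degrees.
#' @return A `rigid_perturbation`.
#' @export
rigid_perturbation <- function(tx = 0, ty = 0, theta = 0) {
  if (!tx %in% c(0, 0.4, 0.8) || !ty %in% c(0, 0.4, 0.8))
    stop("tx and ty must be in {0, 0.4, 0.8} pixels", call. = FALSE)
  if (!theta %in% c(-20, 0, 20))
    stop("theta must be in {-20, 0, 20} degrees", call. = FALSE)
  structure(list(tx = tx, ty = ty, theta = theta), class = "rigid_perturbation")
}

#' Sample a subject's perturbation set
#'
#' Draws `k` rigid perturbations (tx, ty independently and uniformly from
#' \{0, 0.4, 0.8\} pixels; theta uniformly from \{-20, 0, 20\} degrees) plus a
#' fresh displacement-field seed per perturbation. The identical set is meant
#' to be applied to the CT and dose of one subject. Deterministic given
#' `subject_seed`.
#'
#' @param subject_seed integer seed for this subject.
#' @param k number of perturbations (default 40); at least 2, otherwise the
#'   downstream ICC is undefined.
#' @return A `perturbation_set`: list with `specs` (each
#'   `list(rigid, field_seed)`) and `k`.
#' @export
sample_perturbation_set <- function(subject_seed, k = 40) {
  if (k < 2) stop("parameter error: k must be >= 2 (ICC undefined for k < 2)",
                  call. = FALSE)
  draws <- with_seed(as.integer(subject_seed), {
    list(tx = sample(c(0, 0.4, 0.8), k, replace = TRUE),
         ty = sample(c(0, 0.4, 0.8), k, replace = TRUE),
         theta = sample(c(-20, 0, 20), k, replace = TRUE))
  })
  specs <- lapply(seq_len(k), function(i) {
    list(rigid = rigid_perturbation(draws$tx[i], draws$ty[i], draws$theta[i]),
         field_seed = mix_seed(subject_seed, 500L, i))
  })
  structure(list(specs = specs, k = as.integer(k)), class = "perturbation_set")
}

# backward-mapping source coordinates (0-based) for an in-plane rigid
# transform: rotate by theta about the volume centre, then translate (tx, ty)
rigid_source_coords <- function(nx, ny, p) {
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  th <- p$theta * pi / 180
  xo <- rep(seq_len(nx) - 1, times = ny) - cx - p$tx
  yo <- rep(seq_len(ny) - 1, each = nx) - cy - p$ty
  list(xs = cos(th) * xo + sin(th) * yo + cx,
       ys = -sin(th) * xo + cos(th) * yo + cy)
}

#' Apply a rigid perturbation to a volume and its mask
#'
#' The image is resampled with in-plane bilinear interpolation; the mask is
#' resampled the same way and rebinarised at 0.5. Out-of-field voxels are
#' filled with the modality background (-1000 HU for CT, 0 Gy for dose). The
#' identity perturbation returns the inputs bit-exactly.
#'
#' @param volume an [image_volume()].
#' @param mask the paired [roi_mask()].
#' @param p a [rigid_perturbation()].
#' @return `list(volume, mask)` after the transform.
#' @export
apply_rigid <- function(volume, mask, p) {
  check_same_geometry(volume, mask)
  if (p$tx == 0 && p$ty == 0 && p$theta == 0)
    return(list(volume = volume, mask = mask))
  d <- dim(volume$voxels)
  sc <- rigid_source_coords(d[1], d[2], p)
  vout <- cpp_resample_inplane(as.double(volume$voxels), d[1], d[2], d[3],
                               sc$xs, sc$ys, background_value(volume$modality))
  mout <- cpp_resample_inplane(as.double(mask$voxels), d[1], d[2], d[3],
                               sc$xs, sc$ys, 0)
  v2 <- volume; v2$voxels <- array(vout, dim = d)
  m2 <- mask; m2$voxels <- array(as.integer(mout >= 0.5), dim = d)
  if (sum(m2$voxels) == 0L)
    stop("empty ROI: mask left the field of view under the rigid transform",
         call. = FALSE)
  list(volume = v2, mask = m2)
}

#' Generate a smoothed random displacement field
#'
#' Per-voxel x/y components are drawn from Uniform(-1, 1); the z component is
#' identically zero (slice-by-slice contouring leaves no z deformation). The
#' field is then normalised by the root mean square of the vector magnitude
#' over all voxels, and finally each component is smoothed with a Gaussian of
#' width `sigma_smooth` voxels so the deformed contours stay continuous.
#'
#' @param shape grid shape (nx, ny, nz).
#' @param seed integer seed.
#' @param sigma_smooth Gaussian smoothing width, voxels (default 5).
#' @return A `displacement_field` with components `dx`, `dy`, `dz` in voxel
#'   units.
#' @export
make_displacement_field <- function(shape, seed, sigma_smooth = 5) {
  shape <- as.integer(shape)
  n <- prod(shape)
  u <- with_seed(as.integer(seed), stats::runif(2 * n, -1, 1))
  dx <- array(u[seq_len(n)], dim = shape)
  dy <- array(u[n + seq_len(n)], dim = shape)
  rms <- sqrt(mean(dx^2 + dy^2))
  dx <- dx / rms; dy <- dy / rms
  dx <- smooth_gaussian(dx, sigma_smooth)
  dy <- smooth_gaussian(dy, sigma_smooth)
  structure(list(dx = dx, dy = dy, dz = array(0, dim = shape),
                 sigma_smooth = sigma_smooth, seed = as.integer(seed)),
            class = "displacement_field")
}

#' Randomize a contour through a displacement field
#'
#' The mask is backward-warped through the amplitude-scaled field with
#' bilinear interpolation (slice-wise, since the field has no z component)
#' and rebinarised at 0.5, emulating an independent manual delineation.
#' `amplitude` fixes the root-mean-square displacement magnitude of the
#' applied deformation in voxel units (Gaussian smoothing attenuates the
#' unit-RMS raw field, so the smoothed field is rescaled before use).
#'
#' @param mask an [roi_mask()].
#' @param field a [make_displacement_field()] result on the same grid.
#' @param amplitude RMS deformation strength in voxels (default 3).
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return The randomized [roi_mask()].
#' @export
randomize_contour <- function(mask, field, amplitude = 3,
                              interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(mask$voxels)
  if (!identical(dim(field$dx), d))
    stop("geometry error: field shape differs from mask", call. = FALSE)
  if (amplitude == 0) return(mask)
  rms <- sqrt(mean(field$dx^2 + field$dy^2))
  if (rms == 0) stop("degenerate displacement field (zero everywhere)", call. = FALSE)
  dx <- as.double(field$dx) * (amplitude / rms)
  dy <- as.double(field$dy) * (amplitude / rms)
  if (interpolation == "nearest") { dx <- round(dx); dy <- round(dy) }
  w <- cpp_warp_field(as.double(mask$voxels), d[1], d[2], d[3], dx, dy, 0)
  out <- mask
  out$voxels <- array(as.integer(w >= 0.5), dim = d)
  if (sum(out$voxels) == 0L)
    stop("empty ROI: contour randomization removed all voxels", call. = FALSE)
  out
}

#' Perturb one subject's CT and dose
#'
#' For every perturbation in the set: the rigid transform is applied
#' identically to the CT, the dose, and every mask; contour randomization is
#' then applied to each rigidly-transformed mask (one independent field per
#' (perturbation, ROI), seeded from the perturbation's field seed). The CT
#' and dose arms of a given (perturbation, ROI) share the identical final
#' mask.
#'
#' @param ct,dose [image_volume()] objects on a shared grid.
#' @param masks named list of [roi_mask()] objects.
#' @param pset a [sample_perturbation_set()] result.
#' @param amplitude contour-randomization strength, voxels.
#' @param sigma_smooth displacement-field smoothing, voxels.
#' @return List over perturbations, each
#'   `list(index, rigid, ct, dose, masks)` with `masks` the final randomized
#'   masks.
#' @export
perturb_subject <- function(ct, dose, masks, pset, amplitude = 3,
                            sigma_smooth = 5) {
  stopifnot(inherits(pset, "perturbation_set"))
  check_same_geometry(ct, dose)
  d <- dim(ct$voxels)
  resample <- function(arr, sc, fill) {
    array(cpp_resample_inplane(as.double(arr), d[1], d[2], d[3],
                               sc$xs, sc$ys, fill), dim = d)
  }
  lapply(seq_along(pset$specs), function(i) {
    spec <- pset$specs[[i]]
    p <- spec$rigid
    identity_p <- (p$tx == 0 && p$ty == 0 && p$theta == 0)
    ct2 <- ct; dose2 <- dose
    if (!identity_p) {
      sc <- rigid_source_coords(d[1], d[2], p)
      ct2$voxels <- resample(ct$voxels, sc, background_value("CT"))
      dose2$voxels <- resample(dose$voxels, sc, background_value("DOSE"))
    }
    final_masks <- lapply(seq_along(masks), function(m) {
      mk <- masks[[m]]
      if (!identity_p) {
        mk$voxels <- array(as.integer(resample(masks[[m]]$voxels, sc, 0) >= 0.5),
                           dim = d)
        if (sum(mk$voxels) == 0L)
          stop("empty ROI: mask left the field of view under the rigid transform",
               call. = FALSE)
      }
      fld <- make_displacement_field(d, mix_seed(spec$field_seed, m),
                                     sigma_smooth)
      randomize_contour(mk, fld, amplitude)
    })
    names(final_masks) <- names(masks)
    list(index = i, rigid = p, ct = ct2, dose = dose2, masks = final_masks)
  })
}
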