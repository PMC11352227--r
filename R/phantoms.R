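#' Configuration for synthetic phantom generation
#'
#' Phantoms emulate planning-CT geometry: anisotropic voxels (default
#' 0.98 x 0.98 x 5 mm), tissue textures ranging from near-homogeneous
#' (bladder-like soft tissue) to strongly heterogeneous (femoral-bone-like),
#' and dose-like smooth fields with a sharp fall-off outside a target.
#'
#' @param shape integer length-3 voxel counts (nx, ny, nz); at least 16
#'   in-plane and 4 slices.
#' @param spacing voxel spacing in mm.
#' @param texture_scale correlation length of the CT texture, mm.
#' @param contrast standard deviation of the correlated CT noise, HU.
#' @param n_tissue_levels number of piecewise tissue-intensity plateaus
#'   (1 = homogeneous tissue); plateaus are spaced `level_spacing` HU apart.
#' @param level_spacing HU separation between adjacent tissue plateaus.
#' @param dose_peak prescribed dose inside the target, Gy.
#' @param dose_falloff exponential length scale of the dose fall-off, mm.
#' @param dose_noise_sd standard deviation of the smooth dose noise, Gy
#'   (0 disables it; the noise is what differentiates subjects' dose maps).
#' @param spike_rate per-voxel rate of high-density speck centres
#'   (calcification stand-ins; each speck is a compact 3 x 3 x 1 plateau).
#'   Specks anchor a realistically wide intensity range, so fixed-bin-number
#'   discretization concentrates homogeneous tissue into few gray levels as
#'   it does on patient CT.
#' @param spike_amplitude intensity of the specks above local tissue, HU.
#' @param seed master integer seed; all phantom randomness derives from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 8), spacing = c(0.98, 0.98, 5.0),
                           texture_scale = 3, contrast = 30,
                           n_tissue_levels = 3, level_spacing = 100,
                           dose_peak = 50, dose_falloff = 10,
                           dose_noise_sd = 0.5, spike_rate = 0.002,
                           spike_amplitude = 400, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape[1:2] < 16L) || shape[3] < 4L)
    stop("'shape' must be >= 16 voxels in-plane and >= 4 slices", call. = FALSE)
  if (contrast < 0) stop("'contrast' must be >= 0", call. = FALSE)
  if (dose_peak <= 0) stop("'dose_peak' must be > 0", call. = FALSE)
  if (n_tissue_levels < 1) stop("'n_tissue_levels' must be >= 1", call. = FALSE)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 texture_scale = texture_scale, contrast = contrast,
                 n_tissue_levels = as.integer(n_tissue_levels),
                 level_spacing = level_spacing,
                 dose_peak = dose_peak, dose_falloff = dose_falloff,
                 dose_noise_sd = dose_noise_sd, spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude, seed = as.integer(seed)),
            class = "phantom_config")
}

# correlated Gaussian field with marginal SD `sd` and correlation length
# `scale_mm`; the variance lost to smoothing is compensated exactly using the
# discrete kernel's sum of squares, so the marginal SD is `sd` in expectation
correlated_field <- function(shape, spacing, scale_mm, sd, seed) {
  white <- with_seed(seed, array(stats::rnorm(prod(shape)), dim = shape))
  sig <- scale_mm / spacing
  ks <- lapply(sig, gauss_kernel)
  shrink <- sqrt(prod(vapply(ks, function(k) sum(k^2), 0)))
  sm <- correlate_separable(white, ks[[1]], ks[[2]], ks[[3]])
  sm * (sd / shrink)
}

#' Generate a CT-like phantom volume
#'
#' The volume is a piecewise tissue base (quantile plateaus of a smooth
#' random field, `n_tissue_levels` plateaus spaced `level_spacing` HU apart
#' over a 40 HU soft-tissue baseline) plus a Gaussian-correlated noise field
#' with correlation length `texture_scale` and marginal standard deviation
#' `contrast`. Deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return An [image_volume()] with modality `"CT"`.
#' @export
make_ct_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  base <- array(40, dim = shape)
  if (config$n_tissue_levels > 1L) {
    f <- correlated_field(shape, config$spacing, 3 * config$texture_scale, 1,
                          mix_seed(config$seed, 101L))
    qs <- stats::quantile(f, probs = seq(0, 1, length.out = config$n_tissue_levels + 1))
    lev <- cut(f, breaks = qs, labels = FALSE, include.lowest = TRUE)
    base <- base + array((lev - 1) * config$level_spacing, dim = shape)
  }
  if (config$contrast > 0) {
    base <- base + correlated_field(shape, config$spacing, config$texture_scale,
                                    config$contrast, mix_seed(config$seed, 102L))
  }
  if (config$spike_rate > 0) {
    # specks are compact 3 x 3 x 1 plateaus, not single-voxel deltas: CT is
    # band-limited by the scanner PSF, and a delta would lose half its
    # amplitude under a sub-pixel shift, whereas a plateau's interior —
    # which anchors the in-ROI intensity range — is interpolation-stable
    hit <- with_seed(mix_seed(config$seed, 104L),
                     stats::runif(prod(shape)) < config$spike_rate)
    ind <- array(as.double(hit), dim = shape)
    box <- correlate_separable(ind, rep(1, 3), rep(1, 3), 1)
    base <- base + config$spike_amplitude * pmin(box, 1)
  }
  image_volume(base, config$spacing, c(0, 0, 0), "CT")
}

#' Generate a dose-like phantom from a target mask
#'
#' Dose equals `dose_peak` inside the target and decays as
#' `dose_peak * exp(-d / dose_falloff)` with the Euclidean distance d (mm)
#' from the target surface, emulating the sharp fall-off of a treatment plan.
#' Optional smooth noise (`dose_noise_sd` > 0) perturbs the field.
#'
#' @param config a [phantom_config()].
#' @param target_mask the target [roi_mask()] (e.g. the CTV stand-in).
#' @return An [image_volume()] with modality `"DOSE"`.
#' @export
make_dose_phantom <- function(config, target_mask) {
  stopifnot(inherits(config, "phantom_config"), inherits(target_mask, "roi_mask"))
  shape <- config$shape
  if (!identical(dim(target_mask$voxels), shape))
    stop("geometry error: target mask shape differs from config shape", call. = FALSE)
  d <- cpp_edt(as.integer(target_mask$voxels), shape[1], shape[2], shape[3],
               config$spacing[1], config$spacing[2], config$spacing[3])
  dose <- config$dose_peak * exp(-array(d, dim = shape) / config$dose_falloff)
  if (config$dose_noise_sd > 0) {
    dose <- dose + correlated_field(shape, config$spacing, config$dose_falloff,
                                    config$dose_noise_sd, mix_seed(config$seed, 103L))
    dose[dose < 0] <- 0
  }
  image_volume(dose, config$spacing, c(0, 0, 0), "DOSE")
}

# axis-aligned ellipsoid mask in fractional coordinates
ellipsoid_voxels <- function(shape, center_frac, radius_frac) {
  cx <- center_frac * (shape - 1)
  r <- pmax(radius_frac * shape, 1.5)
  x <- (seq_len(shape[1]) - 1 - cx[1]) / r[1]
  y <- (seq_len(shape[2]) - 1 - cx[2]) / r[2]
  z <- (seq_len(shape[3]) - 1 - cx[3]) / r[3]
  q <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(as.integer(q <= 1), dim = shape)
}

#' Ellipsoidal ROI mask
#'
#' Convenience constructor for a single axis-aligned ellipsoid mask, used by
#' the phantom module and by reduced-size validation studies.
#'
#' @param shape grid shape (nx, ny, nz).
#' @param center_frac ellipsoid centre as a fraction of each axis.
#' @param radius_frac semi-axes as fractions of each axis length.
#' @param spacing,origin geometry (mm).
#' @param roi_name label.
#' @return An [roi_mask()].
#' @export
ellipsoid_mask <- function(shape, center_frac = c(0.5, 0.5, 0.5),
                           radius_frac = c(0.3, 0.3, 0.3),
                           spacing = c(0.98, 0.98, 5.0), origin = c(0, 0, 0),
                           roi_name = "ROI") {
  roi_mask(ellipsoid_voxels(as.integer(shape), center_frac, radius_frac),
           spacing, origin, roi_name)
}

#' Generate the five-ROI phantom roster
#'
#' Ellipsoidal stand-ins for the clinically delineated structures: CTV,
#' Bladder, Rectum, LFemoral, and RFemoral. Masks are pairwise disjoint with
#' distinct sizes; at the default 64 x 64 x 8 shape each exceeds 200 voxels.
#'
#' @param config a [phantom_config()].
#' @return Named list of five [roi_mask()] objects.
#' @export
make_roi_masks <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  layout <- list(
    CTV      = list(c = c(0.50, 0.45, 0.5), r = c(0.150, 0.130, 0.32)),
    Bladder  = list(c = c(0.50, 0.76, 0.5), r = c(0.110, 0.100, 0.30)),
    Rectum   = list(c = c(0.50, 0.15, 0.5), r = c(0.085, 0.085, 0.28)),
    LFemoral = list(c = c(0.15, 0.45, 0.5), r = c(0.100, 0.100, 0.30)),
    RFemoral = list(c = c(0.85, 0.45, 0.5), r = c(0.095, 0.095, 0.30))
  )
  masks <- lapply(names(layout), function(nm) {
    roi_mask(ellipsoid_voxels(shape, layout[[nm]]$c, layout[[nm]]$r),
             config$spacing, c(0, 0, 0), nm)
  })
  names(masks) <- names(layout)
  masks
}

#' Generate a synthetic cohort
#'
#' Subjects share the phantom configuration but receive independent texture
#' seeds plus a subject-level intensity offset drawn from
#' `N(0, between_subject_sd)`; that offset is the between-subject variance
#' component the repeatability analysis must recover. Dose maps differ across
#' subjects through their seeded smooth noise. Deterministic given
#' `config$seed`.
#'
#' @param n_subjects number of subjects, at least 3.
#' @param config a [phantom_config()] (its `seed` is the cohort master seed).
#' @param between_subject_sd SD of the subject intensity offset, HU.
#' @param masks optional named list of [roi_mask()] objects shared by all
#'   subjects; defaults to the five-ROI roster of [make_roi_masks()]. The
#'   first mask is the dose target.
#' @return List of subjects, each `list(subject_id, ct, dose, masks, offset)`.
#' @export
make_cohort <- function(n_subjects, config, between_subject_sd = 20,
                        masks = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_subjects < 3) stop("'n_subjects' must be >= 3", call. = FALSE)
  if (is.null(masks)) masks <- make_roi_masks(config)
  offsets <- with_seed(mix_seed(config$seed, 900L),
                       stats::rnorm(n_subjects, 0, between_subject_sd))
  lapply(seq_len(n_subjects), function(i) {
    cfg_i <- config
    cfg_i$seed <- mix_seed(config$seed, 1000L, i)
    ct <- make_ct_phantom(cfg_i)
    ct$voxels <- ct$voxels + offsets[i]
    dose <- make_dose_phantom(cfg_i, masks[[1]])
    list(subject_id = sprintf("S%03d", i), ct = ct, dose = dose,
         masks = masks, offset = offsets[i])
  })
}
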