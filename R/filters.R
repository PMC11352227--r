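# coiflet-1 decomposition filter taps (6-tap; low-pass sums to sqrt(2),
# high-pass sums to 0)
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

#' The image filter bank
#'
#' Enumerates the preprocessing filter bank: the original image, 3-D
#' Laplacian-of-Gaussian filters at the given sigmas (mm), and the eight
#' sub-bands of a single-level undecimated coif1 wavelet decomposition (all
#' combinations of low/high pass per axis, labelled LLL..HHH with letters in
#' x, y, z order). The default bank has 14 members.
#'
#' @param log_sigmas_mm LoG sigma values in mm (default 1:5).
#' @param wavelet_subbands character vector of 3-letter codes over \{L, H\}
#'   (default all 8).
#' @param include_original keep the unfiltered image in the bank?
#' @return data.frame with columns `filter` (id), `kind`, `sigma_mm`,
#'   `subband`.
#' @export
filter_bank <- function(log_sigmas_mm = 1:5,
                        wavelet_subbands = c("LLL", "HLL", "LHL", "HHL",
                                             "LLH", "HLH", "LHH", "HHH"),
                        include_original = TRUE) {
  rows <- list()
  if (include_original)
    rows[[length(rows) + 1L]] <- data.frame(filter = "original", kind = "original",
                                            sigma_mm = NA_real_, subband = NA_character_)
  for (s in log_sigmas_mm)
    rows[[length(rows) + 1L]] <- data.frame(
      filter = sprintf("log-sigma-%g-mm", s), kind = "log",
      sigma_mm = as.numeric(s), subband = NA_character_)
  for (b in wavelet_subbands) {
    if (!grepl("^[LH]{3}$", b))
      stop("wavelet sub-band codes must be 3 letters over {L, H}", call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      filter = paste0("wavelet-", b), kind = "wavelet",
      sigma_mm = NA_real_, subband = b)
  }
  do.call(rbind, rows)
}

#' Laplacian-of-Gaussian filter
#'
#' The LoG response is computed in physical units on the native (possibly
#' anisotropic) grid: per axis the Gaussian width is `sigma_mm / spacing`
#' voxels, and the three second-derivative terms are scaled by the squared
#' spacing so the Laplacian is per mm^2. Boundary handling is reflection.
#' A sigma below a voxel dimension is poorly resolved along that axis and
#' triggers a warning.
#'
#' @param volume an [image_volume()].
#' @param sigma_mm Gaussian scale in mm, > 0.
#' @return The filtered [image_volume()].
#' @export
apply_log <- function(volume, sigma_mm) {
  if (sigma_mm <= 0) stop("'sigma_mm' must be > 0", call. = FALSE)
  if (any(sigma_mm < volume$spacing))
    warning(sprintf(
      "LoG sigma %g mm is below the voxel dimension(s) %s mm; the response is under-resolved along those axes",
      sigma_mm, paste(volume$spacing[sigma_mm < volume$spacing], collapse = ", ")),
      call. = FALSE)
  sig <- sigma_mm / volume$spacing
  g <- lapply(sig, gauss_kernel)
  d2 <- lapply(sig, gauss_d2_kernel)
  acc <- correlate_separable(volume$voxels, d2[[1]], g[[2]], g[[3]]) / volume$spacing[1]^2
  acc <- acc + correlate_separable(volume$voxels, g[[1]], d2[[2]], g[[3]]) / volume$spacing[2]^2
  acc <- acc + correlate_separable(volume$voxels, g[[1]], g[[2]], d2[[3]]) / volume$spacing[3]^2
  out <- volume
  out$voxels <- acc
  out
}

#' Wavelet sub-band filter
#'
#' Single-level undecimated (stationary) separable coif1 decomposition; the
#' sub-band code selects the low- (L) or high-pass (H) decomposition filter
#' per axis, letters in x, y, z order. The output stays on the input grid so
#' ROI masks transfer without resampling; boundaries are reflected.
#'
#' @param volume an [image_volume()].
#' @param subband 3-letter code over \{L, H\}, e.g. `"LLH"`.
#' @return The filtered [image_volume()].
#' @export
apply_wavelet <- function(volume, subband) {
  if (!grepl("^[LH]{3}$", subband))
    stop("'subband' must be 3 letters over {L, H}", call. = FALSE)
  letters3 <- strsplit(subband, "")[[1]]
  ks <- lapply(letters3, function(l) if (l == "L") COIF1_LO else COIF1_HI)
  out <- volume
  out$voxels <- correlate_separable(volume$voxels, ks[[1]], ks[[2]], ks[[3]])
  out
}

#' Apply one filter-bank member
#'
#' @param volume an [image_volume()].
#' @param spec one row of [filter_bank()].
#' @return The filtered [image_volume()].
#' @export
apply_filter <- function(volume, spec) {
  switch(spec$kind,
         original = volume,
         log = apply_log(volume, spec$sigma_mm),
         wavelet = apply_wavelet(volume, spec$subband),
         stop("unknown filter kind '", spec$kind, "'", call. = FALSE))
}

#' Fixed-bin-number gray-level discretization
#'
#' In-ROI intensities are mapped to `n_bins` integer levels 0..n_bins-1 by
#' dividing the in-ROI intensity range into equal bins:
#' `level = floor((v - min) / width)` with the maximum mapped to the top bin.
#' A constant ROI maps entirely to level 0. Bounds are the in-ROI min/max of
#' the supplied (filtered, possibly perturbed) image, recomputed per call.
#'
#' @param volume an [image_volume()] (or any filtered image).
#' @param mask the [roi_mask()].
#' @param n_bins bin count (default 32).
#' @return A `discretized_roi`: `levels` (3-D integer array, -1 outside the
#'   ROI), `n_bins`, `roi_min`, `roi_max`, `n_voxels`.
#' @export
discretize <- function(volume, mask, n_bins = 32) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("geometry error: volume/mask shapes differ", call. = FALSE)
  inm <- mask$voxels == 1L
  if (!any(inm)) stop("empty ROI: cannot discretize", call. = FALSE)
  v <- volume$voxels[inm]
  lo <- min(v); hi <- max(v)
  lev <- array(-1L, dim = dim(volume$voxels))
  if (hi > lo) {
    width <- (hi - lo) / n_bins
    l <- floor((v - lo) / width)
    l[l > n_bins - 1] <- n_bins - 1
    lev[inm] <- as.integer(l)
  } else {
    lev[inm] <- 0L
  }
  structure(list(levels = lev, n_bins = as.integer(n_bins),
                 roi_min = lo, roi_max = hi, n_voxels = sum(inm)),
            class = "discretized_roi")
}
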