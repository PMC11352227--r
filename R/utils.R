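# Deterministic sub-seed derivation: a master seed plus any number of integer
# indices is hashed into a 31-bit seed, so every subject/perturbation draws
# from its own reproducible stream.
mix_seed <- function(seed, ...) {
  ids <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 104729
  for (v in ids) h <- (h * 48271 + (v %% 2147483647) + 11) %% 2147483647
  as.integer(h)
}

# run expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sampled Gaussian kernel, truncated at 4 sigma, normalised to sum 1
gauss_kernel <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# sampled second derivative of a Gaussian, zero-sum corrected so that a
# constant input maps exactly to zero
gauss_d2_kernel <- function(sigma_vox, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_vox^2)) / (sqrt(2 * pi) * sigma_vox)
  k <- (x^2 - sigma_vox^2) / sigma_vox^4 * g
  k - mean(k)
}

# separable correlation of a 3-D array with per-axis 1-D kernels
# (reflect boundary); kernels of length 1 are skipped
correlate_separable <- function(arr, kx, ky, kz,
                                centers = c(ctr(kx), ctr(ky), ctr(kz))) {
  d <- dim(arr)
  v <- as.double(arr)
  if (length(kx) > 1L)
    v <- cpp_correlate_axis(v, d[1], d[2], d[3], as.double(kx), 0L, centers[1])
  if (length(ky) > 1L)
    v <- cpp_correlate_axis(v, d[1], d[2], d[3], as.double(ky), 1L, centers[2])
  if (length(kz) > 1L)
    v <- cpp_correlate_axis(v, d[1], d[2], d[3], as.double(kz), 2L, centers[3])
  array(v, dim = d)
}

ctr <- function(k) as.integer((length(k) - 1) %/% 2)

# Gaussian smoothing with per-axis sigmas in voxel units
smooth_gaussian <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3)
  correlate_separable(arr,
                      gauss_kernel(sigma_vox[1]),
                      gauss_kernel(sigma_vox[2]),
                      gauss_kernel(sigma_vox[3]))
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b [roi_mask()] objects on the same grid.
#' @return `2|A∩B| / (|A|+|B|)`.
#' @export
dice <- function(a, b) {
  check_same_geometry(a, b)
  2 * sum(a$voxels & b$voxels) / (sum(a$voxels) + sum(b$voxels))
}
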