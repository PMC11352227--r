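# Shared fixtures, generated in code.

test_volume <- function(shape = c(16, 16, 4), seed = 1, spacing = c(0.98, 0.98, 5),
                        modality = "CT") {
  set.seed(seed)
  image_volume(array(rnorm(prod(shape), 50, 20), dim = shape),
               spacing = spacing, modality = modality)
}

# quiet phantom config without high-density specks (degenerate examples need
# a truly constant volume)
plain_config <- function(...) phantom_config(spike_rate = 0, ...)

# independent FFT-based circular convolution of a 3-D array with a full 3-D
# kernel, after explicit symmetric-reflection padding; used as the spectral
# oracle for the spatial separable filters
fft_convolve_reflect <- function(arr, kernel) {
  d <- dim(arr); kd <- dim(kernel)
  r <- (kd - 1) %/% 2
  pad_axis <- function(a, axis, before, after) {
    idx <- vector("list", 3); idx[1:3] <- TRUE
    n <- dim(a)[axis]
    pre <- pmin(before, n); post <- pmin(after, n)
    idx_b <- idx; idx_b[[axis]] <- seq_len(pre)
    idx_a <- idx; idx_a[[axis]] <- seq.int(n - post + 1, n)
    flip <- function(block) {
      i2 <- vector("list", 3); i2[1:3] <- TRUE
      i2[[axis]] <- rev(seq_len(dim(block)[axis]))
      do.call(`[`, c(list(block), i2, list(drop = FALSE)))
    }
    abind3 <- function(x, y, z, axis) {
      perm <- c(axis, setdiff(1:3, axis))
      xp <- aperm(x, perm); yp <- aperm(y, perm); zp <- aperm(z, perm)
      out <- array(0, dim = c(dim(xp)[1] + dim(yp)[1] + dim(zp)[1], dim(xp)[2:3]))
      out[seq_len(dim(xp)[1]), , ] <- xp
      out[dim(xp)[1] + seq_len(dim(yp)[1]), , ] <- yp
      out[dim(xp)[1] + dim(yp)[1] + seq_len(dim(zp)[1]), , ] <- zp
      aperm(out, order(perm))
    }
    abind3(flip(do.call(`[`, c(list(a), idx_b, list(drop = FALSE)))), a,
           flip(do.call(`[`, c(list(a), idx_a, list(drop = FALSE)))), axis)
  }
  p <- arr
  for (ax in 1:3) p <- pad_axis(p, ax, r[ax], r[ax])
  pd <- dim(p)
  kfull <- array(0, dim = pd)
  # place kernel centered at index 1 (circularly)
  ks <- lapply(1:3, function(ax) ((seq_len(kd[ax]) - 1 - r[ax]) %% pd[ax]) + 1)
  kfull[ks[[1]], ks[[2]], ks[[3]]] <-
    kernel[, , , drop = FALSE]
  conv <- Re(fft(fft(p) * fft(kfull), inverse = TRUE)) / prod(pd)
  conv[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3]), drop = FALSE]
}

# independent separable-correlation oracle: axis-by-axis tap gather with
# symmetric reflection, out[i] = sum_t k[t] x[i + t - center]
separable_correlate_oracle <- function(arr, ks, center = 2) {
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    n <- d[ax]; k <- ks[[ax]]
    acc <- array(0, d)
    for (t in seq_along(k)) {
      idx0 <- seq_len(n) + (t - 1) - center - 1      # 0-based source index
      idx0 <- vapply(idx0, function(i) {
        while (i < 0 || i >= n) { if (i < 0) i <- -i - 1; if (i >= n) i <- 2 * n - 1 - i }
        i
      }, 0)
      acc <- acc + k[t] * switch(ax,
        out[idx0 + 1, , , drop = FALSE],
        out[, idx0 + 1, , drop = FALSE],
        out[, , idx0 + 1, drop = FALSE])
    }
    out <- acc
  }
  out
}

# brute-force two-loop one-way ANOVA ICC oracle
icc_oracle <- function(x, kden = "k-1") {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  ssr <- 0; ssw <- 0
  for (i in seq_len(n)) {
    mi <- mean(x[i, ])
    ssr <- ssr + k * (mi - gm)^2
    for (j in seq_len(k)) ssw <- ssw + (x[i, j] - mi)^2
  }
  msr <- ssr / (n - 1)
  msw <- ssw / (n * (k - 1))
  den <- if (kden == "k-1") msr + (k - 1) * msw else msr + (k + 1) * msw
  (msr - msw) / den
}

# the 13-direction roster used by the texture counters
perturbrad_dirs13 <- function() {
  rbind(c(1,0,0), c(0,1,0), c(1,1,0), c(-1,1,0),
        c(0,0,1), c(1,0,1), c(-1,0,1), c(0,1,1), c(0,-1,1),
        c(1,1,1), c(-1,1,1), c(1,-1,1), c(-1,-1,1))
}

# brute-force enumeration of in-mask level pairs for one GLCM offset
glcm_pairs_oracle <- function(levels, offset) {
  d <- dim(levels)
  pairs <- matrix(0, 0, 2)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    a <- levels[x, y, z]
    if (a < 0) next
    x2 <- x + offset[1]; y2 <- y + offset[2]; z2 <- z + offset[3]
    if (x2 < 1 || y2 < 1 || z2 < 1 || x2 > d[1] || y2 > d[2] || z2 > d[3]) next
    b <- levels[x2, y2, z2]
    if (b < 0) next
    pairs <- rbind(pairs, c(a, b))
  }
  pairs
}
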