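make_disc <- function(levels_array, n_bins = 32) {
  structure(list(levels = levels_array, n_bins = as.integer(n_bins),
                 roi_min = 0, roi_max = 1,
                 n_voxels = sum(levels_array >= 0)),
            class = "discretized_roi")
}

test_that("first-order features: degenerate and closed-form histograms", {
  m <- ellipsoid_mask(c(12, 12, 4), radius_frac = c(0.4, 0.4, 0.6))
  const <- image_volume(array(5, c(12, 12, 4)))
  d <- discretize(const, m)
  fo <- first_order_features(d, const$voxels[m$voxels == 1])
  expect_equal(unname(fo["Entropy"]), 0)
  expect_equal(unname(fo["Uniformity"]), 1)
  expect_equal(unname(fo["Variance"]), 0)

  # two equally occupied bins -> 1 bit of entropy, uniformity 1/2
  two <- image_volume(array(0, c(12, 12, 4)))
  n <- sum(m$voxels)
  two$voxels[m$voxels == 1] <- rep(c(0, 10), length.out = n)
  d2 <- discretize(two, m)
  fo2 <- first_order_features(d2, two$voxels[m$voxels == 1])
  expect_equal(unname(fo2["Entropy"]), 1, tolerance = 1e-3)
  expect_equal(unname(fo2["Uniformity"]), 0.5, tolerance = 1e-3)
})

test_that("first-order features match a direct-summation oracle on a random ROI", {
  set.seed(77)
  shape <- c(10, 10, 5)
  m <- roi_mask(array(as.integer(runif(prod(shape)) < 0.5) |
                        c(1L, rep(0L, prod(shape) - 1)), dim = shape))
  v <- test_volume(shape, seed = 78)
  expect_gt(sum(m$voxels), 200)
  d <- discretize(v, m, 32)
  raw <- v$voxels[m$voxels == 1]
  fo <- first_order_features(d, raw, voxel_volume = prod(v$spacing))

  # independent transcription: plain sums over the raw vector / histogram
  x <- sort(raw); N <- length(x)
  mu <- sum(x) / N
  cen <- x - mu
  hist_p <- as.numeric(table(d$levels[d$levels >= 0])) / N
  q <- quantile(raw, c(.1, .25, .5, .75, .9), names = FALSE)
  mid <- x[x >= q[1] & x <= q[5]]
  oracle <- c(sum(x^2), prod(v$spacing) * sum(x^2),
              -sum(hist_p * log2(hist_p)), x[1], q[1], q[5], x[N], mu, q[3],
              q[4] - q[2], x[N] - x[1], sum(abs(cen)) / N,
              sum(abs(mid - sum(mid) / length(mid))) / length(mid),
              sqrt(sum(x^2) / N),
              (sum(cen^3) / N) / (sum(cen^2) / N)^1.5,
              (sum(cen^4) / N) / (sum(cen^2) / N)^2,
              sum(cen^2) / N, sum(hist_p^2))
  expect_equal(as.numeric(fo), oracle, tolerance = 1e-10)
})

test_that("GLCM counts match brute-force pair enumeration", {
  # hand case: 2 x 2 x 1 ROI, levels [[0,0],[1,1]] along y
  lv <- array(-1L, c(2, 2, 1))
  lv[1, 1, 1] <- 0L; lv[2, 1, 1] <- 0L
  lv[1, 2, 1] <- 1L; lv[2, 2, 1] <- 1L
  raw <- perturbrad:::cpp_glcm(as.integer(lv), 2L, 2L, 1L, 2L)
  # direction 1 is the +x offset: pairs (0,0) at y=1 and (1,1) at y=2
  expect_equal(raw[[1]], matrix(c(1L, 0L, 0L, 1L), 2, 2))

  # random fixture: every direction's count matrix equals the enumeration,
  # and entries sum to the number of valid in-mask pairs
  set.seed(5)
  shape <- c(6, 5, 4)
  lv <- array(sample(0:3, prod(shape), replace = TRUE), dim = shape)
  lv[sample(prod(shape), 40)] <- -1L
  raw <- perturbrad:::cpp_glcm(as.integer(lv), 6L, 5L, 4L, 4L)
  dirs <- perturbrad_dirs13()
  for (d in seq_len(13)) {
    pairs <- glcm_pairs_oracle(lv, dirs[d, ])
    expect_equal(sum(raw[[d]]), nrow(pairs))
    expected <- matrix(0L, 4, 4)
    for (r in seq_len(nrow(pairs)))
      expected[pairs[r, 1] + 1, pairs[r, 2] + 1] <-
        expected[pairs[r, 1] + 1, pairs[r, 2] + 1] + 1L
    expect_equal(raw[[d]], expected)
  }
})

test_that("GLCM features match a direct-formula oracle on a toy ROI", {
  set.seed(11)
  lv <- array(sample(0:3, 4 * 4 * 2, replace = TRUE), dim = c(4, 4, 2))
  disc <- make_disc(lv, n_bins = 4)
  got <- texture_features(texture_matrix(disc, "GLCM"))

  dirs <- perturbrad_dirs13()
  per_dir <- lapply(seq_len(13), function(d) {
    pairs <- glcm_pairs_oracle(lv, dirs[d, ])
    P <- matrix(0, 4, 4)
    for (r in seq_len(nrow(pairs))) {
      P[pairs[r, 1] + 1, pairs[r, 2] + 1] <- P[pairs[r, 1] + 1, pairs[r, 2] + 1] + 1
      P[pairs[r, 2] + 1, pairs[r, 1] + 1] <- P[pairs[r, 2] + 1, pairs[r, 1] + 1] + 1
    }
    p <- P / sum(P)
    # direct elementwise loops over the normalized symmetric matrix
    ng <- 4
    feats <- c(Autocorrelation = 0, JointAverage = 0, Contrast = 0,
               JointEnergy = 0, JointEntropy = 0, Idm = 0, Id = 0,
               InverseVariance = 0, MaximumProbability = max(p),
               SumSquares = 0)
    mux <- 0
    for (i in 1:ng) for (j in 1:ng) mux <- mux + i * p[i, j]
    for (i in 1:ng) for (j in 1:ng) {
      pij <- p[i, j]
      feats["Autocorrelation"] <- feats["Autocorrelation"] + i * j * pij
      feats["JointAverage"] <- feats["JointAverage"] + i * pij
      feats["Contrast"] <- feats["Contrast"] + (i - j)^2 * pij
      feats["JointEnergy"] <- feats["JointEnergy"] + pij^2
      if (pij > 0) feats["JointEntropy"] <- feats["JointEntropy"] - pij * log2(pij)
      feats["Idm"] <- feats["Idm"] + pij / (1 + (i - j)^2)
      feats["Id"] <- feats["Id"] + pij / (1 + abs(i - j))
      if (i != j) feats["InverseVariance"] <- feats["InverseVariance"] + pij / (i - j)^2
      feats["SumSquares"] <- feats["SumSquares"] + (i - mux)^2 * pij
    }
    feats
  })
  oracle <- Reduce(`+`, per_dir) / 13
  for (nm in names(oracle))
    expect_equal(unname(got[paste0("glcm_", nm)]), unname(oracle[nm]),
                 tolerance = 1e-10, label = nm)
})

test_that("constant ROI: GLCM is a single cell, GLSZM a single zone", {
  lv <- array(-1L, c(6, 6, 3))
  lv[2:5, 2:5, 1:3] <- 0L
  disc <- make_disc(lv)
  g <- texture_features(texture_matrix(disc, "GLCM"))
  expect_equal(unname(g["glcm_MaximumProbability"]), 1)
  expect_equal(unname(g["glcm_JointEntropy"]), 0)
  zones <- texture_matrix(disc, "GLSZM")$matrix
  expect_equal(nrow(zones), 1L)
  expect_equal(zones[1, 2], 48L)    # one 26-connected zone of |ROI| voxels
  expect_equal(zones[1, 1], 0L)
})

test_that("run-length and dependence counting agree with hand enumeration", {
  # 4 x 1 x 1 line with levels 0,0,1,1: +x runs are two runs of length 2
  lv <- array(-1L, c(4, 1, 1)); lv[, 1, 1] <- c(0L, 0L, 1L, 1L)
  rl <- perturbrad:::cpp_glrlm(as.integer(lv), 4L, 1L, 1L, 2L)
  expect_equal(rl[[1]][1, 2], 1L)   # level 0, run length 2
  expect_equal(rl[[1]][2, 2], 1L)   # level 1, run length 2
  expect_equal(sum(rl[[1]]), 2L)

  # dependence: middle voxel of a constant 3 x 3 x 1 patch has 8 equal
  # neighbours
  lv2 <- array(-1L, c(3, 3, 1)); lv2[, , 1] <- 0L
  gd <- perturbrad:::cpp_gldm(as.integer(lv2), 3L, 3L, 1L, 1L, 0L)
  expect_equal(gd[1, 9], 1L)        # dependence 8 -> column 9
  expect_equal(sum(gd), 9L)

  # NGTDM on the same patch: every |level - neighbourhood mean| is 0
  ng <- perturbrad:::cpp_ngtdm(as.integer(lv2), 3L, 3L, 1L, 1L)
  expect_equal(ng$n[1], 9L)
  expect_equal(ng$s[1], 0)
})

test_that("the full vector has 1302 features with the documented partition", {
  cfg <- phantom_config(shape = c(24, 24, 6), seed = 2)
  ct <- make_ct_phantom(cfg)
  m <- ellipsoid_mask(c(24, 24, 6), radius_frac = c(0.32, 0.32, 0.4))
  f <- extract_features(ct, m)
  expect_equal(nrow(f), 1302L)
  expect_equal(length(unique(f$feature_id)), 1302L)
  counts <- table(f$class) / length(unique(f$filter))
  expect_equal(as.numeric(counts[c("firstorder", "glcm", "gldm", "glrlm",
                                   "glszm", "ngtdm")]),
               c(18, 24, 14, 16, 16, 5))
  expect_true(all(is.finite(f$value)))
  f2 <- extract_features(ct, m)
  expect_identical(f$value, f2$value)
})

test_that("histogram features are permutation-invariant; texture features are not", {
  set.seed(9)
  shape <- c(12, 12, 4)
  m <- ellipsoid_mask(shape, radius_frac = c(0.4, 0.4, 0.6))
  v <- test_volume(shape, seed = 10)
  v2 <- v
  idx <- which(m$voxels == 1)
  v2$voxels[idx] <- v$voxels[sample(idx)]
  bank1 <- filter_bank(log_sigmas_mm = numeric(0),
                       wavelet_subbands = character(0))
  a <- extract_features(v, m, bank1)
  b <- extract_features(v2, m, bank1)
  hist_based <- a$feature %in% c("Entropy", "Uniformity", "Mean", "Variance",
                                 "Energy", "Minimum", "Maximum")
  expect_equal(a$value[hist_based], b$value[hist_based], tolerance = 1e-10)
  texture <- a$class == "glcm"
  expect_false(isTRUE(all.equal(a$value[texture], b$value[texture])))
})
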