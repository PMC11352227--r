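test_that("characteristics records have (filter x roi x modality) cardinality", {
  cfg <- plain_config(shape = c(20, 20, 4), seed = 8, dose_noise_sd = 0)
  masks <- list(A = ellipsoid_mask(c(20, 20, 4), c(0.35, 0.5, 0.5),
                                   c(0.2, 0.22, 0.4), roi_name = "A"),
                B = ellipsoid_mask(c(20, 20, 4), c(0.72, 0.5, 0.5),
                                   c(0.16, 0.18, 0.4), roi_name = "B"))
  cohort <- make_cohort(3, cfg, masks = masks)
  bank <- filter_bank(log_sigmas_mm = 2, wavelet_subbands = c("LLL", "HHH"))
  ch <- image_characteristics(cohort, bank, c("CT", "DOSE"))
  expect_equal(nrow(ch), 4 * 2 * 2)
  expect_true(all(ch$mean_uniformity > 0 & ch$mean_uniformity <= 1))
  expect_true(all(ch$mean_entropy >= 0 & ch$mean_entropy <= 5))
  expect_equal(ch$n_subjects, rep(3, 16))
})

test_that("a constant cohort has zero entropy, unit uniformity, zero variance", {
  cfg <- plain_config(shape = c(16, 16, 4), contrast = 0, n_tissue_levels = 1,
                      dose_noise_sd = 0)
  masks <- list(A = ellipsoid_mask(c(16, 16, 4), roi_name = "A"))
  cohort <- make_cohort(3, cfg, between_subject_sd = 0, masks = masks)
  bank <- filter_bank(log_sigmas_mm = numeric(0),
                      wavelet_subbands = character(0))
  ch <- image_characteristics(cohort, bank, "CT")
  expect_equal(ch$mean_entropy, 0)
  expect_equal(ch$mean_uniformity, 1)
  expect_equal(ch$mean_variance, 0)
})

test_that("subject averaging equals an independent group-by recomputation", {
  cfg <- plain_config(shape = c(16, 16, 4), seed = 31, dose_noise_sd = 0)
  masks <- list(A = ellipsoid_mask(c(16, 16, 4), roi_name = "A"))
  cohort <- make_cohort(4, cfg, masks = masks)
  bank <- filter_bank(log_sigmas_mm = 1, wavelet_subbands = "HHL")
  ch <- image_characteristics(cohort, bank, "CT")
  for (b in seq_len(nrow(bank))) {
    per_subject <- vapply(cohort, function(s) {
      filt <- suppressWarnings(apply_filter(s$ct, bank[b, ]))
      image_characteristics_one(filt, masks$A)["entropy"]
    }, 0)
    expect_equal(ch$mean_entropy[ch$filter == bank$filter[b]],
                 mean(per_subject), tolerance = 1e-12)
  }
})

test_that("Pearson correlation against the textbook formula and its symmetries", {
  rec <- data.frame(filter = letters[1:5], roi = "A", modality = "CT",
                    mean_entropy = c(1, 2, 3, 4, 5),
                    mean_uniformity = c(0.9, 0.7, 0.5, 0.4, 0.2),
                    mean_variance = c(10, 30, 20, 50, 40),
                    mean_icc = c(0.2, 0.45, 0.55, 0.8, 0.9))
  # perfect linearity
  rec_lin <- rec; rec_lin$mean_icc <- 0.1 * rec$mean_entropy + 0.05
  expect_equal(correlate_characteristic(rec_lin, "entropy")$r, 1,
               tolerance = 1e-12)
  # direct-formula transcription
  x <- rec$mean_variance; y <- rec$mean_icc
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cc <- correlate_characteristic(rec, "variance")
  expect_equal(cc$r, r_direct, tolerance = 1e-12)
  expect_equal(cc$n, 5)
  # antisymmetry under negation of the characteristic
  rec_neg <- rec; rec_neg$mean_variance <- -rec$mean_variance
  expect_equal(correlate_characteristic(rec_neg, "variance")$r, -cc$r,
               tolerance = 1e-12)
  # degenerate input
  rec_const <- rec; rec_const$mean_entropy <- 1
  expect_error(correlate_characteristic(rec_const, "entropy"),
               "undefined correlation")
  expect_error(correlate_characteristic(rec[1:2, ], "entropy"), "at least 3")
})

test_that("correlate_characteristics reports all three metrics per modality", {
  rec <- data.frame(filter = rep(letters[1:4], 2), roi = "A",
                    modality = rep(c("CT", "DOSE"), each = 4),
                    mean_entropy = rnorm(8), mean_uniformity = rnorm(8),
                    mean_variance = rnorm(8), mean_icc = rnorm(8))
  out <- correlate_characteristics(rec)
  expect_equal(nrow(out), 6L)
  expect_setequal(unique(out$characteristic),
                  c("entropy", "uniformity", "variance"))
  expect_true(all(abs(out$r) <= 1))
})
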