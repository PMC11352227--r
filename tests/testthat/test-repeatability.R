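test_that("noise-free matrices give ICC 1; size limits are enforced", {
  x <- matrix(rep(c(1, 5, 9), each = 4), nrow = 3, byrow = TRUE)
  r <- icc_oneway(x)
  expect_equal(r$icc, 1)
  expect_true(r$high_repeatable)
  expect_false(r$degenerate)

  allsame <- matrix(2, 4, 3)
  r2 <- icc_oneway(allsame)
  expect_equal(r2$icc, 1)
  expect_true(r2$degenerate)

  expect_error(icc_oneway(matrix(0, 2, 5)), "parameter error")
  expect_error(icc_oneway(matrix(0, 5, 1)), "parameter error")
})

test_that("ICC matches the brute-force one-way ANOVA oracle", {
  x <- matrix(c(0, 2, 1, -1, -1, 0), nrow = 3, byrow = TRUE)
  expect_equal(icc_oneway(x)$icc, icc_oracle(x), tolerance = 1e-12)
  # audit variant with the (k+1) denominator
  expect_equal(icc_oneway(x, denominator = "k+1")$icc,
               icc_oracle(x, "k+1"), tolerance = 1e-12)
  set.seed(41)
  for (rep in 1:50) {
    m <- matrix(rnorm(20), 5, 4)
    expect_lt(abs(icc_oneway(m)$icc - icc_oracle(m)), 1e-12)
  }
})

test_that("threshold classification uses >= 0.9", {
  # construct a matrix whose ICC is exactly representable near the boundary
  set.seed(2)
  m <- matrix(rnorm(200, sd = 1), 50, 4) + rnorm(50, sd = 6)
  r <- icc_oneway(m, threshold = r0 <- 0.9)
  expect_identical(r$high_repeatable, r$icc >= r0)
  r_at <- icc_oneway(matrix(rep(c(1, 5, 9), each = 4), 3, byrow = TRUE),
                     threshold = 1)
  expect_true(r_at$high_repeatable)   # icc == threshold counts as high
})

test_that("ICC is invariant to affine transforms and column permutations", {
  set.seed(13)
  for (rep in 1:20) {
    m <- matrix(rnorm(24), 6, 4)
    base <- icc_oneway(m)$icc
    expect_equal(icc_oneway(3.7 * m - 11)$icc, base, tolerance = 1e-12)
    expect_equal(icc_oneway(-2 * m + 5)$icc, base, tolerance = 1e-12)
    expect_equal(icc_oneway(m[, sample(4)])$icc, base, tolerance = 1e-12)
    # duplicating every subject leaves the mean squares' expectation alone;
    # the finite-sample (n-1) denominator shifts the estimate only at O(1/n)
    expect_equal(icc_oneway(rbind(m, m))$icc, base, tolerance = 0.2)
  }
})

test_that("ICC recovers the variance ratio across its range", {
  set.seed(19)
  for (target in c(0.1, 0.5, 0.9)) {
    sb <- sqrt(target); sw <- sqrt(1 - target)
    est <- vapply(1:100, function(r) {
      b <- rnorm(200, sd = sb)
      icc_oneway(outer(b, rep(1, 40)) +
                   matrix(rnorm(200 * 40, sd = sw), 200, 40))$icc
    }, 0)
    expect_lt(abs(mean(est) - target), 0.03, label = paste("target", target))
  }
})

test_that("expected ICC decreases as within-subject variance grows", {
  set.seed(7)
  mean_icc <- vapply(c(0.5, 1, 2, 4), function(sw) {
    mean(vapply(1:40, function(r) {
      b <- rnorm(30, sd = sqrt(3))
      icc_oneway(outer(b, rep(1, 8)) + matrix(rnorm(240, sd = sw), 30, 8))$icc
    }, 0))
  }, 0)
  expect_true(all(diff(mean_icc) < 0))
})

make_feature_table <- function(n = 4, k = 3, fids = paste0("f", 1:6),
                               rois = "A", modality = "CT", seed = 1) {
  set.seed(seed)
  g <- expand.grid(subject = paste0("S", 1:n), perturbation = 1:k,
                   feature_id = fids, roi = rois, modality = modality,
                   stringsAsFactors = FALSE)
  g$filter <- ifelse(g$feature_id %in% fids[1:3], "original", "wavelet-LLL")
  g$class <- "firstorder"
  subj_eff <- rnorm(n, sd = 2)[match(g$subject, paste0("S", 1:n))]
  g$value <- subj_eff + rnorm(nrow(g), sd = 0.5)
  g
}

test_that("icc_table yields one row per feature and is column-order invariant", {
  tab <- make_feature_table()
  res <- icc_table(tab)
  expect_equal(nrow(res), 6L)
  expect_true(all(c("icc", "MSR", "MSW", "n", "k", "high_repeatable",
                    "filter", "class") %in% names(res)))

  tab2 <- tab[sample(nrow(tab)), ]
  tab2$perturbation <- ave(tab2$perturbation, tab2$subject, tab2$feature_id,
                           FUN = function(p) rev(p))
  res2 <- icc_table(tab2)
  res2 <- res2[match(res$feature_id, res2$feature_id), ]
  expect_equal(res$icc, res2$icc, tolerance = 1e-12)

  small <- tab[tab$subject %in% c("S1", "S2"), ]
  expect_warning(expect_error(icc_table(small), "no stratum"), "below minimum")
})

test_that("group summaries equal an independent aggregation", {
  tab <- make_feature_table(seed = 4)
  res <- icc_table(tab)
  s <- summarize_icc(res, "filter")
  for (g in unique(s$group)) {
    member <- res$icc[res$filter == g]
    expect_equal(s$mean_icc[s$group == g], mean(member), tolerance = 1e-12)
    expect_equal(s$sd_icc[s$group == g], sd(member), tolerance = 1e-12)
  }
  # all-identical ICCs give zero SD in every group
  res$icc[] <- 0.5
  s0 <- summarize_icc(res, "filter")
  expect_true(all(s0$sd_icc == 0))
})

test_that("modality agreement partitions features into the four categories", {
  ct <- data.frame(feature_id = c("a", "b", "c", "d"), roi = "A",
                   filter = "original", class = "firstorder",
                   high_repeatable = c(TRUE, TRUE, FALSE, FALSE))
  dose <- data.frame(feature_id = c("a", "b", "c", "d"), roi = "A",
                     high_repeatable = c(TRUE, FALSE, TRUE, FALSE))
  agr <- compare_modalities(ct, dose)
  expect_equal(agr$records$category, c("both_high", "ct_only", "dose_only",
                                       "both_low"))
  expect_equal(sum(agr$by_filter[, c("both_high", "both_low", "ct_only",
                                     "dose_only")]) , 1)
  expect_equal(agr$by_filter$n, 4)

  dose_bad <- dose[1:3, ]
  expect_error(compare_modalities(ct, dose_bad), "reconciliation error")
})
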