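EPS <- 2.2e-16

#' First-order statistics (18 features)
#'
#' Computed from the raw in-mask intensities and, for entropy and uniformity,
#' from the fixed-bin-number discretized histogram. Variance, skewness, and
#' kurtosis use population (1/N) moments; kurtosis is non-excess. Skewness
#' and kurtosis of a degenerate ROI (fewer than 2 voxels, or zero variance)
#' are returned as 0 and flagged via `attr(x, "degenerate")`.
#'
#' @param discretized a [discretize()] result.
#' @param raw_in_mask numeric vector of in-mask intensities of the same image.
#' @param voxel_volume voxel volume in mm^3 (for total energy).
#' @return Named numeric vector of the 18 first-order features.
#' @export
first_order_features <- function(discretized, raw_in_mask,
                                 voxel_volume = 0.98 * 0.98 * 5) {
  v <- as.numeric(raw_in_mask)
  n <- length(v)
  if (n < 1) stop("empty ROI", call. = FALSE)
  lv <- discretized$levels[discretized$levels >= 0]
  p <- tabulate(lv + 1L, nbins = discretized$n_bins)
  p <- p / sum(p)
  pnz <- p[p > 0]
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  sub <- v[v >= q[1] & v <= q[5]]
  degenerate <- (n < 2 || m2 == 0)
  skew <- if (degenerate) 0 else mean((v - mu)^3) / m2^1.5
  kurt <- if (degenerate) 0 else mean((v - mu)^4) / m2^2
  out <- c(
    Energy = sum(v^2),
    TotalEnergy = voxel_volume * sum(v^2),
    Entropy = -sum(pnz * log2(pnz)),
    Minimum = min(v),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(v),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation = if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
  attr(out, "degenerate") <- degenerate
  out
}

#' Build a gray-level texture matrix
#'
#' Matrices follow the IBSI conventions: GLCM and GLRLM use the 13 unique
#' 3-D direction offsets at Chebyshev distance 1 (one matrix per direction;
#' GLCM symmetrized); GLDM and NGTDM use the 26-connected neighbourhood
#' (GLDM dependence tolerance alpha = 0); GLSZM zones are 26-connected
#' components of equal level. Only in-mask voxels participate.
#'
#' @param discretized a [discretize()] result.
#' @param kind one of `"GLCM"`, `"GLDM"`, `"GLRLM"`, `"GLSZM"`, `"NGTDM"`.
#' @param alpha GLDM dependence tolerance (default 0).
#' @return A `texture_matrix` object; structure depends on `kind`.
#' @export
texture_matrix <- function(discretized, kind = c("GLCM", "GLDM", "GLRLM",
                                                 "GLSZM", "NGTDM"),
                           alpha = 0L) {
  kind <- match.arg(kind)
  d <- dim(discretized$levels)
  lv <- as.integer(discretized$levels)
  ng <- discretized$n_bins
  m <- switch(kind,
    GLCM = {
      raw <- cpp_glcm(lv, d[1], d[2], d[3], ng)
      lapply(raw, function(x) x + t(x))   # symmetrization
    },
    GLRLM = cpp_glrlm(lv, d[1], d[2], d[3], ng),
    GLSZM = cpp_glszm_zones(lv, d[1], d[2], d[3]),
    GLDM = cpp_gldm(lv, d[1], d[2], d[3], ng, as.integer(alpha)),
    NGTDM = cpp_ngtdm(lv, d[1], d[2], d[3], ng))
  structure(list(kind = kind, matrix = m, ng = ng,
                 n_voxels = discretized$n_voxels),
            class = "texture_matrix")
}

glcm_features_one <- function(P) {
  s <- sum(P)
  p <- P / s
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)          # gray levels 1..Ng
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * p); muy <- sum(j * p)
  sigx <- sqrt(sum((i - mux)^2 * p)); sigy <- sqrt(sum((j - muy)^2 * p))
  # diagonal / cross-diagonal marginals
  kd <- as.vector(i - j)
  pd <- tapply(as.vector(p), abs(kd), sum)          # |i-j| = 0..Ng-1
  kdv <- as.numeric(names(pd))
  ks <- as.vector(i + j)
  psv <- tapply(as.vector(p), ks, sum)              # i+j = 2..2Ng
  ksv <- as.numeric(names(psv))
  da <- sum(kdv * pd)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  pxy <- outer(px, py)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0] + EPS))
  hxy2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  corr <- if (sigx * sigy > 0) (sum(i * j * p) - mux * muy) / (sigx * sigy) else 0
  # maximal correlation coefficient
  # Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) py(k)); MCC = sqrt of its second
  # largest eigenvalue, 1 for a single-level ROI
  mcc <- {
    nz <- which(px > 0)
    if (length(nz) < 2) 1 else {
      pq <- p[nz, nz, drop = FALSE]
      Q <- sweep(pq, 1, px[nz], "/") %*% t(sweep(pq, 2, py[nz], "/"))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      if (length(ev) < 2 || ev[2] < 0) 0 else sqrt(ev[2])
    }
  }
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum((kdv - da)^2 * pd),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(p),
    SumAverage = sum(ksv * psv),
    SumEntropy = -sum(psv[psv > 0] * log2(psv[psv > 0])),
    SumSquares = sum((i - mux)^2 * p),
    MCC = mcc)
}

rl_features <- function(P, np, prefix) {
  # shared 16-formula roster of the run-length / size-zone families:
  # P is Ng x max-size counts, np the ROI voxel count
  nr <- sum(P)
  p <- P / nr
  ng <- nrow(P); nl <- ncol(P)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  ri <- rowSums(P); rj <- colSums(P)
  mui <- sum(i * p); muj <- sum(j * p)
  nm <- c("SmallEmphasis", "LargeEmphasis", "GrayLevelNonUniformity",
          "GrayLevelNonUniformityNormalized", "SizeNonUniformity",
          "SizeNonUniformityNormalized", "Percentage", "GrayLevelVariance",
          "SizeVariance", "Entropy", "LowGrayLevelEmphasis",
          "HighGrayLevelEmphasis", "SmallLowGrayLevelEmphasis",
          "SmallHighGrayLevelEmphasis", "LargeLowGrayLevelEmphasis",
          "LargeHighGrayLevelEmphasis")
  vals <- c(sum(p / j^2), sum(p * j^2), sum(ri^2) / nr, sum(ri^2) / nr^2,
            sum(rj^2) / nr, sum(rj^2) / nr^2, nr / np,
            sum((i - mui)^2 * p), sum((j - muj)^2 * p),
            -sum(p[p > 0] * log2(p[p > 0])),
            sum(p / i^2), sum(p * i^2),
            sum(p / (i^2 * j^2)), sum(p * i^2 / j^2),
            sum(p * j^2 / i^2), sum(p * i^2 * j^2))
  stats::setNames(vals, paste0(prefix, nm))
}

#' Texture features from a texture matrix
#'
#' IBSI-standard formulas; gray levels enter the formulas as 1..Ng.
#' Per-direction matrices (GLCM, GLRLM) are feature-averaged over the 13
#' directions. Feature counts per class: GLCM 24, GLDM 14, GLRLM 16,
#' GLSZM 16, NGTDM 5.
#'
#' @param tm a [texture_matrix()].
#' @return Named numeric vector.
#' @export
texture_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"))
  switch(tm$kind,
    GLCM = {
      per_dir <- lapply(tm$matrix, function(P) if (sum(P) > 0) glcm_features_one(P) else NULL)
      per_dir <- per_dir[!vapply(per_dir, is.null, TRUE)]
      if (!length(per_dir)) stop("GLCM empty in every direction", call. = FALSE)
      avg <- Reduce(`+`, per_dir) / length(per_dir)
      stats::setNames(avg, paste0("glcm_", names(avg)))
    },
    GLRLM = {
      per_dir <- lapply(tm$matrix, function(P) {
        if (sum(P) == 0) return(NULL)
        f <- rl_features(P, tm$n_voxels, "")
        names(f) <- sub("^Small", "ShortRun", names(f))
        names(f) <- sub("^Large", "LongRun", names(f))
        names(f) <- sub("^Size", "RunLength", names(f))
        names(f) <- sub("^Percentage", "RunPercentage", names(f))
        names(f) <- sub("^Entropy", "RunEntropy", names(f))
        names(f) <- sub("^RunLengthVariance", "RunVariance", names(f))
        names(f) <- sub("LowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                        fixed = TRUE, names(f))
        names(f) <- sub("HighGrayLevelEmphasis", "HighGrayLevelRunEmphasis",
                        fixed = TRUE, names(f))
        names(f) <- sub("^ShortRunLowGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis", names(f))
        names(f) <- sub("^ShortRunHighGrayLevelRunEmphasis", "ShortRunHighGrayLevelEmphasis", names(f))
        names(f) <- sub("^LongRunLowGrayLevelRunEmphasis", "LongRunLowGrayLevelEmphasis", names(f))
        names(f) <- sub("^LongRunHighGrayLevelRunEmphasis", "LongRunHighGrayLevelEmphasis", names(f))
        f
      })
      per_dir <- per_dir[!vapply(per_dir, is.null, TRUE)]
      avg <- Reduce(`+`, per_dir) / length(per_dir)
      stats::setNames(avg, paste0("glrlm_", names(avg)))
    },
    GLSZM = {
      zones <- tm$matrix          # (level, size) rows
      if (nrow(zones) == 0) stop("GLSZM has no zones", call. = FALSE)
      P <- matrix(0, tm$ng, max(zones[, 2]))
      for (r in seq_len(nrow(zones)))
        P[zones[r, 1] + 1L, zones[r, 2]] <- P[zones[r, 1] + 1L, zones[r, 2]] + 1
      f <- rl_features(P, tm$n_voxels, "")
      names(f) <- sub("^Small", "SmallArea", names(f))
      names(f) <- sub("^Large", "LargeArea", names(f))
      names(f) <- sub("^Size", "SizeZone", names(f))
      names(f) <- sub("^Percentage", "ZonePercentage", names(f))
      names(f) <- sub("^Entropy", "ZoneEntropy", names(f))
      names(f) <- sub("^SizeZoneVariance", "ZoneVariance", names(f))
      names(f) <- sub("LowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
                      fixed = TRUE, names(f))
      names(f) <- sub("HighGrayLevelEmphasis", "HighGrayLevelZoneEmphasis",
                      fixed = TRUE, names(f))
      names(f) <- sub("^SmallAreaLowGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis", names(f))
      names(f) <- sub("^SmallAreaHighGrayLevelZoneEmphasis", "SmallAreaHighGrayLevelEmphasis", names(f))
      names(f) <- sub("^LargeAreaLowGrayLevelZoneEmphasis", "LargeAreaLowGrayLevelEmphasis", names(f))
      names(f) <- sub("^LargeAreaHighGrayLevelZoneEmphasis", "LargeAreaHighGrayLevelEmphasis", names(f))
      stats::setNames(f, paste0("glszm_", names(f)))
    },
    GLDM = {
      P <- tm$matrix              # ng x 27, dependence 0..26 -> j = dep + 1
      nz <- sum(P)
      p <- P / nz
      ng <- nrow(P); nd <- ncol(P)
      i <- matrix(seq_len(ng), ng, nd)
      j <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
      mui <- sum(i * p); muj <- sum(j * p)
      ri <- rowSums(P); rj <- colSums(P)
      f <- c(SmallDependenceEmphasis = sum(p / j^2),
             LargeDependenceEmphasis = sum(p * j^2),
             GrayLevelNonUniformity = sum(ri^2) / nz,
             DependenceNonUniformity = sum(rj^2) / nz,
             DependenceNonUniformityNormalized = sum(rj^2) / nz^2,
             GrayLevelVariance = sum((i - mui)^2 * p),
             DependenceVariance = sum((j - muj)^2 * p),
             DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
             LowGrayLevelEmphasis = sum(p / i^2),
             HighGrayLevelEmphasis = sum(p * i^2),
             SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
             SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
             LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
             LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2))
      stats::setNames(f, paste0("gldm_", names(f)))
    },
    NGTDM = {
      nvec <- tm$matrix$n; svec <- tm$matrix$s
      nvp <- sum(nvec)
      pv <- nvec / nvp
      act <- which(nvec > 0)
      ngp <- length(act)
      lev <- act                       # gray levels as 1..Ng
      pi_ <- pv[act]; si <- svec[act]
      coarse <- { den <- sum(pi_ * si); if (den > 0) 1 / den else 1e6 }
      contrast <- if (ngp > 1) {
        (sum(outer(pi_, pi_) * outer(lev, lev, `-`)^2) / (ngp * (ngp - 1))) *
          (sum(si) / nvp)
      } else 0
      busy <- { den <- sum(abs(outer(lev * pi_, lev * pi_, `-`)))
                if (den > 0) sum(pi_ * si) / den else 0 }
      cplx <- if (nvp > 0) {
        num <- outer(lev, lev, function(a, b) abs(a - b)) *
          (outer(pi_ * si, rep(1, ngp)) + outer(rep(1, ngp), pi_ * si)) /
          (outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_))
        sum(num) / nvp
      } else 0
      strength <- { den <- sum(si)
                    if (den > 0) sum((outer(pi_, pi_, `+`)) * outer(lev, lev, `-`)^2) / den
                    else 0 }
      c(ngtdm_Coarseness = coarse, ngtdm_Contrast = contrast,
        ngtdm_Busyness = busy, ngtdm_Complexity = cplx,
        ngtdm_Strength = strength)
    })
}

# the 93 features of one filtered image within one ROI
features_one_image <- function(filtered, mask, n_bins, voxel_volume) {
  disc <- discretize(filtered, mask, n_bins)
  raw <- filtered$voxels[mask$voxels == 1L]
  fo <- first_order_features(disc, raw, voxel_volume)
  out <- c(stats::setNames(fo, paste0("firstorder_", names(fo))),
           texture_features(texture_matrix(disc, "GLCM")),
           texture_features(texture_matrix(disc, "GLDM")),
           texture_features(texture_matrix(disc, "GLRLM")),
           texture_features(texture_matrix(disc, "GLSZM")),
           texture_features(texture_matrix(disc, "NGTDM")))
  out
}

#' Extract the full feature vector for a volume and its ROIs
#'
#' Applies the filter bank, discretizes each filtered image over each mask,
#' and computes the 93-feature set (18 first-order + 24 GLCM + 14 GLDM +
#' 16 GLRLM + 16 GLSZM + 5 NGTDM) per filtered image. Under the default
#' 14-filter bank this yields 14 x 93 = 1302 features per ROI. Feature ids
#' follow `<filter>_<class>_<name>`. Deterministic.
#'
#' @param volume an [image_volume()].
#' @param masks a single [roi_mask()] or a named list of them.
#' @param bank a [filter_bank()] data.frame.
#' @param n_bins discretization bin count (default 32).
#' @return data.frame with columns `roi`, `filter`, `class`, `feature`,
#'   `feature_id`, `value`.
#' @export
extract_features <- function(volume, masks, bank = filter_bank(), n_bins = 32) {
  if (inherits(masks, "roi_mask")) {
    masks <- stats::setNames(list(masks), masks$roi_name)
  }
  voxvol <- prod(volume$spacing)
  res <- vector("list", nrow(bank) * length(masks))
  ridx <- 0L
  for (b in seq_len(nrow(bank))) {
    spec <- bank[b, ]
    filtered <- suppressWarnings(apply_filter(volume, spec))
    for (m in seq_along(masks)) {
      vals <- features_one_image(filtered, masks[[m]], n_bins, voxvol)
      cls <- sub("_.*$", "", names(vals))
      ridx <- ridx + 1L
      res[[ridx]] <- data.frame(
        roi = names(masks)[m] %||% masks[[m]]$roi_name,
        filter = spec$filter,
        class = cls,
        feature = sub("^[a-z]+_", "", names(vals)),
        feature_id = paste0(spec$filter, "_", names(vals)),
        value = unname(vals))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (any(!is.finite(out$value)))
    stop("non-finite feature value produced: ",
         paste(utils::head(out$feature_id[!is.finite(out$value)], 5), collapse = ", "),
         call. = FALSE)
  out
}
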