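#' Image characteristics of one filtered image within an ROI
#'
#' Entropy and uniformity of the 32-bin discretized histogram and variance
#' of the raw in-mask intensities — the first-order metrics used to explain
#' repeatability differences (complexity, homogeneity, contrast).
#'
#' @param volume a (filtered) [image_volume()].
#' @param mask the [roi_mask()].
#' @param n_bins discretization bin count.
#' @return Named numeric: `entropy` (bits), `uniformity`, `variance`.
#' @export
image_characteristics_one <- function(volume, mask, n_bins = 32) {
  disc <- discretize(volume, mask, n_bins)
  lv <- disc$levels[disc$levels >= 0]
  p <- tabulate(lv + 1L, nbins = n_bins)
  p <- p / sum(p)
  pnz <- p[p > 0]
  v <- volume$voxels[mask$voxels == 1L]
  c(entropy = -sum(pnz * log2(pnz)),
    uniformity = sum(pnz^2),
    variance = mean((v - mean(v))^2))
}

#' Mean image characteristics per (filter, ROI, modality)
#'
#' Computes entropy/uniformity/variance of the unperturbed preprocessed
#' (filtered) images for every subject and averages over subjects per
#' (filter, ROI, modality) — the image-appearance side of the
#' characteristics-vs-repeatability correlation analysis.
#'
#' @param cohort a [make_cohort()] result (or any list of subjects with
#'   `ct`, `dose`, `masks`).
#' @param bank a [filter_bank()].
#' @param modalities subset of `c("CT", "DOSE")`.
#' @param n_bins discretization bin count.
#' @return data.frame: `filter`, `roi`, `modality`, `mean_entropy`,
#'   `mean_uniformity`, `mean_variance`, `n_subjects`.
#' @export
image_characteristics <- function(cohort, bank = filter_bank(),
                                  modalities = c("CT", "DOSE"), n_bins = 32) {
  rows <- list()
  for (subj in cohort) {
    for (mod in modalities) {
      vol <- if (mod == "CT") subj$ct else subj$dose
      for (b in seq_len(nrow(bank))) {
        filtered <- suppressWarnings(apply_filter(vol, bank[b, ]))
        for (m in seq_along(subj$masks)) {
          ch <- image_characteristics_one(filtered, subj$masks[[m]], n_bins)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subj$subject_id, modality = mod,
            filter = bank$filter[b], roi = names(subj$masks)[m],
            entropy = ch["entropy"], uniformity = ch["uniformity"],
            variance = ch["variance"])
        }
      }
    }
  }
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  agg <- stats::aggregate(long[, c("entropy", "uniformity", "variance")],
                          by = list(filter = long$filter, roi = long$roi,
                                    modality = long$modality), FUN = mean)
  cnt <- stats::aggregate(list(n_subjects = long$entropy),
                          by = list(filter = long$filter, roi = long$roi,
                                    modality = long$modality), FUN = length)
  out <- merge(agg, cnt, by = c("filter", "roi", "modality"))
  names(out)[names(out) %in% c("entropy", "uniformity", "variance")] <-
    c("mean_entropy", "mean_uniformity", "mean_variance")
  out
}

#' Join characteristics with mean repeatability
#'
#' Attaches the mean ICC (averaged over the features of each filter) to each
#' (filter, ROI, modality) characteristics record.
#'
#' @param characteristics an [image_characteristics()] result.
#' @param icc an [icc_table()] result with a `filter` column.
#' @return The characteristics data.frame with a `mean_icc` column; records
#'   without a matching ICC stratum are dropped with a warning.
#' @export
characteristics_with_icc <- function(characteristics, icc) {
  micc <- stats::aggregate(list(mean_icc = icc$icc),
                           by = list(filter = icc$filter, roi = icc$roi,
                                     modality = icc$modality), FUN = mean)
  out <- merge(characteristics, micc, by = c("filter", "roi", "modality"))
  if (nrow(out) < nrow(characteristics))
    warning(nrow(characteristics) - nrow(out),
            " characteristics records had no ICC stratum and were dropped",
            call. = FALSE)
  out
}

#' Pearson correlation between an image characteristic and mean ICC
#'
#' Pools all (filter, ROI) points of one modality and correlates the chosen
#' characteristic with the mean ICC, with a two-sided p-value.
#'
#' @param records a [characteristics_with_icc()] result (one modality or
#'   filtered by the caller; all rows are pooled).
#' @param characteristic `"entropy"`, `"uniformity"`, or `"variance"`.
#' @return list `r`, `p`, `n`, `characteristic`.
#' @export
correlate_characteristic <- function(records,
                                     characteristic = c("entropy", "uniformity",
                                                        "variance")) {
  characteristic <- match.arg(characteristic)
  x <- records[[paste0("mean_", characteristic)]]
  y <- records$mean_icc
  if (length(x) < 3) stop("need at least 3 records for a correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in ",
         if (stats::sd(x) == 0) characteristic else "mean ICC", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(characteristic = characteristic, r = unname(ct$estimate),
       p = ct$p.value, n = length(x))
}

#' All characteristic-vs-ICC correlations per modality
#'
#' @param records a [characteristics_with_icc()] result.
#' @return data.frame: modality, characteristic, r, p, n.
#' @export
correlate_characteristics <- function(records) {
  out <- list()
  for (mod in unique(records$modality)) {
    sub <- records[records$modality == mod, ]
    for (ch in c("entropy", "uniformity", "variance")) {
      cc <- correlate_characteristic(sub, ch)
      out[[length(out) + 1L]] <- data.frame(
        modality = mod, characteristic = ch, r = cc$r, p = cc$p, n = cc$n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
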