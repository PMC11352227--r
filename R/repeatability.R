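#' One-way random-effects intraclass correlation (ICC(1,1))
#'
#' Quantifies feature stability across perturbations relative to
#' between-subject variation. With `n` subjects (rows) and `k` perturbations
#' (columns):
#' \deqn{MSR = k \sum_i (\bar x_i - \bar x)^2 / (n-1), \quad
#'       MSW = \sum_i \sum_j (x_{ij} - \bar x_i)^2 / (n(k-1))}
#' \deqn{ICC = (MSR - MSW) / (MSR + (k-1) MSW)}
#' A matrix with zero variance everywhere (MSR = MSW = 0) is returned as
#' ICC = 1 with `degenerate = TRUE` (the ratio is 0/0 and the measurement is
#' perfectly stable). Raw (possibly negative) ICC values are reported;
#' binarization at `threshold` handles classification.
#'
#' @param x numeric matrix, subjects x perturbations (n >= 3, k >= 2).
#' @param threshold high-repeatability cut-off (default 0.9, compared with
#'   `>=`).
#' @param denominator `"k-1"` (the standard one-way form, default) or
#'   `"k+1"` (audit variant).
#' @return An `icc_oneway` object: `icc`, `MSR`, `MSW`, `n`, `k`,
#'   `high_repeatable`, `degenerate`.
#' @export
icc_oneway <- function(x, threshold = 0.9, denominator = c("k-1", "k+1")) {
  denominator <- match.arg(denominator)
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2)
    stop("parameter error: ICC needs >= 3 subjects and >= 2 perturbations",
         call. = FALSE)
  if (any(!is.finite(x))) stop("ICC input contains non-finite values", call. = FALSE)
  xi <- rowMeans(x)
  xbar <- mean(x)
  msr <- k * sum((xi - xbar)^2) / (n - 1)
  msw <- sum((x - xi)^2) / (n * (k - 1))
  kden <- if (denominator == "k-1") k - 1 else k + 1
  degenerate <- (msr == 0 && msw == 0)
  icc <- if (degenerate) 1 else (msr - msw) / (msr + kden * msw)
  structure(list(icc = icc, MSR = msr, MSW = msw, n = n, k = k,
                 threshold = threshold,
                 high_repeatable = icc >= threshold,
                 degenerate = degenerate),
            class = "icc_oneway")
}

#' @export
print.icc_oneway <- function(x, ...) {
  cat(sprintf("One-way random-effects ICC(1,1): %.4f  (%s-repeatable at %.2g)\n",
              x$icc, if (x$high_repeatable) "high" else "low", x$threshold))
  cat(sprintf("  MSR = %.6g, MSW = %.6g, n = %d subjects, k = %d perturbations\n",
              x$MSR, x$MSW, x$n, x$k))
  if (x$degenerate) cat("  note: all-equal input; ICC defined as 1\n")
  invisible(x)
}

#' @export
coef.icc_oneway <- function(object, ...) c(icc = object$icc)

#' Per-feature ICC table from a long feature table
#'
#' Computes one ICC per feature per (modality, roi) stratum. The feature
#' table is long-format with columns `subject`, `perturbation`, `modality`,
#' `roi`, `feature_id`, `value` (plus optional `filter`, `class` carried
#' through). Features missing some perturbations use the available columns
#' pairwise; strata with fewer than 3 subjects or 2 perturbations are
#' skipped with a warning.
#'
#' @param features long-format data.frame as produced by the extraction
#'   stage.
#' @param threshold binarization threshold (default 0.9).
#' @param denominator see [icc_oneway()].
#' @return data.frame with one row per (modality, roi, feature_id):
#'   `icc`, `MSR`, `MSW`, `n`, `k`, `high_repeatable`, plus `filter` and
#'   `class` when present.
#' @export
icc_table <- function(features, threshold = 0.9, denominator = c("k-1", "k+1")) {
  denominator <- match.arg(denominator)
  needed <- c("subject", "perturbation", "modality", "roi", "feature_id", "value")
  if (!all(needed %in% names(features)))
    stop("feature table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  strata <- unique(features[, c("modality", "roi")])
  out <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- features[features$modality == strata$modality[s] &
                    features$roi == strata$roi[s], ]
    subjects <- sort(unique(sub$subject))
    perturbs <- sort(unique(sub$perturbation))
    fids <- unique(sub$feature_id)
    n <- length(subjects); k <- length(perturbs)
    if (n < 3 || k < 2) {
      warning(sprintf("stratum (%s, %s) below minimum size (n=%d, k=%d); skipped",
                      strata$modality[s], strata$roi[s], n, k), call. = FALSE)
      next
    }
    a <- array(NA_real_, dim = c(n, k, length(fids)),
               dimnames = list(subjects, perturbs, fids))
    a[cbind(match(sub$subject, subjects), match(sub$perturbation, perturbs),
            match(sub$feature_id, fids))] <- sub$value
    kden <- if (denominator == "k-1") "k-1" else "k+1"
    rows <- lapply(seq_along(fids), function(f) {
      m <- a[, , f]
      keep <- colSums(is.na(m)) == 0    # pairwise-complete perturbation columns
      m <- m[, keep, drop = FALSE]
      if (ncol(m) < 2) return(NULL)
      r <- icc_oneway(m, threshold, kden)
      data.frame(modality = strata$modality[s], roi = strata$roi[s],
                 feature_id = fids[f], icc = r$icc, MSR = r$MSR, MSW = r$MSW,
                 n = r$n, k = r$k, high_repeatable = r$high_repeatable)
    })
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (!length(out)) stop("no stratum met the minimum size for ICC", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # carry filter/class annotation when derivable from the feature table
  ann <- unique(features[, intersect(c("feature_id", "filter", "class"),
                                     names(features))])
  if (all(c("filter", "class") %in% names(ann)))
    res <- merge(res, ann, by = "feature_id", sort = FALSE)
  res
}

#' Mean and SD of ICC per filter or feature class
#'
#' @param icc an [icc_table()] result carrying `filter` and `class` columns.
#' @param by `"filter"` or `"class"`.
#' @return data.frame of group, modality, roi, `mean_icc`, `sd_icc`,
#'   `n_features`.
#' @export
summarize_icc <- function(icc, by = c("filter", "class")) {
  by <- match.arg(by)
  if (!by %in% names(icc))
    stop("icc table lacks a '", by, "' column", call. = FALSE)
  agg <- stats::aggregate(icc$icc,
                          by = list(group = icc[[by]], modality = icc$modality,
                                    roi = icc$roi),
                          FUN = function(v) c(mean = mean(v),
                                              sd = if (length(v) > 1) stats::sd(v) else 0,
                                              n = length(v)))
  out <- data.frame(group = agg$group, modality = agg$modality, roi = agg$roi,
                    mean_icc = agg$x[, "mean"], sd_icc = agg$x[, "sd"],
                    n_features = agg$x[, "n"])
  out[order(out$modality, out$roi, out$group), , drop = FALSE]
}

#' CT-vs-dose binarized repeatability agreement
#'
#' Classifies every feature into `both_high`, `both_low`, `ct_only`
#' (repeatable in CT only), or `dose_only` by the binarized ICC of the two
#' modalities, per ROI, and summarizes category ratios per filter and per
#' feature class.
#'
#' @param ct_icc,dose_icc [icc_table()] results for the two modalities.
#' @return list with `records` (per-feature categories) and `by_filter`,
#'   `by_class` ratio summaries.
#' @export
compare_modalities <- function(ct_icc, dose_icc) {
  keys <- c("feature_id", "roi")
  m <- merge(ct_icc[, c(keys, "high_repeatable",
                        intersect(c("filter", "class"), names(ct_icc)))],
             dose_icc[, c(keys, "high_repeatable")],
             by = keys, suffixes = c("_ct", "_dose"))
  lost <- setdiff(union(paste(ct_icc$feature_id, ct_icc$roi),
                        paste(dose_icc$feature_id, dose_icc$roi)),
                  paste(m$feature_id, m$roi))
  if (length(lost))
    stop("reconciliation error: unmatched feature ids: ",
         paste(utils::head(lost, 5), collapse = ", "), call. = FALSE)
  m$category <- ifelse(m$high_repeatable_ct & m$high_repeatable_dose, "both_high",
                ifelse(!m$high_repeatable_ct & !m$high_repeatable_dose, "both_low",
                ifelse(m$high_repeatable_ct, "ct_only", "dose_only")))
  ratio_by <- function(col) {
    if (!col %in% names(m)) return(NULL)
    tab <- table(m[[col]], factor(m$category, levels = c("both_high", "both_low",
                                                         "ct_only", "dose_only")))
    data.frame(group = rownames(tab),
               both_high = as.numeric(tab[, "both_high"]) / rowSums(tab),
               both_low = as.numeric(tab[, "both_low"]) / rowSums(tab),
               ct_only = as.numeric(tab[, "ct_only"]) / rowSums(tab),
               dose_only = as.numeric(tab[, "dose_only"]) / rowSums(tab),
               n = as.numeric(rowSums(tab)))
  }
  list(records = m[, c("feature_id", "roi",
                       intersect(c("filter", "class"), names(m)), "category")],
       by_filter = ratio_by("filter"),
       by_class = ratio_by("class"))
}
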