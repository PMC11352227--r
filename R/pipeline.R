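#' Fit a perturbation-repeatability study on a synthetic cohort
#'
#' The package's top-level entry point. It composes the full analysis:
#' generate (or accept) a phantom cohort; draw `k` rigid perturbations plus
#' contour randomizations per subject; extract the feature vector for every
#' (subject, perturbation, modality, ROI); estimate the one-way
#' random-effects ICC per feature; binarize at `threshold` and classify
#' CT-vs-dose agreement; and correlate mean image characteristics (entropy,
#' uniformity, variance of the unperturbed preprocessed images) with mean
#' ICC. Every random draw derives deterministically from `config$seed`.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param k perturbations per subject (>= 2; 40 emulates a full study).
#' @param config a [phantom_config()]; its `seed` is the master seed.
#' @param bank a [filter_bank()] (default: the 14-filter bank).
#' @param amplitude contour-randomization strength, voxels.
#' @param sigma_smooth displacement-field smoothing, voxels.
#' @param between_subject_sd between-subject intensity offset SD, HU.
#' @param modalities subset of `c("CT", "DOSE")`.
#' @param rois ROI names to analyse (default: all phantom ROIs).
#' @param n_bins gray-level discretization bins.
#' @param threshold ICC binarization threshold.
#' @param cohort optionally, a precomputed [make_cohort()] result.
#' @param verbose print stage progress?
#' @return An object of class `repeatability_study` with components
#'   `features` (long table), `icc`, `summary_filter`, `summary_class`,
#'   `agreement`, `characteristics`, `correlations`, and the settings used.
#' @export
repeatability_study <- function(n_subjects = 5, k = 5,
                                config = phantom_config(),
                                bank = filter_bank(),
                                amplitude = 3, sigma_smooth = 5,
                                between_subject_sd = 20,
                                modalities = c("CT", "DOSE"),
                                rois = NULL, n_bins = 32, threshold = 0.9,
                                cohort = NULL, verbose = FALSE) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  if (k < 2) stop("parameter error: k must be >= 2", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage phantom: %d subjects", n_subjects)
  if (is.null(cohort)) cohort <- make_cohort(n_subjects, config, between_subject_sd)
  if (!is.null(rois)) {
    cohort <- lapply(cohort, function(s) { s$masks <- s$masks[rois]; s })
  }

  say("stage perturb+extract: k = %d, %d filters", k, nrow(bank))
  feats <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    pset <- sample_perturbation_set(mix_seed(config$seed, 2000L, i), k)
    perts <- perturb_subject(subj$ct, subj$dose, subj$masks, pset,
                             amplitude, sigma_smooth)
    per_subj <- list()
    for (pert in perts) {
      for (mod in modalities) {
        vol <- if (mod == "CT") pert$ct else pert$dose
        f <- extract_features(vol, pert$masks, bank, n_bins)
        f$subject <- subj$subject_id
        f$perturbation <- pert$index
        f$modality <- mod
        per_subj[[length(per_subj) + 1L]] <- f
      }
    }
    feats[[i]] <- do.call(rbind, per_subj)
    say("  subject %s done", subj$subject_id)
  }
  features <- do.call(rbind, feats)

  say("stage icc")
  icc <- icc_table(features, threshold)
  s_filter <- summarize_icc(icc, "filter")
  s_class <- summarize_icc(icc, "class")

  agreement <- NULL
  if (all(c("CT", "DOSE") %in% modalities)) {
    say("stage agreement")
    agreement <- compare_modalities(icc[icc$modality == "CT", ],
                                    icc[icc$modality == "DOSE", ])
  }

  say("stage characteristics")
  chars <- image_characteristics(cohort, bank, modalities, n_bins)
  chars <- characteristics_with_icc(chars, icc)
  correlations <- correlate_characteristics(chars)

  structure(list(features = features, icc = icc,
                 summary_filter = s_filter, summary_class = s_class,
                 agreement = agreement, characteristics = chars,
                 correlations = correlations,
                 settings = list(n_subjects = length(cohort), k = k,
                                 config = config, bank = bank,
                                 amplitude = amplitude,
                                 sigma_smooth = sigma_smooth,
                                 between_subject_sd = between_subject_sd,
                                 modalities = modalities,
                                 rois = unique(features$roi),
                                 n_bins = n_bins, threshold = threshold),
                 call = match.call()),
            class = "repeatability_study")
}

#' @export
print.repeatability_study <- function(x, ...) {
  s <- x$settings
  cat("Perturbation-repeatability study\n")
  cat(sprintf("  %d subjects x %d perturbations, %d filters, %d bins, ROIs: %s\n",
              s$n_subjects, s$k, nrow(s$bank), s$n_bins,
              paste(s$rois, collapse = ", ")))
  nfeat <- length(unique(x$features$feature_id))
  cat(sprintf("  %d features per (volume, ROI); %d ICC estimates\n",
              nfeat, nrow(x$icc)))
  for (mod in s$modalities) {
    sub <- x$icc[x$icc$modality == mod, ]
    cat(sprintf("  %s: mean ICC %.3f, %.1f%% high-repeatable (ICC >= %.2g)\n",
                mod, mean(sub$icc), 100 * mean(sub$high_repeatable), s$threshold))
  }
  invisible(x)
}

#' @export
summary.repeatability_study <- function(object, ...) {
  out <- list(by_filter = object$summary_filter,
              by_class = object$summary_class,
              correlations = object$correlations,
              agreement_by_filter = object$agreement$by_filter)
  class(out) <- "summary.repeatability_study"
  out
}

#' @export
print.summary.repeatability_study <- function(x, ...) {
  cat("Mean ICC by image filter:\n")
  print(x$by_filter, row.names = FALSE, digits = 3)
  cat("\nMean ICC by feature class:\n")
  print(x$by_class, row.names = FALSE, digits = 3)
  cat("\nImage characteristics vs mean ICC (Pearson):\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  if (!is.null(x$agreement_by_filter)) {
    cat("\nCT-vs-dose binarized agreement by filter:\n")
    print(x$agreement_by_filter, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
plot.repeatability_study <- function(x, which = c("filters", "agreement",
                                                  "characteristics"), ...) {
  which <- match.arg(which)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  if (which == "filters") {
    sf <- x$summary_filter
    filters <- unique(sf$group)
    graphics::par(mar = c(9, 4, 2, 1))
    graphics::plot(NULL, xlim = c(0.5, length(filters) + 0.5), ylim = c(0, 1),
                   xaxt = "n", xlab = "", ylab = "mean ICC",
                   main = "Feature repeatability by image filter")
    graphics::axis(1, at = seq_along(filters), labels = filters, las = 2,
                   cex.axis = 0.7)
    cols <- c(CT = "purple", DOSE = "darkgreen")
    for (mod in unique(sf$modality)) {
      sub <- stats::aggregate(list(m = sf$mean_icc[sf$modality == mod]),
                              by = list(g = sf$group[sf$modality == mod]), mean)
      idx <- match(sub$g, filters)
      graphics::points(idx, sub$m, col = cols[mod], pch = 19)
      graphics::lines(idx[order(idx)], sub$m[order(idx)], col = cols[mod])
    }
    graphics::legend("bottomleft", legend = unique(sf$modality),
                     col = cols[unique(sf$modality)], pch = 19, bty = "n")
  } else if (which == "agreement") {
    if (is.null(x$agreement)) stop("study has no two-modality agreement", call. = FALSE)
    bf <- x$agreement$by_filter
    m <- t(as.matrix(bf[, c("both_high", "both_low", "ct_only", "dose_only")]))
    colnames(m) <- bf$group
    graphics::par(mar = c(9, 4, 2, 1))
    graphics::barplot(m, col = c("darkgreen", "grey60", "plum", "lightgreen"),
                      las = 2, cex.names = 0.7, ylab = "ratio of features",
                      main = "CT-vs-dose binarized repeatability agreement")
    graphics::legend("topright", legend = rownames(m), cex = 0.7,
                     fill = c("darkgreen", "grey60", "plum", "lightgreen"), bty = "n")
  } else {
    ch <- x$characteristics
    graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
    for (v in c("mean_entropy", "mean_uniformity", "mean_variance")) {
      graphics::plot(ch[[v]], ch$mean_icc, xlab = v, ylab = "mean ICC",
                     col = ifelse(ch$modality == "CT", "purple", "darkgreen"),
                     pch = 19, main = sub("mean_", "", v))
    }
  }
  invisible(x)
}

#' Write study outputs as CSV + JSON manifest
#'
#' Emits `icc_<modality>_<roi>.csv`, `agreement_<roi>.csv`, group summary
#' and characteristics/correlation CSVs, the long feature table, and a
#' `manifest.json` recording every setting. Re-running an identically
#' configured study reproduces the CSVs byte-identically.
#'
#' @param study a [repeatability_study()] result.
#' @param dir output directory (created if needed).
#' @param write_features also write the (large) long feature table?
#' @return `dir`, invisibly.
#' @export
write_study_outputs <- function(study, dir, write_features = TRUE) {
  stopifnot(inherits(study, "repeatability_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(df, name) {
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     file.path(dir, name), row.names = FALSE, quote = TRUE)
  }
  for (mod in unique(study$icc$modality))
    for (roi in unique(study$icc$roi))
      wcsv(study$icc[study$icc$modality == mod & study$icc$roi == roi, ],
           sprintf("icc_%s_%s.csv", tolower(mod), roi))
  if (!is.null(study$agreement)) {
    for (roi in unique(study$agreement$records$roi))
      wcsv(study$agreement$records[study$agreement$records$roi == roi, ],
           sprintf("agreement_%s.csv", roi))
    wcsv(study$agreement$by_filter, "agreement_by_filter.csv")
    wcsv(study$agreement$by_class, "agreement_by_class.csv")
  }
  wcsv(study$summary_filter, "summary_by_filter.csv")
  wcsv(study$summary_class, "summary_by_class.csv")
  wcsv(study$characteristics, "characteristics.csv")
  wcsv(study$correlations, "correlations.csv")
  if (write_features) wcsv(study$features, "features.csv")
  s <- study$settings
  manifest <- list(n_subjects = s$n_subjects, k = s$k,
                   seed = s$config$seed,
                   phantom = s$config[setdiff(names(s$config), "seed")],
                   filters = s$bank$filter, amplitude = s$amplitude,
                   sigma_smooth = s$sigma_smooth,
                   between_subject_sd = s$between_subject_sd,
                   modalities = s$modalities, rois = s$rois,
                   n_bins = s$n_bins, threshold = s$threshold)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Run the pipeline from a flat configuration
#'
#' Config-driven orchestration: phantom generation, perturbation, feature
#' extraction, ICC, agreement, and characteristics run in order, and all
#' outputs plus a manifest are written to `config$out_dir`. The
#' configuration is a plain list (or a YAML/JSON file path) with fields
#' `n_subjects`, `k`, `seed`, `amplitude`, `phantom` (arguments to
#' [phantom_config()]), `filters` (arguments to [filter_bank()]), `n_bins`,
#' `threshold`, `between_subject_sd`, `modalities`, `rois`, `out_dir`,
#' `write_features`.
#'
#' @param config list or path to a YAML/JSON file.
#' @return The [repeatability_study()] object, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml_load_file(config)
  }
  if (!is.null(config$k) && config$k < 2)
    stop("parameter error: k must be >= 2 (rejected before compute)", call. = FALSE)
  pc <- do.call(phantom_config, c(config$phantom %||% list(),
                                  list(seed = config$seed %||% 1L)))
  bank <- do.call(filter_bank, config$filters %||% list())
  study <- repeatability_study(
    n_subjects = config$n_subjects %||% 5,
    k = config$k %||% 5,
    config = pc, bank = bank,
    amplitude = config$amplitude %||% 3,
    sigma_smooth = config$sigma_smooth %||% 5,
    between_subject_sd = config$between_subject_sd %||% 20,
    modalities = config$modalities %||% c("CT", "DOSE"),
    rois = config$rois,
    n_bins = config$n_bins %||% 32,
    threshold = config$threshold %||% 0.9,
    verbose = isTRUE(config$verbose))
  if (!is.null(config$out_dir))
    write_study_outputs(study, config$out_dir,
                        write_features = !isFALSE(config$write_features))
  invisible(study)
}

# YAML is only needed when a YAML config is supplied; the yaml package is
# part of the supported stack but kept out of hard Imports
yaml_load_file <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  yaml::read_yaml(path)
}

#' Heterogeneity sweep: texture complexity vs feature repeatability
#'
#' Runs one [repeatability_study()] per tissue-heterogeneity level (the
#' number of tissue plateaus sweeps the in-ROI entropy), pools the
#' (filter, level) characteristics records, and correlates mean entropy,
#' uniformity, and variance with mean ICC. This reproduces, directionally,
#' the association between image complexity and feature repeatability:
#' entropy correlates positively and uniformity negatively with mean ICC.
#'
#' @param n_subjects subjects per heterogeneity level.
#' @param k perturbations per subject.
#' @param levels integer vector of `n_tissue_levels` values to sweep.
#' @param config base [phantom_config()] shared by all levels.
#' @param modalities modalities to analyse (default CT).
#' @param bank filter bank.
#' @param ... passed to [repeatability_study()].
#' @return list with `records` (pooled characteristics + mean ICC, one row
#'   per (filter, level, modality)) and `correlations`.
#' @export
heterogeneity_sweep <- function(n_subjects = 10, k = 10, levels = 1:6,
                                config = phantom_config(),
                                modalities = "CT", bank = filter_bank(), ...) {
  records <- list()
  roi <- list(TARGET = ellipsoid_mask(config$shape,
                                      radius_frac = c(0.32, 0.32, 0.34),
                                      spacing = config$spacing,
                                      roi_name = "TARGET"))
  for (lv in levels) {
    cfg <- config
    cfg$n_tissue_levels <- as.integer(lv)
    cfg$seed <- mix_seed(config$seed, 7000L, lv)
    cohort <- make_cohort(n_subjects, cfg, masks = roi)
    st <- repeatability_study(n_subjects = n_subjects, k = k, config = cfg,
                              bank = bank, modalities = modalities,
                              cohort = cohort, ...)
    ch <- st$characteristics
    ch$roi <- sprintf("level%d", lv)
    records[[length(records) + 1L]] <- ch
  }
  pooled <- do.call(rbind, records)
  list(records = pooled, correlations = correlate_characteristics(pooled))
}

#' Summarize a completed run directory as a markdown report
#'
#' Re-parses the CSV outputs of [run_pipeline()]/[write_study_outputs()] and
#' writes `report.md` with the mean-ICC-by-filter/class tables, the
#' binarized agreement ratios, and the characteristics correlations.
#' Missing stage outputs are listed; the report is still produced for the
#' available stages.
#'
#' @param run_dir directory written by [write_study_outputs()].
#' @return Path to `report.md`, invisibly.
#' @export
report <- function(run_dir) {
  if (!dir.exists(run_dir)) stop("no run directory '", run_dir, "'", call. = FALSE)
  wanted <- c("summary_by_filter.csv", "summary_by_class.csv",
              "correlations.csv", "agreement_by_filter.csv",
              "agreement_by_class.csv", "characteristics.csv")
  present <- file.exists(file.path(run_dir, wanted))
  if (!any(present))
    stop("missing artifacts in '", run_dir, "': ",
         paste(wanted[!present], collapse = ", "), call. = FALSE)
  md <- c("# Perturbation-repeatability report", "")
  if (any(!present))
    md <- c(md, paste("Missing stage outputs:",
                      paste(wanted[!present], collapse = ", ")), "")
  md_table <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) signif(v, 6))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste("|", paste(unlist(df[i, ]), collapse = " | "), "|"), ""))
  }
  add_section <- function(md, title, csv) {
    f <- file.path(run_dir, csv)
    if (!file.exists(f)) return(md)
    c(md, paste("##", title), "", md_table(utils::read.csv(f)), "")
  }
  md <- add_section(md, "Mean ICC by image filter", "summary_by_filter.csv")
  md <- add_section(md, "Mean ICC by feature class", "summary_by_class.csv")
  md <- add_section(md, "CT-vs-dose agreement by filter", "agreement_by_filter.csv")
  md <- add_section(md, "CT-vs-dose agreement by class", "agreement_by_class.csv")
  md <- add_section(md, "Image characteristics vs mean ICC", "correlations.csv")
  out <- file.path(run_dir, "report.md")
  writeLines(md, out)
  invisible(out)
}
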