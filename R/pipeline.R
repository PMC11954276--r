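#' Read a NIfTI volume
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return Numeric array with attributes from the header.
#' @export
read_nifti_vol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  img
}

#' Write an array as NIfTI-1
#'
#' @param arr 3D or 4D numeric array.
#' @param path Output path.
#' @param voxel_mm Voxel sizes in mm.
#' @param tr Repetition time in seconds for 4D data.
#' @return The path, invisibly.
#' @export
write_nifti_vol <- function(arr, path, voxel_mm = c(3, 3, 3), tr = NULL) {
  pd <- if (length(dim(arr)) == 4L) c(rep_len(voxel_mm, 3L),
                                      if (is.null(tr)) 1 else tr)
        else rep_len(voxel_mm, 3L)
  img <- RNifti::asNifti(arr, pixdim = pd)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param n_ci,n_cp Cohort sizes.
#' @param grid_shape,n_timepoints,effect_synchrony,effect_homotopy,noise_sd,seed
#'   Passed to [cohort_spec()].
#' @param metrics Derivative maps to compute.
#' @param combinations List of metric subsets to model; default all
#'   non-empty subsets of `metrics`.
#' @param band,fwhm_mm,r_threshold Derivative parameters.
#' @param n_bins,wavelet Radiomics parameters.
#' @param prune_threshold,n_folds,split_ratio Selection/split parameters.
#' @param n_tests Bonferroni family size for associations.
#' @param blob_radius Hippocampus blob radius.
#' @return A `run_config` list.
#' @export
run_config <- function(n_ci = 30L, n_cp = 30L,
                       grid_shape = c(12L, 12L, 12L), n_timepoints = 64L,
                       effect_synchrony = 0, effect_homotopy = 0,
                       noise_sd = 1, seed = 1L,
                       metrics = c("ReHo", "VMHC"),
                       combinations = NULL,
                       band = c(0.01, 0.1), fwhm_mm = 6, r_threshold = 0.25,
                       n_bins = 32L, wavelet = "coif1",
                       prune_threshold = 0.9, n_folds = 10L,
                       split_ratio = 0.7, n_tests = 7L, blob_radius = 2) {
  spec <- cohort_spec(n_ci, n_cp, grid_shape = grid_shape,
                      n_timepoints = n_timepoints,
                      effect_synchrony = effect_synchrony,
                      effect_homotopy = effect_homotopy,
                      noise_sd = noise_sd, seed = seed)
  structure(list(spec = spec, metrics = metrics, combinations = combinations,
                 band = band, fwhm_mm = fwhm_mm, r_threshold = r_threshold,
                 n_bins = n_bins, wavelet = wavelet,
                 prune_threshold = prune_threshold, n_folds = n_folds,
                 split_ratio = split_ratio, n_tests = n_tests,
                 blob_radius = blob_radius), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Extract per-metric radiomics tables for a cohort
#'
#' Streams through the cohort subject by subject: generates the BOLD volume,
#' computes the requested derivative maps, and extracts the 819-feature
#' vector of each map over the bilateral hippocampus ROI.
#'
#' @param config A [run_config()].
#' @param progress Print per-subject progress lines.
#' @return List with `tables` (per metric, subjects x 819), `clinical`,
#'   `groups`, `mask`, `severity`.
#' @export
cohort_features <- function(config, progress = FALSE) {
  spec <- config$spec
  sim <- simulate_cohort(spec, config$blob_radius, keep_bold = FALSE)
  roi <- sim$mask > 0L
  geom <- roi_geometry(roi)
  n <- length(sim$groups)
  tables <- stats::setNames(
    lapply(config$metrics, function(m) matrix(NA_real_, n, 819L)),
    config$metrics)
  for (i in seq_len(n)) {
    b <- generate_bold(spec, sim$mask, sim$groups[i], i, sim$severity[i])
    maps <- derive_maps(b, config$metrics, config$band, config$fwhm_mm,
                        config$r_threshold)
    for (m in config$metrics) {
      fv <- extract_all(maps[[m]]$final, roi, spec$voxel_mm,
                        config$n_bins, config$wavelet, geom)
      if (i == 1L) colnames(tables[[m]]) <- names(fv)
      tables[[m]][i, ] <- fv
    }
    if (progress) message("subject ", i, "/", n, " done")
  }
  list(tables = tables, clinical = sim$clinical, groups = sim$groups,
       mask = sim$mask, severity = sim$severity)
}

#' Run the full analysis pipeline
#'
#' simulate -> derive -> extract -> split -> select/train/evaluate per metric
#' combination -> clinical associations, with a manifest of content digests
#' for the deterministic stages.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @param progress Verbose per-stage output.
#' @return List with `features`, `clinical`, `split`, `results`,
#'   `associations`, `summary`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, progress = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  feats <- stage("extract", cohort_features(config, progress))
  split <- stage("split", split_cohort(feats$groups, config$split_ratio,
                                       seed = config$spec$seed))
  subsets <- config$combinations
  results <- stage("model", combination_sweep(
    feats$tables, feats$groups, split, subsets = subsets,
    prune_threshold = config$prune_threshold, n_folds = config$n_folds,
    seed = config$spec$seed))

  summary <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    do.call(rbind, lapply(c("train", "validation"), function(cohort) {
      lr <- r$logistic[[cohort]]
      rs <- r$radscore[[cohort]]
      data.frame(combination = nm, cohort = cohort,
                 auc_lr = lr$auc, auc_lr_lo = lr$auc_ci[1L],
                 auc_lr_hi = lr$auc_ci[2L], acc_lr = lr$acc,
                 sen_lr = lr$sen, spe_lr = lr$spe,
                 auc_rad = rs$auc, acc_rad = rs$acc,
                 sen_rad = rs$sen, spe_rad = rs$spe,
                 stringsAsFactors = FALSE)
    }))
  }))

  # associations: selected features of the first (or richest) combination
  best <- results[[length(results)]]
  sel_names <- best$selection$selected
  full <- do.call(cbind, lapply(names(feats$tables), function(m) {
    x <- feats$tables[[m]]
    colnames(x) <- paste0(m, "_", colnames(x))
    x
  }))
  nrm <- normalize_features(full)
  sel_present <- intersect(sel_names, colnames(nrm$train))
  assoc <- stage("associate", associate_features(
    nrm$train[, sel_present, drop = FALSE], feats$clinical,
    n_tests = config$n_tests))

  manifest <- list(
    config_digest = digest_object(unclass(config)),
    seed = config$spec$seed,
    n_subjects = length(feats$groups),
    feature_digest = digest_object(feats$tables),
    split_digest = digest_object(split),
    summary_digest = digest_object(summary),
    timestamp = format(Sys.time(), tz = "UTC"))

  out <- list(features = feats$tables, clinical = feats$clinical,
              groups = feats$groups, split = split, results = results,
              associations = assoc, summary = summary, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(feats$clinical, file.path(out_dir, "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(assoc))
      utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    best_model <- best$radscore$model
    jsonlite::write_json(
      list(weights = as.list(best_model$weights),
           intercept = best_model$intercept,
           youden_threshold = best_model$youden_threshold,
           lambda = best$selection$lambda_selected),
      file.path(out_dir, "radscore_model.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}

# Content digest of an R object, via serialisation to a temporary file and
# tools::md5sum (version 2 serialisation for cross-session stability).
digest_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
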