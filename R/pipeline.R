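#' Resolved run configuration
#'
#' Bundles every setting that affects a measurement so reports can embed it
#' verbatim for provenance. Values may come from a JSON or YAML config file
#' (`load_run_config()`); explicit arguments win over file values.
#'
#' @param segmentation a [segmentation_config()].
#' @param antialias_sigma surface-reconstruction anti-aliasing in voxels
#'   (see [compute_hii_for_mask()]).
#' @param smoothing `"off"` or `list(iterations =, passband =)` for Taubin
#'   mesh smoothing.
#' @param expansion an [expansion_rule()].
#' @param seed integer seed for any stochastic step.
#' @return An object of class `run_config`.
#' @export
run_config <- function(segmentation = segmentation_config(),
                       antialias_sigma = 1.5,
                       smoothing = "off",
                       expansion = expansion_rule(),
                       seed = 1L) {
  structure(list(segmentation = segmentation,
                 antialias_sigma = antialias_sigma,
                 smoothing = smoothing,
                 expansion = expansion,
                 seed = as.integer(seed)),
            class = "run_config")
}

.config_as_list <- function(config) {
  list(segmentation = unclass(config$segmentation),
       antialias_sigma = config$antialias_sigma,
       smoothing = config$smoothing,
       expansion = unclass(config$expansion),
       seed = config$seed)
}

#' Load a run configuration from a JSON or YAML file
#'
#' @param path config file; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @param ... overrides applied on top of the file values (flags win).
#' @return A [run_config()].
#' @export
load_run_config <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = , yml = yaml::read_yaml(path),
    stop_hii("hii_io_error", sprintf("unsupported config format: .%s", ext)))
  over <- list(...)
  vals[names(over)] <- over
  seg <- do.call(segmentation_config, vals$segmentation %||% list())
  exp_rule <- do.call(expansion_rule, vals$expansion %||% list())
  run_config(segmentation = seg,
             antialias_sigma = vals$antialias_sigma %||% 1.5,
             smoothing = vals$smoothing %||% "off",
             expansion = exp_rule,
             seed = vals$seed %||% 1L)
}

.read_any_volume <- function(input) {
  if (dir.exists(input)) read_dicom_series(input) else read_nifti(input)
}

#' Measure one case end to end
#'
#' Read a CT volume (NIfTI file or DICOM series directory), threshold-
#' segment the hematoma, subtract an optional exclusion mask (e.g.
#' intraventricular blood), reconstruct the surface and report the shape
#' metrics. The report embeds the resolved configuration.
#'
#' @param input path to a NIfTI file or a DICOM series directory.
#' @param exclusion optional path to a NIfTI exclusion mask.
#' @param config a [run_config()].
#' @param case_id identifier for the report.
#' @param out optional path: write the report as JSON.
#' @return The case report (a list), invisibly when `out` is given.
#' @export
run_case <- function(input, exclusion = NULL, config = run_config(),
                     case_id = basename(input), out = NULL) {
  volume <- .read_any_volume(input)
  mask <- segment_hematoma(volume, config$segmentation)
  if (!is.null(exclusion)) {
    excl <- read_mask(exclusion)
    if (sum(excl$voxels) == 0L)
      warning("exclusion mask is empty; nothing excluded")
    mask <- apply_exclusion_mask(mask, excl)
    if (sum(mask$voxels) == 0L)
      stop_hii("hii_empty_segmentation",
               "exclusion mask removed the entire segmentation")
  }
  if (min(dim(mask$voxels)) < 4L)
    warning("borderline resolution: fewer than 4 voxels along an axis")
  metrics <- compute_hii_for_mask(
    mask, antialias_sigma = config$antialias_sigma,
    smoothing = if (identical(config$smoothing, "off")) NULL
                else config$smoothing)
  report <- case_report(metrics, case_id = case_id,
                        segmentation = config$segmentation,
                        antialias_sigma = config$antialias_sigma,
                        smoothing = if (identical(config$smoothing, "off"))
                          NULL else config$smoothing)
  report$config <- .config_as_list(config)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

.COHORT_REQUIRED <- c("case_id", .COHORT_PREDICTORS, "expansion")

#' Full cohort analysis: baseline table to ROC
#'
#' Runs the complete statistical chain on a cohort table: baseline
#' comparison with the normality gate, univariate logistic screen of every
#' covariate, selection at p < 0.1, the adjusted multivariate model,
#' Hosmer-Lemeshow calibration of that model, and ROC/Youden analysis of
#' the irregularity index.
#'
#' @param table a data.frame, or path to a CSV, with the documented cohort
#'   columns (`case_id`, `age`, `female`, `alcohol`, `smoking`,
#'   `hypertension`, `diabetes`, `gcs`, `onset_to_ct_h`,
#'   `baseline_volume_mL`, `hii`, `expansion`).
#' @param out optional path: write the JSON report.
#' @param text_out optional path: write a plain-text rendering.
#' @return An object of class `hii_cohort_report`.
#' @export
run_cohort <- function(table, out = NULL, text_out = NULL) {
  records <- if (is.character(table)) {
    if (!file.exists(table))
      stop_hii("hii_io_error", sprintf("file not found: %s", table))
    utils::read.csv(table)
  } else as.data.frame(table)
  missing_cols <- setdiff(.COHORT_REQUIRED, names(records))
  if (length(missing_cols))
    stop_hii("hii_stats_error", sprintf(
      "cohort table is missing columns: %s",
      paste(missing_cols, collapse = ", ")))
  if (length(unique(records$expansion)) != 2L)
    stop_hii("hii_stats_error", "outcome 'expansion' must contain both classes")

  baseline <- summarize_baseline(records)
  univ <- univariate_logistic(records)
  selected <- select_for_multivariate(univ)
  adjusted <- if (length(selected) >= 1L)
    fit_logistic(records, "expansion", selected) else NULL
  hl <- if (!is.null(adjusted))
    hosmer_lemeshow(adjusted$fit$fitted.values, records$expansion) else NULL
  roc <- roc_youden(records$hii, records$expansion)

  report <- structure(list(
    n = nrow(records),
    n_expansion = sum(records$expansion == 1),
    baseline = baseline,
    univariate = univ,
    selected = selected,
    adjusted = adjusted,
    hosmer_lemeshow = hl,
    roc = roc), class = "hii_cohort_report")

  if (!is.null(out)) {
    json <- list(
      n = report$n, n_expansion = report$n_expansion,
      baseline = baseline,
      univariate = univ,
      selected = selected,
      adjusted = if (!is.null(adjusted)) adjusted$table,
      hosmer_lemeshow = hl,
      roc = report$roc[c("auc", "auc_ci_low", "auc_ci_high", "p_value",
                         "youden_cutoff", "sensitivity_at_cutoff",
                         "specificity_at_cutoff")])
    jsonlite::write_json(json, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  if (!is.null(text_out)) {
    con <- file(text_out, "w")
    sink(con); print(report); sink()
    close(con)
  }
  report
}

#' @export
print.hii_cohort_report <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d with expansion (%.1f%%)\n\n",
              x$n, x$n_expansion, 100 * x$n_expansion / x$n))
  cat("Baseline comparison (expansion vs no expansion):\n")
  print(x$baseline, row.names = FALSE)
  cat("\nUnivariate logistic screen:\n")
  univ <- x$univariate
  univ[-1] <- lapply(univ[-1], signif, 3)
  print(univ, row.names = FALSE)
  cat(sprintf("\nSelected for the adjusted model (p < 0.1): %s\n",
              paste(x$selected, collapse = ", ")))
  if (!is.null(x$adjusted)) { cat("\nAdjusted model:\n"); print(x$adjusted) }
  if (!is.null(x$hosmer_lemeshow))
    cat(sprintf("\nHosmer-Lemeshow: chi2 = %.2f (df %d), p = %.3f%s\n",
                x$hosmer_lemeshow$statistic, x$hosmer_lemeshow$df,
                x$hosmer_lemeshow$p_value,
                if (x$hosmer_lemeshow$merged) " [groups merged]" else ""))
  cat("\n"); print(x$roc)
  invisible(x)
}

#' Materialise the standard phantom fixture suite
#'
#' Writes the sphere / ellipsoid / lobulated / thick-slice phantoms as
#' NIfTI volumes with JSON truth sidecars, plus a manifest. Deterministic
#' under `seed`; only the lobulated phantom actually consumes randomness.
#'
#' @param output_dir writable directory (created if needed).
#' @param seed RNG seed for the stochastic phantoms.
#' @param spacing_mm isotropic spacing of the analytic phantoms.
#' @return Invisibly, the manifest as a data.frame.
#' @export
make_fixtures <- function(output_dir, seed = 1L, spacing_mm = 0.5) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    sphere_r20 = function() make_sphere_phantom(20, spacing_mm),
    ellipsoid_1_1 = function() make_ellipsoid_phantom(15, 15, 15, spacing_mm),
    ellipsoid_2_1 = function() make_ellipsoid_phantom(20, 10, 10, spacing_mm),
    ellipsoid_4_1 = function() make_ellipsoid_phantom(40, 10, 10, spacing_mm),
    lobulated_5 = function() make_lobulated_phantom(
      n_lobes = 5, lobe_radius_range_mm = c(6, 12), center_spread_mm = 8,
      spacing_mm = 1, seed = seed),
    sphere_r20_sliced5mm = function() {
      ph <- make_sphere_phantom(20, 1)
      ph$volume <- resample_to_slices(ph$volume, 5)
      ph
    })
  rows <- lapply(names(specs), function(nm) {
    ph <- specs[[nm]]()
    vol_path <- file.path(output_dir, paste0(nm, ".nii.gz"))
    truth_path <- file.path(output_dir, paste0(nm, "_truth.json"))
    write_volume(ph$volume, vol_path)
    jsonlite::write_json(Filter(Negate(is.null), unclass(ph$truth)),
                         truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    data.frame(name = nm, volume = basename(vol_path),
               truth = basename(truth_path), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
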