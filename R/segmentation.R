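#' Segmentation settings for HU-window thresholding
#'
#' Scriptable stand-in for slice-by-slice semi-automatic labeling of acute
#' blood on non-contrast CT: voxels inside a closed HU window
#' (default \[40, 100\], the usual acute-clot window) are candidates, then a
#' single 26-connected component is kept -- the largest, or the one holding a
#' user-supplied seed. Manual corrections are represented by the seed rule
#' and by exclusion masks ([apply_exclusion_mask()]), not by interaction.
#'
#' @param hu_low,hu_high inclusive HU window bounds; `hu_low < hu_high`.
#' @param component_rule `"largest"` or `"seeded"`.
#' @param seed_point voxel index (length-3, 1-based) for the seeded rule.
#' @param min_component_voxels components smaller than this are discarded
#'   before selection.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(hu_low = 40, hu_high = 100,
                                component_rule = c("largest", "seeded"),
                                seed_point = NULL,
                                min_component_voxels = 1L) {
  component_rule <- match.arg(component_rule)
  if (!is.numeric(hu_low) || !is.numeric(hu_high) || hu_low >= hu_high)
    stop_hii("hii_domain_error", "hu_low must be strictly below hu_high")
  if (component_rule == "seeded" && is.null(seed_point))
    stop_hii("hii_domain_error", "seeded component rule requires a seed_point")
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 component_rule = component_rule,
                 seed_point = if (!is.null(seed_point)) as.integer(seed_point),
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "segmentation_config")
}

#' Threshold-segment a hematoma from a CT volume
#'
#' @param volume a [ct_volume()].
#' @param config a [segmentation_config()].
#' @return A [binary_mask()] containing exactly one 26-connected component.
#' @export
segment_hematoma <- function(volume, config = segmentation_config()) {
  stopifnot(inherits(volume, "ct_volume"),
            inherits(config, "segmentation_config"))
  hu <- volume$voxels
  inwin <- hu >= config$hu_low & hu <= config$hu_high
  if (!any(inwin)) {
    qs <- stats::quantile(hu, c(0, .25, .5, .75, 1))
    stop_hii("hii_empty_segmentation", sprintf(
      "no voxel in HU window [%g, %g]; HU quantiles: %s",
      config$hu_low, config$hu_high,
      paste(sprintf("%s=%g", names(qs), qs), collapse = " ")),
      hu_quantiles = qs)
  }
  lab <- .label_components26(array(as.integer(inwin), dim = dim(hu)), dim(hu))
  n <- attr(lab, "n_components")
  counts <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(counts >= config$min_component_voxels)
  if (length(keep) == 0L)
    stop_hii("hii_empty_segmentation", sprintf(
      "all %d in-window components are below min_component_voxels = %d",
      n, config$min_component_voxels))
  if (config$component_rule == "largest") {
    sel <- keep[which.max(counts[keep])]
  } else {
    sp <- config$seed_point
    sel <- lab[sp[1], sp[2], sp[3]]
    if (sel == 0L || !(sel %in% keep))
      stop_hii("hii_domain_error", sprintf(
        "seed point (%s) is not inside any retained in-window component",
        paste(sp, collapse = ",")))
  }
  binary_mask(lab == sel, volume$spacing_mm, volume$origin_mm)
}

#' Remove excluded voxels (e.g. intraventricular blood) from a mask
#'
#' Returns `mask AND NOT exclusion`; the result may be empty.
#'
#' @param mask,exclusion [binary_mask()]s on the same grid and spacing.
#' @return A [binary_mask()].
#' @export
apply_exclusion_mask <- function(mask, exclusion) {
  stopifnot(inherits(mask, "binary_mask"), inherits(exclusion, "binary_mask"))
  if (!identical(dim(mask$voxels), dim(exclusion$voxels)))
    stop_hii("hii_alignment_error", sprintf(
      "grid mismatch: mask is %s, exclusion is %s",
      paste(dim(mask$voxels), collapse = "x"),
      paste(dim(exclusion$voxels), collapse = "x")))
  if (max(abs(mask$spacing_mm - exclusion$spacing_mm)) > 1e-6)
    stop_hii("hii_alignment_error", "mask and exclusion spacing differ")
  binary_mask(mask$voxels == 1L & exclusion$voxels == 0L,
              mask$spacing_mm, mask$origin_mm)
}
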