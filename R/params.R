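#' Image-pipeline parameters
#'
#' All thresholds of the per-cell analysis in one validated object. The
#' numeric defaults for roundness (0.8), minimum mean tubulin (30, on an
#' 8-bit 0-255 intensity scale), relative spot intensity (0.095), splitting
#' coefficient (0.56) and the multipolar pole-count rule (more than 2 poles)
#' are the screen's published operating point; the remaining parameters are
#' this implementation's own knobs.
#'
#' @param phh3_threshold minimum mean PHH3 intensity over a nucleus for it
#'   to be called mitotic, or `"auto"` to estimate the threshold as
#'   mean + 3 SD of the lower (interphase) mode of per-nucleus PHH3 means.
#' @param roundness_min minimum isoperimetric roundness `4*pi*A/P^2` of a
#'   mitotic cytoplasm mask; less-round cells are excluded as poorly
#'   segmented.
#' @param tubulin_mean_min minimum mean tubulin intensity over the cytoplasm
#'   mask; dimmer cells are excluded because individual poles cannot be
#'   distinguished. Interpreted on the intensity scale of the input images
#'   (the published value of 30 assumes 8-bit data).
#' @param rel_spot_intensity_min minimum relative spot intensity
#'   `(peak - background) / (cell max - background)` for a local maximum to
#'   count as a spindle pole.
#' @param splitting_coefficient two candidate poles are merged (keeping the
#'   brighter) when the minimum smoothed intensity along the straight path
#'   between them exceeds this fraction of the dimmer peak — i.e. the
#'   valley between them is too shallow to split.
#' @param smoothing_sigma Gaussian smoothing SD (px) applied to the tubulin
#'   channel before local-maxima detection.
#' @param multipolar_pole_count_min minimum pole count classed as
#'   multipolar (default 3, i.e. strictly more than two poles).
#' @param nucleus_min_area smallest nucleus area (px) kept by segmentation.
#' @param watershed_tolerance minimum object-separation depth (px of the
#'   distance map) when splitting touching nuclei.
#' @param dna_threshold DNA-intensity threshold for mitotic-nucleus gating
#'   in [measure_spindle_intensity()], or `"auto"`.
#' @param spindle_search_radius px around a mitotic nucleus searched for
#'   marker-positive spindle regions in [measure_spindle_intensity()].
#' @return a list of class `pipeline_params`.
#' @export
pipeline_params <- function(phh3_threshold = "auto", roundness_min = 0.8,
                            tubulin_mean_min = 30,
                            rel_spot_intensity_min = 0.095,
                            splitting_coefficient = 0.56,
                            smoothing_sigma = 1,
                            multipolar_pole_count_min = 3L,
                            nucleus_min_area = 15L,
                            watershed_tolerance = 1,
                            dna_threshold = "auto",
                            spindle_search_radius = 15) {
  if (roundness_min <= 0 || roundness_min > 1)
    stopf("roundness_min must lie in (0, 1]")
  if (rel_spot_intensity_min <= 0 || rel_spot_intensity_min >= 1)
    stopf("rel_spot_intensity_min must lie in (0, 1)")
  if (splitting_coefficient < 0 || splitting_coefficient > 1)
    stopf("splitting_coefficient must lie in [0, 1]")
  if (smoothing_sigma < 0) stopf("smoothing_sigma must be >= 0")
  if (multipolar_pole_count_min < 1)
    stopf("multipolar_pole_count_min must be >= 1")
  structure(list(phh3_threshold = phh3_threshold,
                 roundness_min = roundness_min,
                 tubulin_mean_min = tubulin_mean_min,
                 rel_spot_intensity_min = rel_spot_intensity_min,
                 splitting_coefficient = splitting_coefficient,
                 smoothing_sigma = smoothing_sigma,
                 multipolar_pole_count_min =
                   as.integer(multipolar_pole_count_min),
                 nucleus_min_area = as.integer(nucleus_min_area),
                 watershed_tolerance = watershed_tolerance,
                 dna_threshold = dna_threshold,
                 spindle_search_radius = spindle_search_radius),
            class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
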