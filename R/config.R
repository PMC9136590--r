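#' Pipeline configuration
#'
#' Bundles every tunable parameter of the scoring pipeline with its
#' default. Area thresholds are expressed relative to the expected
#' pixel area of a single worm, so they scale with image resolution.
#'
#' @param polarity `"dark"` (worms darker than agar, the default) or
#'   `"light"`.
#' @param threshold `"otsu"` for automatic histogram thresholding on the
#'   plate-interior pixels, or a single numeric in (0, 1) for a fixed
#'   threshold applied to the polarity-normalized intensities.
#' @param expected_worm_area_px expected pixel area of one worm at the
#'   working resolution; scales the object-size filters.
#' @param min_area_px components smaller than this are filtered as
#'   debris. Default `0.2 * expected_worm_area_px`.
#' @param max_area_px components larger than this are filtered as
#'   plate-scale artifacts; the generous default
#'   `50 * expected_worm_area_px` keeps even large worm clumps.
#' @param ring_filter drop hollow, thin-ring components (spot-edge
#'   artifacts from unabsorbed compound droplets). `FALSE` restores the
#'   unfiltered behavior.
#' @param ring_score_min minimum perimeter^2 / area marking a thin-ring
#'   candidate (a disc scores ~12.6, a worm ~30-40, a spot ring >100).
#' @param hollow_ratio_min minimum hole-filled-area / area for a ring
#'   candidate to be filtered (a solid object scores ~1).
#' @param margin_frac,center_exclusion_frac,axis_rotation_deg plate
#'   layout, see [plate_geometry].
#' @param flatten_radius half-width in pixels of the median filter used
#'   for illumination flattening; `NULL` picks `max(5, radius / 20)`
#'   from the detected plate radius. Must exceed the worm body width.
#' @param test_pair diagonal quadrant pair carrying the test compound,
#'   `c(1, 3)` or `c(2, 4)`.
#' @return object of class `ct_config`.
#' @export
ct_config <- function(polarity = c("dark", "light"),
                      threshold = "otsu",
                      expected_worm_area_px = 120,
                      min_area_px = NULL,
                      max_area_px = NULL,
                      ring_filter = TRUE,
                      ring_score_min = 60,
                      hollow_ratio_min = 1.5,
                      margin_frac = 0.05,
                      center_exclusion_frac = 0.15,
                      axis_rotation_deg = 0,
                      flatten_radius = NULL,
                      test_pair = c(1L, 3L)) {
  polarity <- match.arg(polarity)
  if (is.character(threshold)) {
    threshold <- match.arg(threshold, "otsu")
  } else if (!(is.numeric(threshold) && length(threshold) == 1L &&
               threshold > 0 && threshold < 1)) {
    stop("`threshold` must be \"otsu\" or a single numeric in (0, 1)")
  }
  if (is.null(min_area_px)) min_area_px <- 0.2 * expected_worm_area_px
  if (is.null(max_area_px)) max_area_px <- 50 * expected_worm_area_px
  if (min_area_px < 0 || max_area_px < min_area_px)
    stop("need 0 <= min_area_px <= max_area_px")
  tp <- sort(as.integer(test_pair))
  if (!(identical(tp, c(1L, 3L)) || identical(tp, c(2L, 4L))))
    stop("test_pair must be a diagonal pair: c(1,3) or c(2,4)")
  structure(
    list(polarity = polarity, threshold = threshold,
         expected_worm_area_px = expected_worm_area_px,
         min_area_px = min_area_px, max_area_px = max_area_px,
         ring_filter = isTRUE(ring_filter),
         ring_score_min = ring_score_min,
         hollow_ratio_min = hollow_ratio_min,
         margin_frac = margin_frac,
         center_exclusion_frac = center_exclusion_frac,
         axis_rotation_deg = axis_rotation_deg,
         flatten_radius = flatten_radius,
         test_pair = tp),
    class = "ct_config")
}
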