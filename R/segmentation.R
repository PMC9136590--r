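#' Flatten plate illumination
#'
#' Vignetting and uneven illumination defeat a single global threshold,
#' so the large-scale background inside the plate is estimated and
#' removed. The estimate is a grayscale morphological closing (after
#' polarity normalization so foreground is always dark) with a disc
#' wider than a worm body — worms, debris and spot-edge rings vanish
#' from the estimate even when clumped, while the smooth illumination
#' field survives — followed by a median smoothing pass. Pixels outside
#' the plate are replaced by the in-plate median first so the dark
#' surround does not bleed into the estimate near the wall. The
#' flattened image is re-centered at 0.5, clipped to \[0, 1\], and
#' returned in the original polarity.
#'
#' @param image a [grayscale_image].
#' @param geometry a [plate_geometry].
#' @param config a [ct_config]; `flatten_radius` sets the smoothing
#'   window and `expected_worm_area_px` scales the closing disc.
#' @return a flattened [grayscale_image].
#' @export
preprocess <- function(image, geometry, config = ct_config()) {
  stopifnot(inherits(image, "grayscale_image"),
            inherits(geometry, "plate_geometry"))
  px <- image$pixels
  x <- if (config$polarity == "light") 1 - px else px
  nr <- nrow(x); nc <- ncol(x)
  dr <- matrix(seq_len(nr) - geometry$center[1], nr, nc)
  dc <- matrix(seq_len(nc) - geometry$center[2], nr, nc, byrow = TRUE)
  in_plate <- dr^2 + dc^2 <= geometry$radius^2
  size <- config$flatten_radius
  if (is.null(size)) size <- max(5L, round(geometry$radius / 40))
  brush <- 2L * max(3L, ceiling(sqrt(config$expected_worm_area_px) / 2)) + 1L

  padded <- x
  padded[!in_plate] <- median(x[in_plate])
  bg <- EBImage::closing(EBImage::Image(t(padded)),
                         EBImage::makeBrush(brush, shape = "disc"))
  bg <- t(EBImage::imageData(EBImage::medianFilter(bg, size = size)))
  out <- x - bg + 0.5
  out[out < 0] <- 0; out[out > 1] <- 1
  if (config$polarity == "light") out <- 1 - out
  grayscale_image(out)
}

#' Segment foreground objects inside the plate
#'
#' Applies one global threshold to the pixels inside the trimmed plate
#' disk; everything outside the plate is forced to background. With
#' `polarity = "light"` intensities are inverted first, so foreground is
#' always "below threshold" and inverting both the image and the
#' polarity flag yields the identical mask. The automatic threshold is
#' Otsu's method computed from the plate-interior histogram only. A
#' degenerate (single-valued) histogram — or an automatic threshold that
#' would flood more than 30% of the plate, as on an object-free noisy
#' image — yields an empty mask with a warning rather than an error.
#'
#' @param image a (preferably [preprocess]ed) [grayscale_image].
#' @param geometry a [plate_geometry].
#' @param config a [ct_config] (`polarity`, `threshold`).
#' @return logical matrix, `TRUE` = raw foreground pixel.
#' @export
segment_foreground <- function(image, geometry, config = ct_config()) {
  stopifnot(inherits(image, "grayscale_image"),
            inherits(geometry, "plate_geometry"))
  x <- image$pixels
  if (config$polarity == "light") x <- 1 - x
  nr <- nrow(x); nc <- ncol(x)
  dr <- matrix(seq_len(nr) - geometry$center[1], nr, nc)
  dc <- matrix(seq_len(nc) - geometry$center[2], nr, nc, byrow = TRUE)
  inside <- dr^2 + dc^2 <= ((1 - geometry$margin_frac) * geometry$radius)^2
  vals <- x[inside]
  if (diff(range(vals)) < 1e-8) {
    warning("degenerate intensity histogram inside the plate; empty mask")
    return(matrix(FALSE, nr, nc))
  }
  th <- if (is.numeric(config$threshold)) config$threshold
  else EBImage::otsu(EBImage::Image(matrix(vals)), range = c(0, 1))
  fg <- inside & x < th
  # Otsu assumes a bimodal histogram; on an object-free plate it splits
  # the noise in half. Worms never plausibly cover most of the agar, so
  # a huge foreground fraction means "nothing to segment".
  if (!is.numeric(config$threshold) && sum(fg) > 0.3 * sum(inside)) {
    warning("automatic threshold found no object/background separation ",
            "(foreground would cover >30% of the plate); empty mask")
    return(matrix(FALSE, nr, nc))
  }
  fg
}

#' Keep nematode objects, count the filtered pixels
#'
#' Connected components (8-connectivity, so thin diagonal bodies stay
#' whole) of the raw foreground are removed when their area falls below
#' `min_area_px` (debris specks) or above `max_area_px` (plate-scale
#' artifacts), or when a thin-ring score (high perimeter^2 / area
#' combined with a hollow interior) marks them as the reflective edge of
#' an unabsorbed compound spot. Clumps of worms are deliberately kept
#' whole and never split into individuals: pixel area, not animal
#' count, is the downstream measurement. Every removed pixel is counted
#' in `filtered_pixels`, so kept + filtered equals the raw foreground
#' exactly.
#'
#' @param mask logical matrix from [segment_foreground].
#' @param geometry a [plate_geometry] (recorded, not re-applied; the
#'   mask is already confined to the plate).
#' @param config a [ct_config].
#' @return object of class `segmentation_result`: `mask` (kept pixels),
#'   `filtered_mask`, `filtered_pixels`, and `objects`, a `data.frame`
#'   of kept components with area, bounding box, an eccentricity-like
#'   elongation score (perimeter^2 / (4 pi area); 1 for a disc), and
#'   the ring score.
#' @export
filter_objects <- function(mask, geometry, config = ct_config()) {
  stopifnot(is.matrix(mask))
  lab <- label_components8(matrix(as.integer(mask), nrow(mask)))
  nlab <- max(lab)
  if (nlab == 0L) {
    return(structure(
      list(mask = mask & FALSE, filtered_mask = mask & FALSE,
           filtered_pixels = 0L,
           objects = empty_objects_df()),
      class = "segmentation_result"))
  }
  areas <- tabulate(lab, nbins = nlab)
  perim <- label_perimeter(lab, nlab)
  keep <- areas >= config$min_area_px & areas <= config$max_area_px

  ring_score <- perim^2 / areas
  hollow <- rep(NA_real_, nlab)
  if (config$ring_filter) {
    cand <- which(keep & ring_score >= config$ring_score_min)
    for (l in cand) {
      hollow[l] <- hollow_ratio(lab, l)
      if (hollow[l] >= config$hollow_ratio_min) keep[l] <- FALSE
    }
  }

  kept_mask <- matrix(FALSE, nrow(mask), ncol(mask))
  pos <- lab > 0
  kept_mask[pos] <- keep[lab[pos]]
  filtered_mask <- pos & !kept_mask

  kept_ids <- which(keep)
  objects <- if (length(kept_ids)) {
    bbox <- t(vapply(kept_ids, function(l) {
      w <- which(lab == l, arr.ind = TRUE)
      c(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2]))
    }, numeric(4)))
    data.frame(label = kept_ids, area = areas[kept_ids],
               row_min = bbox[, 1], row_max = bbox[, 2],
               col_min = bbox[, 3], col_max = bbox[, 4],
               elongation = perim[kept_ids]^2 / (4 * pi * areas[kept_ids]),
               ring_score = ring_score[kept_ids])
  } else empty_objects_df()

  structure(
    list(mask = kept_mask, filtered_mask = filtered_mask,
         filtered_pixels = as.integer(sum(filtered_mask)),
         objects = objects),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result %d objects, %d px kept, %d px filtered>\n",
              nrow(x$objects), sum(x$mask), x$filtered_pixels))
  invisible(x)
}

empty_objects_df <- function() {
  data.frame(label = integer(), area = integer(),
             row_min = numeric(), row_max = numeric(),
             col_min = numeric(), col_max = numeric(),
             elongation = numeric(), ring_score = numeric())
}

# internal: hole-filled area / area for one component (cropped to its
# bounding box; other components in the crop are ignored)
hollow_ratio <- function(lab, l) {
  w <- which(lab == l, arr.ind = TRUE)
  r0 <- min(w[, 1]); r1 <- max(w[, 1])
  c0 <- min(w[, 2]); c1 <- max(w[, 2])
  crop <- lab[r0:r1, c0:c1, drop = FALSE] == l
  filled <- t(EBImage::imageData(
    EBImage::fillHull(EBImage::Image(t(crop * 1)))) > 0)
  sum(filled) / sum(crop)
}
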