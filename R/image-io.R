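#' Grayscale plate image
#'
#' A minimal container for a single-plate photograph: a numeric matrix of
#' intensities in \[0, 1\] indexed `[row, col]` (row 1 is the top of the
#' image). All pipeline stages consume and produce this type.
#'
#' @param pixels numeric matrix with finite values in \[0, 1\].
#' @return object of class `grayscale_image` with fields `pixels`,
#'   `height`, `width`.
#' @export
grayscale_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 64L || ncol(pixels) < 64L)
    stop("image too small: need at least 64 x 64 pixels, got ",
         nrow(pixels), " x ", ncol(pixels))
  if (!all(is.finite(pixels)))
    stop("image contains non-finite pixel values")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel intensities must lie in [0, 1]")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels)),
    class = "grayscale_image"
  )
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("<grayscale_image %d x %d, intensity range [%.3f, %.3f]>\n",
              x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Load a plate photograph
#'
#' Reads a PNG, TIFF or JPEG image and returns a normalized
#' [grayscale_image]. 8- and 16-bit inputs are mapped to \[0, 1\]
#' transparently by the decoder; RGB images are converted to grayscale by
#' Rec. 709 luminance weighting (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path path to an image file.
#' @return a [grayscale_image].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path")
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path)
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) stop("cannot read image '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (EBImage::colorMode(img) == EBImage::Color)
    img <- EBImage::channel(img, "luminance")
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3L) px <- px[, , 1L]   # drop alpha/extra frames
  if (length(px) == 0L)
    stop("image '", path, "' is zero-sized")
  # EBImage stores (x, y); transpose into [row, col]
  px <- t(px)
  px[px < 0] <- 0; px[px > 1] <- 1
  grayscale_image(px)
}

#' Write an image or a diagnostic overlay as PNG
#'
#' With only `image`, writes the grayscale pixels losslessly to PNG. When
#' `geometry` and/or a [segmentation_result] are supplied, an RGB overlay
#' is written instead: the plate circle, trimmed margin, center-exclusion
#' circle and quadrant axes in blue, kept nematode objects in green, and
#' filtered (non-nematode) pixels in red. Debug rendering never alters any
#' numerical output of the pipeline.
#'
#' @param image a [grayscale_image] used as the base layer.
#' @param path output path; the parent directory is created if needed.
#' @param geometry optional [plate_geometry] to draw.
#' @param segmentation optional [segmentation_result] whose kept/filtered
#'   pixels are colored.
#' @return `invisible(path)`.
#' @export
write_debug_image <- function(image, path, geometry = NULL,
                              segmentation = NULL) {
  stopifnot(inherits(image, "grayscale_image"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dirname(path)))
    stop("cannot create directory for debug image: ", dirname(path))

  if (is.null(geometry) && is.null(segmentation)) {
    out <- EBImage::Image(t(image$pixels))
  } else {
    r <- image$pixels; g <- image$pixels; b <- image$pixels
    if (!is.null(segmentation)) {
      kept <- segmentation$mask > 0
      filt <- segmentation$filtered_mask > 0
      g[kept] <- 1; r[kept] <- 0.1; b[kept] <- 0.1
      r[filt] <- 1; g[filt] <- 0.1; b[filt] <- 0.1
    }
    if (!is.null(geometry)) {
      ol <- geometry_outline(geometry, dim(image$pixels))
      r[ol] <- 0.15; g[ol] <- 0.4; b[ol] <- 1
    }
    out <- EBImage::rgbImage(red = t(r), green = t(g), blue = t(b))
  }
  ok <- tryCatch({ EBImage::writeImage(out, path, type = "png"); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write debug image to: ", path)
  invisible(path)
}

# internal: logical matrix of outline pixels for circles + quadrant axes
geometry_outline <- function(geometry, shape) {
  nr <- shape[1]; nc <- shape[2]
  dr <- matrix(seq_len(nr) - geometry$center[1], nr, nc)
  dc <- matrix(seq_len(nc) - geometry$center[2], nr, nc, byrow = TRUE)
  rad <- sqrt(dr^2 + dc^2)
  near <- function(target) abs(rad - target) <= 0.75
  ol <- near(geometry$radius) |
    near((1 - geometry$margin_frac) * geometry$radius) |
    near(geometry$center_exclusion_frac * geometry$radius)
  # quadrant axes: two perpendicular diameters at the configured rotation
  th <- atan2(-dr, dc) - geometry$axis_rotation_deg * pi / 180
  inside <- rad <= (1 - geometry$margin_frac) * geometry$radius
  axis_dist <- pmin(abs(rad * sin(th)), abs(rad * cos(th)))
  ol | (inside & axis_dist <= 0.6)
}
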