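#' Plate geometry
#'
#' The detected (or manually supplied) circular plate boundary together
#' with the layout parameters that turn it into scoring regions: a margin
#' trimmed at the plate wall, a center-exclusion disk around the animal
#' placement origin, and the rotation of the quadrant axes relative to
#' the image axes.
#'
#' @param center numeric length-2, plate center as (row, col), sub-pixel.
#' @param radius plate radius in pixels.
#' @param margin_frac fraction of the radius trimmed at the plate wall to
#'   drop the wall and meniscus reflections. Default 0.05.
#' @param center_exclusion_frac fraction of the radius defining the
#'   origin zone whose animals never left the center and are excluded
#'   from the CI denominator. Default 0.15; set 0 to count every plate
#'   pixel.
#' @param axis_rotation_deg rotation of the quadrant axes,
#'   counter-clockwise degrees. Default 0 (plates photographed square).
#' @return object of class `plate_geometry`.
#' @export
plate_geometry <- function(center, radius, margin_frac = 0.05,
                           center_exclusion_frac = 0.15,
                           axis_rotation_deg = 0) {
  stopifnot(length(center) == 2L, is.finite(center), is.finite(radius))
  if (radius <= 0) stop("plate radius must be positive")
  if (margin_frac < 0 || margin_frac >= 0.5)
    stop("margin_frac must be in [0, 0.5)")
  if (center_exclusion_frac < 0 ||
      center_exclusion_frac >= 1 - margin_frac)
    stop("center_exclusion_frac must be in [0, 1 - margin_frac)")
  structure(
    list(center = as.numeric(center), radius = as.numeric(radius),
         margin_frac = margin_frac,
         center_exclusion_frac = center_exclusion_frac,
         axis_rotation_deg = axis_rotation_deg),
    class = "plate_geometry"
  )
}

#' @export
print.plate_geometry <- function(x, ...) {
  cat(sprintf(
    "<plate_geometry center=(%.2f, %.2f) radius=%.2f margin=%.2f center_zone=%.2f rot=%g deg>\n",
    x$center[1], x$center[2], x$radius, x$margin_frac,
    x$center_exclusion_frac, x$axis_rotation_deg))
  invisible(x)
}

# region codes used in the label map
REGION_OUTSIDE <- 0L
REGION_CENTER  <- 5L

#' Detect the circular plate boundary in a raw image
#'
#' The plate interior (illuminated agar) is brighter than the surround,
#' so detection proceeds: Otsu threshold on the whole frame, keep the
#' largest connected bright region, fill its holes (worms, spots), take
#' its boundary pixels, and fit a circle to them by algebraic
#' least squares. The fit is accepted only if the radial residuals are
#' small relative to the radius; otherwise a detection error asks for a
#' manual geometry override ([plate_geometry] can be passed directly to
#' the scoring functions).
#'
#' @param image a [grayscale_image].
#' @param config a [ct_config]; supplies the margin, center-exclusion and
#'   rotation parameters copied into the result.
#' @return a [plate_geometry].
#' @export
detect_plate <- function(image, config = ct_config()) {
  stopifnot(inherits(image, "grayscale_image"))
  px <- image$pixels
  rng <- range(px)
  if (diff(rng) < 1e-6)
    stop("plate detection failed: image has no contrast; ",
         "supply geometry manually via plate_geometry()")
  th <- EBImage::otsu(EBImage::Image(matrix(px)), range = c(0, 1))
  bright <- px > th
  frac <- mean(bright)
  if (frac < 0.005 || frac > 0.95)
    stop("plate detection failed: no plausible plate-sized bright region; ",
         "supply geometry manually via plate_geometry()")
  lab <- label_components8(matrix(as.integer(bright), nrow(bright)))
  sizes <- tabulate(lab)
  blob <- lab == which.max(sizes)
  blob <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(blob * 1)))) > 0)

  # boundary pixels: blob pixels with a 4-neighbour outside the blob
  pad <- rbind(FALSE, cbind(FALSE, blob, FALSE), FALSE)
  nr <- nrow(blob); nc <- ncol(blob)
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
        pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  boundary <- which(core & !nb, arr.ind = TRUE)
  if (nrow(boundary) < 16L)
    stop("plate detection failed: boundary too small; ",
         "supply geometry manually via plate_geometry()")

  fit <- fit_circle(boundary[, 1], boundary[, 2])
  if (!is.finite(fit$radius) || fit$radius <= 8 ||
      fit$rms > 0.02 * fit$radius)
    stop(sprintf(
      paste0("plate detection failed: boundary is not circular ",
             "(rms residual %.1f px at radius %.1f px); ",
             "supply geometry manually via plate_geometry()"),
      fit$rms, fit$radius))

  plate_geometry(center = fit$center, radius = fit$radius,
                 margin_frac = config$margin_frac,
                 center_exclusion_frac = config$center_exclusion_frac,
                 axis_rotation_deg = config$axis_rotation_deg)
}

# internal: algebraic (Kasa) least-squares circle fit to boundary points
fit_circle <- function(rows, cols) {
  A <- cbind(2 * rows, 2 * cols, 1)
  b <- rows^2 + cols^2
  sol <- qr.solve(A, b)
  center <- sol[1:2]
  radius <- sqrt(sol[3] + sum(center^2))
  resid <- sqrt((rows - center[1])^2 + (cols - center[2])^2) - radius
  list(center = unname(center), radius = unname(radius),
       rms = sqrt(mean(resid^2)))
}

#' Build the quadrant / center-exclusion region label map
#'
#' Splits the trimmed plate disk into four quadrants by two perpendicular
#' lines through the center at the configured axis rotation. Quadrants
#' are numbered 1-4 counter-clockwise starting upper-right (image row
#' axis points down, so "up" is decreasing row). Boundary pixels are
#' assigned by strict half-open angular intervals \[0, 90), \[90, 180),
#' ... so every pixel gets exactly one code.
#'
#' @param geometry a [plate_geometry].
#' @param shape integer length-2, (height, width) of the target image.
#' @return integer matrix with codes 0 = outside the trimmed plate,
#'   1-4 = quadrants, 5 = center-exclusion zone.
#' @export
build_region_map <- function(geometry, shape) {
  stopifnot(inherits(geometry, "plate_geometry"), length(shape) == 2L)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  rmax <- (1 - geometry$margin_frac) * geometry$radius
  if (geometry$center[1] - rmax < 0.5 || geometry$center[1] + rmax > nr + 0.5 ||
      geometry$center[2] - rmax < 0.5 || geometry$center[2] + rmax > nc + 0.5)
    stop("plate geometry (after margin trim) extends outside the image")
  dr <- matrix(seq_len(nr) - geometry$center[1], nr, nc)
  dc <- matrix(seq_len(nc) - geometry$center[2], nr, nc, byrow = TRUE)
  rad2 <- dr^2 + dc^2
  theta <- (atan2(-dr, dc) * 180 / pi - geometry$axis_rotation_deg) %% 360
  quad <- theta %/% 90 + 1
  labels <- matrix(REGION_OUTSIDE, nr, nc)
  inside <- rad2 <= rmax^2
  labels[inside] <- quad[inside]
  labels[rad2 <= (geometry$center_exclusion_frac * geometry$radius)^2] <-
    REGION_CENTER
  storage.mode(labels) <- "integer"
  labels
}
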