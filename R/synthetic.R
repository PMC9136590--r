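#' Specification for a synthetic chemotaxis plate image
#'
#' Describes a rendered plate: a bright circular plate on a dark
#' background with a radial-quadratic vignette, worm-shaped blobs of
#' known pixel area placed in known quadrants, optional blobs left
#' inside the center-exclusion zone, optional sub-worm debris specks,
#' and an optional hollow ring emulating the reflective edge of an
#' unabsorbed compound spot. Worm blobs are rendered as short
#' random-walk thick curves rather than discs so that shape-based
#' filters are exercised by realistic elongated objects.
#'
#' @param image_size image side length in pixels (square image).
#' @param plate_center (row, col) of the plate center.
#' @param plate_radius plate radius in pixels.
#' @param foreground_polarity `"dark_on_light"` (worms darker than agar)
#'   or `"light_on_dark"` (worms brighter).
#' @param worms_per_quadrant 4 non-negative integers, quadrants numbered
#'   1-4 counter-clockwise from upper-right. The default places 17 worms
#'   in each test quadrant (pair 1,3) and 4 in each control quadrant;
#'   with the 8 animals left in the center this emulates a 50-animal
#'   plate responding to an attractant.
#' @param worm_area_px target mean pixel area of a single worm blob.
#' @param center_worms blobs left fully inside the center-exclusion zone
#'   (animals that never left the origin).
#' @param debris_count 3-pixel specks, below any worm size.
#' @param spot_ring `NULL`, or `list(quadrant =, radius =, thickness =)`
#'   rendering a hollow ring at the quadrant's compound-spot position.
#' @param vignette_strength 0-1, radial-quadratic illumination falloff
#'   at the plate edge.
#' @param noise_sd additive Gaussian pixel noise, intensity units.
#' @param margin_frac,center_exclusion_frac layout fractions used for the
#'   ground-truth [plate_geometry]; defaults match [ct_config()].
#' @param seed RNG seed; a fixed spec + seed renders bit-identically.
#' @return object of class `synthetic_plate_spec`.
#' @export
synthetic_plate_spec <- function(image_size = 512L,
                                 plate_center = c(256, 256),
                                 plate_radius = 200,
                                 foreground_polarity = c("dark_on_light",
                                                         "light_on_dark"),
                                 worms_per_quadrant = c(17L, 4L, 17L, 4L),
                                 worm_area_px = 120,
                                 center_worms = 8L,
                                 debris_count = 3L,
                                 spot_ring = NULL,
                                 vignette_strength = 0.3,
                                 noise_sd = 0.02,
                                 margin_frac = 0.05,
                                 center_exclusion_frac = 0.15,
                                 seed = 1L) {
  foreground_polarity <- match.arg(foreground_polarity)
  stopifnot(length(worms_per_quadrant) == 4L,
            all(worms_per_quadrant >= 0), center_worms >= 0,
            debris_count >= 0, vignette_strength >= 0,
            vignette_strength <= 1, noise_sd >= 0)
  if (worm_area_px < 4) stop("worm_area_px must be at least 4")
  if (plate_center[1] - plate_radius < 1 ||
      plate_center[1] + plate_radius > image_size ||
      plate_center[2] - plate_radius < 1 ||
      plate_center[2] + plate_radius > image_size)
    stop("plate circle must lie fully inside the image")
  if (!is.null(spot_ring)) {
    stopifnot(is.list(spot_ring),
              all(c("quadrant", "radius", "thickness") %in% names(spot_ring)),
              spot_ring$quadrant %in% 1:4, spot_ring$radius > 0,
              spot_ring$thickness > 0)
  }
  structure(
    list(image_size = as.integer(image_size),
         plate_center = as.numeric(plate_center),
         plate_radius = as.numeric(plate_radius),
         foreground_polarity = foreground_polarity,
         worms_per_quadrant = as.integer(worms_per_quadrant),
         worm_area_px = worm_area_px,
         center_worms = as.integer(center_worms),
         debris_count = as.integer(debris_count),
         spot_ring = spot_ring,
         vignette_strength = vignette_strength,
         noise_sd = noise_sd,
         margin_frac = margin_frac,
         center_exclusion_frac = center_exclusion_frac,
         seed = as.integer(seed)),
    class = "synthetic_plate_spec"
  )
}

#' Render a synthetic plate with exact ground truth
#'
#' Deterministic for a fixed spec (which includes the seed). Every worm
#' blob lies fully within its assigned region — a quadrant (outside the
#' center-exclusion zone, inside the trimmed margin) or the center zone —
#' and blobs never overlap, so the ground-truth areas equal the exact
#' rendered foreground pixel counts per region. If a blob cannot be
#' placed after bounded retries a capacity error (condition class
#' `chemotax_capacity_error`) is raised.
#'
#' @param spec a [synthetic_plate_spec].
#' @param test_pair diagonal quadrant pair treated as "test" when
#'   computing the true CI; `c(1, 3)` or `c(2, 4)`.
#' @return list with `image` (a [grayscale_image]) and `truth`, a
#'   `synthetic_ground_truth` holding `true_geometry`,
#'   `true_area_per_quadrant`, `true_center_area`, `true_debris_pixels`,
#'   `true_ring_pixels`, `true_ci` (`NA` when no animal left the
#'   center), plus the exact `worm_mask` and `foreground_mask` for
#'   oracle tests.
#' @export
generate_synthetic_plate <- function(spec, test_pair = c(1L, 3L)) {
  stopifnot(inherits(spec, "synthetic_plate_spec"))
  with_local_seed(spec$seed, render_plate(spec, test_pair))
}

# internal: all rendering, run under the spec seed
render_plate <- function(spec, test_pair) {
  n <- spec$image_size
  geom <- plate_geometry(spec$plate_center, spec$plate_radius,
                         margin_frac = spec$margin_frac,
                         center_exclusion_frac = spec$center_exclusion_frac)
  regions <- build_region_map(geom, c(n, n))

  # pixels worms/debris must avoid so a spot ring stays a separate object
  avoid <- matrix(FALSE, n, n)
  ring_zone <- NULL
  if (!is.null(spec$spot_ring)) {
    ring_zone <- ring_pixels(spec, geom, dilate = 3)
    avoid[ring_zone$zone] <- TRUE
  }

  occupied <- matrix(FALSE, n, n)
  worm_mask <- matrix(FALSE, n, n)
  qareas <- integer(4)

  place_blobs <- function(count, region_code, area_px) {
    for (i in seq_len(count)) {
      placed <- FALSE
      for (try in seq_len(300L)) {
        idx <- draw_worm_blob(spec, geom, region_code, area_px, n)
        if (is.null(idx)) next
        lin <- idx[, 1] + (idx[, 2] - 1L) * n
        if (any(occupied[lin]) || any(avoid[lin])) next
        if (any(regions[lin] != region_code)) next
        occupied[lin] <<- TRUE
        worm_mask[lin] <<- TRUE
        if (region_code %in% 1:4)
          qareas[region_code] <<- qareas[region_code] + length(lin)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(structure(class = c("chemotax_capacity_error", "error",
                                 "condition"),
                       list(message = paste0(
                              "cannot place blob in region ", region_code,
                              " without overlap after 300 retries"),
                            call = sys.call(-1))))
    }
  }

  for (q in 1:4) place_blobs(spec$worms_per_quadrant[q], q, spec$worm_area_px)
  place_blobs(spec$center_worms, REGION_CENTER, min(spec$worm_area_px, 40))
  center_area <- sum(worm_mask[regions == REGION_CENTER])

  # debris: 3-px L-shaped specks anywhere in the quadrant annulus
  debris_mask <- matrix(FALSE, n, n)
  for (i in seq_len(spec$debris_count)) {
    placed <- FALSE
    for (try in seq_len(300L)) {
      r0 <- sample.int(n - 1L, 1L); c0 <- sample.int(n - 1L, 1L)
      rr <- c(r0, r0, r0 + 1L); cc <- c(c0, c0 + 1L, c0)
      lin <- rr + (cc - 1L) * n
      if (any(regions[lin] == REGION_OUTSIDE) ||
          any(regions[lin] == REGION_CENTER)) next
      if (any(occupied[lin]) || any(avoid[lin])) next
      occupied[lin] <- TRUE
      debris_mask[lin] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      stop(structure(class = c("chemotax_capacity_error", "error",
                               "condition"),
                     list(message = "cannot place debris speck",
                          call = sys.call(-1))))
  }

  ring_mask <- matrix(FALSE, n, n)
  if (!is.null(ring_zone)) ring_mask[ring_zone$ring] <- TRUE

  fg <- worm_mask | debris_mask | ring_mask

  # intensity model: dark surround, vignetted agar, foreground at worm level
  lv <- if (spec$foreground_polarity == "dark_on_light")
    c(bg = 0.08, agar = 0.82, worm = 0.15)
  else c(bg = 0.05, agar = 0.35, worm = 0.90)
  dr <- matrix(seq_len(n) - geom$center[1], n, n)
  dc <- matrix(seq_len(n) - geom$center[2], n, n, byrow = TRUE)
  rad2 <- dr^2 + dc^2
  in_plate <- rad2 <= geom$radius^2
  vig <- 1 - spec$vignette_strength * rad2 / geom$radius^2
  px <- matrix(lv["bg"], n, n)
  px[in_plate] <- lv["agar"] * vig[in_plate]
  px[fg] <- lv["worm"] * vig[fg]
  if (spec$noise_sd > 0) px <- px + rnorm(n * n, sd = spec$noise_sd)
  px[px < 0] <- 0; px[px > 1] <- 1

  total_q <- sum(qareas)
  true_ci <- if (total_q == 0) NA_real_ else
    (sum(qareas[test_pair]) - sum(qareas[-test_pair])) / total_q

  truth <- structure(
    list(true_geometry = geom,
         true_area_per_quadrant = qareas,
         true_center_area = center_area,
         true_debris_pixels = sum(debris_mask),
         true_ring_pixels = sum(ring_mask),
         true_ci = true_ci,
         test_pair = sort(as.integer(test_pair)),
         worm_mask = worm_mask,
         foreground_mask = fg),
    class = "synthetic_ground_truth")
  list(image = grayscale_image(px), truth = truth)
}

# internal: pixel set of one worm blob (random-walk thick curve), or NULL
# if the walk left the target region
draw_worm_blob <- function(spec, geom, region_code, area_px, n) {
  # disc stamp of radius 2.2 px covers ~13 px; each unit step adds ~4.5
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  offs <- offs[offs$dr^2 + offs$dc^2 <= 4.84, ]
  n_steps <- max(1L, round((area_px - 13) / 4.5))

  if (region_code == REGION_CENTER) {
    rmax <- geom$center_exclusion_frac * geom$radius
    rr <- sqrt(runif(1)) * max(rmax - 4, 1)
    th <- runif(1, 0, 2 * pi)
  } else {
    rmin <- geom$center_exclusion_frac * geom$radius + 4
    rmax <- (1 - geom$margin_frac) * geom$radius - 4
    rr <- sqrt(runif(1, (rmin / rmax)^2, 1)) * rmax
    th <- runif(1, (region_code - 1) * pi / 2, region_code * pi / 2) +
      geom$axis_rotation_deg * pi / 180
  }
  pos <- geom$center + rr * c(-sin(th), cos(th))
  heading <- runif(1, 0, 2 * pi)
  turns <- rnorm(n_steps, sd = 0.2)
  hs <- heading + cumsum(turns)
  path <- rbind(pos,
                cbind(pos[1] + cumsum(sin(hs)), pos[2] + cumsum(cos(hs))))
  rows <- round(rep(path[, 1], each = nrow(offs)) + offs$dr)
  cols <- round(rep(path[, 2], each = nrow(offs)) + offs$dc)
  if (min(rows) < 1 || max(rows) > n || min(cols) < 1 || max(cols) > n)
    return(NULL)
  unique(cbind(as.integer(rows), as.integer(cols)))
}

# internal: spot-ring annulus pixels and a dilated exclusion zone
ring_pixels <- function(spec, geom, dilate = 3) {
  n <- spec$image_size
  sr <- spec$spot_ring
  ang <- (45 + 90 * (sr$quadrant - 1) + geom$axis_rotation_deg) * pi / 180
  d <- 0.55 * (1 - geom$margin_frac) * geom$radius
  ctr <- geom$center + d * c(-sin(ang), cos(ang))
  dr <- matrix(seq_len(n) - ctr[1], n, n)
  dc <- matrix(seq_len(n) - ctr[2], n, n, byrow = TRUE)
  rad <- sqrt(dr^2 + dc^2)
  half <- sr$thickness / 2
  list(ring = rad >= sr$radius - half & rad <= sr$radius + half,
       zone = rad >= sr$radius - half - dilate &
              rad <= sr$radius + half + dilate)
}

#' Render a batch of synthetic plates with a ground-truth manifest
#'
#' Writes `plate_0001.png`, `plate_0002.png`, ... plus a tab-separated
#' manifest `ground_truth.tsv` with columns `image`, `q1_true_px` ...
#' `q4_true_px`, `center_px`, `debris_px`, `true_ci`, `seed`. Plate
#' `i` is rendered from the base spec with seed `seed + i - 1`.
#'
#' @param n_plates number of plates to render.
#' @param out_dir output directory, created if needed.
#' @param spec base [synthetic_plate_spec]; its seed field is replaced
#'   per plate.
#' @param test_pair diagonal test pair for the true CI.
#' @param seed first seed of the batch.
#' @return the manifest `data.frame`, invisibly.
#' @export
simulate_plates <- function(n_plates, out_dir,
                            spec = synthetic_plate_spec(),
                            test_pair = c(1L, 3L), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_plates)
  for (i in seq_len(n_plates)) {
    s <- spec
    s$seed <- as.integer(seed + i - 1L)
    gen <- generate_synthetic_plate(s, test_pair = test_pair)
    name <- sprintf("plate_%04d.png", i)
    EBImage::writeImage(EBImage::Image(t(gen$image$pixels)),
                        file.path(out_dir, name), type = "png")
    tr <- gen$truth
    rows[[i]] <- data.frame(
      image = name,
      q1_true_px = tr$true_area_per_quadrant[1],
      q2_true_px = tr$true_area_per_quadrant[2],
      q3_true_px = tr$true_area_per_quadrant[3],
      q4_true_px = tr$true_area_per_quadrant[4],
      center_px = tr$true_center_area,
      debris_px = tr$true_debris_pixels + tr$true_ring_pixels,
      true_ci = tr$true_ci,
      seed = s$seed)
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(out_dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
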