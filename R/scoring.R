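#' Measure nematode pixel area per quadrant
#'
#' Sums kept nematode pixels over each region of the label map.
#' Assignment is per-pixel: a clump straddling a quadrant boundary
#' contributes its pixels to both quadrants, consistent with using area
#' (not object identity) as the measurement.
#'
#' @param mask logical kept-pixel mask (e.g. `filter_objects()$mask`).
#' @param regions integer region map from [build_region_map].
#' @return object of class `quadrant_areas` with integer fields
#'   `q1`-`q4` and `center_px` (kept pixels still inside the
#'   center-exclusion zone; reported but excluded from the CI).
#' @export
measure_quadrant_areas <- function(mask, regions) {
  if (!is.matrix(mask) || !identical(dim(mask), dim(regions)))
    stop("mask and region map must be matrices of identical shape")
  counts <- vapply(c(1:4, REGION_CENTER),
                   function(code) sum(mask[regions == code]), numeric(1))
  structure(
    list(q1 = as.integer(counts[1]), q2 = as.integer(counts[2]),
         q3 = as.integer(counts[3]), q4 = as.integer(counts[4]),
         center_px = as.integer(counts[5])),
    class = "quadrant_areas")
}

#' @export
print.quadrant_areas <- function(x, ...) {
  cat(sprintf("<quadrant_areas q1=%d q2=%d q3=%d q4=%d center=%d>\n",
              x$q1, x$q2, x$q3, x$q4, x$center_px))
  invisible(x)
}

#' Compute the chemotaxis index from quadrant areas
#'
#' \deqn{CI = (A_{test} - A_{control}) / (A_{test} + A_{control})}
#' where `A_test` sums the pixel area over the diagonal test-quadrant
#' pair and `A_control` over the other pair; pixel area stands proxy for
#' animal counts. Animals still inside the center-exclusion zone never
#' left the origin and are excluded from the denominator. A CI of 1 is
#' maximum attraction, -1 maximum avoidance. When no area lies in any
#' quadrant the CI is undefined and `NA` is returned (never silently 0,
#' which would fake a neutral response).
#'
#' @param areas a [quadrant_areas] (or list with `q1`-`q4`).
#' @param test_pair `c(1, 3)` or `c(2, 4)`.
#' @return CI in \[-1, 1\], or `NA_real_` when undefined.
#' @export
compute_ci <- function(areas, test_pair = c(1L, 3L)) {
  tp <- sort(as.integer(test_pair))
  if (!(identical(tp, c(1L, 3L)) || identical(tp, c(2L, 4L))))
    stop("test_pair must be a diagonal pair: c(1,3) or c(2,4)")
  a <- c(areas$q1, areas$q2, areas$q3, areas$q4)
  if (any(a < 0)) stop("quadrant areas must be non-negative")
  total <- sum(a)
  if (total == 0) return(NA_real_)
  (sum(a[tp]) - sum(a[-tp])) / total
}

#' Score one plate image
#'
#' Runs the full pipeline: plate detection (unless `geometry` is
#' supplied), illumination flattening, foreground segmentation, object
#' filtering, per-quadrant area measurement and CI computation. With
#' `debug_dir` set, one overlay PNG per stage is written; debug output
#' never changes any number.
#'
#' @param input path to an image file, or a [grayscale_image].
#' @param config a [ct_config].
#' @param geometry optional [plate_geometry] overriding detection.
#' @param debug_dir optional directory for per-stage debug overlays.
#' @param image_id identifier recorded in the output row; defaults to
#'   the file name (or `"image"` for in-memory input).
#' @return a one-row `data.frame` (a plate score) with columns `image`,
#'   `q1_px`-`q4_px`, `center_px`, `filtered_px`, `test_pair`, `ci`.
#' @export
score_image <- function(input, config = ct_config(), geometry = NULL,
                        debug_dir = NULL, image_id = NULL) {
  if (is.character(input)) {
    if (is.null(image_id)) image_id <- basename(input)
    image <- load_image(input)
  } else {
    stopifnot(inherits(input, "grayscale_image"))
    if (is.null(image_id)) image_id <- "image"
    image <- input
  }
  if (is.null(geometry)) geometry <- detect_plate(image, config)
  flat <- preprocess(image, geometry, config)
  raw_mask <- segment_foreground(flat, geometry, config)
  seg <- filter_objects(raw_mask, geometry, config)
  regions <- build_region_map(geometry, dim(image$pixels))
  areas <- measure_quadrant_areas(seg$mask, regions)
  ci <- compute_ci(areas, config$test_pair)

  if (!is.null(debug_dir)) {
    stem <- tools::file_path_sans_ext(image_id)
    write_debug_image(image, file.path(debug_dir, paste0(stem, "_1_geometry.png")),
                      geometry = geometry)
    write_debug_image(flat, file.path(debug_dir, paste0(stem, "_2_flattened.png")))
    write_debug_image(image, file.path(debug_dir, paste0(stem, "_3_objects.png")),
                      geometry = geometry, segmentation = seg)
  }

  data.frame(image = image_id,
             q1_px = areas$q1, q2_px = areas$q2,
             q3_px = areas$q3, q4_px = areas$q4,
             center_px = areas$center_px,
             filtered_px = seg$filtered_pixels,
             test_pair = paste(config$test_pair, collapse = ","),
             ci = ci,
             stringsAsFactors = FALSE)
}

#' Score a batch of plate images
#'
#' Processes images in order, isolating failures: an unreadable or
#' undetectable plate yields an all-`NA` row and a warning while the
#' remaining images are still scored. The number of failed images is
#' attached as attribute `n_failed`.
#'
#' @param inputs character vector of image paths.
#' @param config a [ct_config].
#' @param out optional path; when set the results TSV is written with
#'   [write_results].
#' @param debug_dir optional directory for per-stage debug overlays.
#' @param quiet suppress the per-image progress line.
#' @return `data.frame` of plate scores, one row per input, in input
#'   order.
#' @export
score_plates <- function(inputs, config = ct_config(), out = NULL,
                         debug_dir = NULL, quiet = TRUE) {
  rows <- vector("list", length(inputs))
  n_failed <- 0L
  for (i in seq_along(inputs)) {
    rows[[i]] <- tryCatch(
      {
        row <- score_image(inputs[i], config, debug_dir = debug_dir)
        if (!quiet)
          message(sprintf("%s: kept q=(%d,%d,%d,%d) center=%d filtered=%d ci=%s",
                          row$image, row$q1_px, row$q2_px, row$q3_px,
                          row$q4_px, row$center_px, row$filtered_px,
                          format(row$ci)))
        row
      },
      error = function(e) {
        n_failed <<- n_failed + 1L
        warning("failed to score '", inputs[i], "': ",
                conditionMessage(e), call. = FALSE)
        data.frame(image = basename(inputs[i]),
                   q1_px = NA_integer_, q2_px = NA_integer_,
                   q3_px = NA_integer_, q4_px = NA_integer_,
                   center_px = NA_integer_, filtered_px = NA_integer_,
                   test_pair = paste(config$test_pair, collapse = ","),
                   ci = NA_real_, stringsAsFactors = FALSE)
      })
  }
  scores <- do.call(rbind, rows)
  if (!is.null(out)) write_results(scores, out)
  attr(scores, "n_failed") <- n_failed
  scores
}

#' Write the per-image results file
#'
#' Tab-separated text with header `image, q1_px, q2_px, q3_px, q4_px,
#' center_px, filtered_px, test_pair, ci`, one row per image in input
#' order. Undefined CIs are written as `NA`. CIs are printed with 17
#' significant digits so a round-trip through [read_results] reproduces
#' the doubles exactly.
#'
#' @param scores `data.frame` from [score_plates] / [score_image].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_results <- function(scores, path) {
  cols <- c("image", "q1_px", "q2_px", "q3_px", "q4_px", "center_px",
            "filtered_px", "test_pair", "ci")
  if (!all(cols %in% names(scores)))
    stop("scores is missing columns: ",
         paste(setdiff(cols, names(scores)), collapse = ", "))
  out <- scores[, cols]
  out$ci <- ifelse(is.na(out$ci), "NA",
                   formatC(out$ci, digits = 17, format = "g"))
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results file to: ", path)
  invisible(path)
}

#' Read a results file written by [write_results]
#'
#' @param path path to the TSV.
#' @return `data.frame` with the same columns and types as
#'   [score_plates] output.
#' @export
read_results <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(image = "character", q1_px = "integer",
                            q2_px = "integer", q3_px = "integer",
                            q4_px = "integer", center_px = "integer",
                            filtered_px = "integer",
                            test_pair = "character", ci = "numeric"))
}
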