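# Color/size grading of a segmented apple.

#' Grading configuration
#'
#' All thresholds and calibration constants of the pipeline in one place.
#'
#' @param a_star_threshold CIELAB a* units; pixels with `a* >` this value
#'   inside the apple mask count as red (default 15).
#' @param y_threshold normalized CIE Y (reference white Y = 1); pixels above it
#'   count as yellow (default 0.5).
#' @param y_normalization `"white"` applies `y_threshold` to the white-relative
#'   Y plane directly (default); `"apple_max"` first divides Y by its maximum
#'   over the apple region, making the rule scale-invariant per image.
#' @param s_threshold saturation threshold of the background-removal rule
#'   (default 0.5; the reference data separates fruit from the dark conveyor
#'   at this value under the `"hsi"` saturation convention).
#' @param pixel_length_mm physical side length of one pixel (default 0.312 mm,
#'   the rig's calibration).
#' @param size_cutoff_mm apples whose larger bounding-box extent reaches this
#'   length are graded `large` (default 75 mm).
#' @param red_presence_min minimum red fraction for an apple to count as
#'   having red surface at all; below it the variety is Golden (default 0.01).
#' @param starking_red_min red fraction at or above which an apple with no
#'   appreciable yellow is Starking rather than Jonagold (default 0.50).
#' @param min_area_px speck-removal threshold of [clean_mask()] (default 100).
#' @param fill_holes fill interior holes during cleanup (default TRUE).
#' @param linearize apply the sRGB transfer function before the RGB-to-XYZ
#'   matrix. Default FALSE: the thresholds above were established on planes
#'   computed from gamma-encoded RGB (the "as-measured" convention; see the
#'   methods vignette).
#' @param saturation_method saturation convention of the S plane,
#'   `"hsi"` (default) or `"hexcone"`; see [rgb_to_hsv()].
#' @param cone_model cone model of the chromatic adaptation,
#'   `"von_kries"` (default) or `"bradford"`.
#' @return A list of class `grading_config`.
#' @export
grading_config <- function(a_star_threshold = 15,
                           y_threshold = 0.5,
                           y_normalization = c("white", "apple_max"),
                           s_threshold = 0.5,
                           pixel_length_mm = 0.312,
                           size_cutoff_mm = 75,
                           red_presence_min = 0.01,
                           starking_red_min = 0.50,
                           min_area_px = 100,
                           fill_holes = TRUE,
                           linearize = FALSE,
                           saturation_method = c("hsi", "hexcone"),
                           cone_model = c("von_kries", "bradford")) {
  y_normalization <- match.arg(y_normalization)
  saturation_method <- match.arg(saturation_method)
  cone_model <- match.arg(cone_model)
  cfg <- list(a_star_threshold = a_star_threshold,
              y_threshold = y_threshold,
              y_normalization = y_normalization,
              s_threshold = s_threshold,
              pixel_length_mm = pixel_length_mm,
              size_cutoff_mm = size_cutoff_mm,
              red_presence_min = red_presence_min,
              starking_red_min = starking_red_min,
              min_area_px = min_area_px,
              fill_holes = fill_holes,
              linearize = linearize,
              saturation_method = saturation_method,
              cone_model = cone_model)
  num <- unlist(cfg[c("a_star_threshold", "y_threshold", "s_threshold",
                      "pixel_length_mm", "size_cutoff_mm",
                      "red_presence_min", "starking_red_min", "min_area_px")])
  if (any(!is.finite(num)))
    ag_stop("all thresholds must be finite", "applegrader_value_error")
  if (cfg$pixel_length_mm <= 0)
    ag_stop("pixel_length_mm must be positive", "applegrader_value_error")
  structure(cfg, class = "grading_config")
}

check_region_shape <- function(plane, apple) {
  if (!all(dim(plane) == dim(apple$mask$pixels)))
    ag_stop("plane shape does not match apple mask", "applegrader_shape_error")
}

#' Red surface regions inside the apple
#'
#' A pixel is red when its CIELAB a* strictly exceeds
#' `config$a_star_threshold` and it lies inside the apple mask.
#'
#' @param a_plane a* matrix (from [compute_planes()]).
#' @param apple an [extract_apple()] result.
#' @param config a [grading_config()].
#' @return A `binary_mask`.
#' @export
red_region_mask <- function(a_plane, apple, config = grading_config()) {
  check_region_shape(a_plane, apple)
  rule <- threshold_rule("a", config$a_star_threshold)
  m <- threshold_plane(a_plane, rule)
  new_binary_mask(m$pixels & apple$mask$pixels,
                  c(apple$mask$provenance, list(rule)))
}

#' Yellow surface regions inside the apple
#'
#' A pixel is yellow when its normalized Y strictly exceeds
#' `config$y_threshold` and it lies inside the apple mask. With
#' `y_normalization = "white"` the plane is used as is (white-relative);
#' with `"apple_max"` it is divided by its maximum over the apple region
#' first.
#'
#' @param y_plane Y matrix (from [compute_planes()]).
#' @param apple an [extract_apple()] result.
#' @param config a [grading_config()].
#' @return A `binary_mask`.
#' @export
yellow_region_mask <- function(y_plane, apple, config = grading_config()) {
  check_region_shape(y_plane, apple)
  if (config$y_normalization == "apple_max") {
    mx <- max(y_plane[apple$mask$pixels])
    if (mx > 0) y_plane <- y_plane / mx
  }
  rule <- threshold_rule("Y", config$y_threshold)
  m <- threshold_plane(y_plane, rule)
  new_binary_mask(m$pixels & apple$mask$pixels,
                  c(apple$mask$provenance, list(rule)))
}

#' Infer the apple variety from its red and yellow fractions
#'
#' No appreciable red surface means Golden; a predominantly red surface with
#' no appreciable yellow means Starking; anything else (red and yellow
#' together, or an intermediate amount of red) is Jonagold. The two rule
#' constants are configurable because only the Golden rule is fixed by the
#' reference procedure.
#'
#' @param red_fraction,yellow_fraction fractions of the apple area in \[0, 1\].
#' @param config a [grading_config()].
#' @return `"Golden"`, `"Starking"` or `"Jonagold"`.
#' @export
classify_variety <- function(red_fraction, yellow_fraction,
                             config = grading_config()) {
  stopifnot(red_fraction >= 0, red_fraction <= 1,
            yellow_fraction >= 0, yellow_fraction <= 1)
  if (red_fraction < config$red_presence_min) return("Golden")
  if (red_fraction >= config$starking_red_min &&
      yellow_fraction < config$red_presence_min) return("Starking")
  "Jonagold"
}

#' Red-vs-yellow color group
#'
#' The group is `red` when the red fraction is at least the yellow fraction
#' (ties go to red), otherwise `yellow`.
#'
#' @inheritParams classify_variety
#' @return `"red"` or `"yellow"`.
#' @export
classify_color_group <- function(red_fraction, yellow_fraction) {
  stopifnot(red_fraction >= 0, red_fraction <= 1,
            yellow_fraction >= 0, yellow_fraction <= 1)
  if (red_fraction >= yellow_fraction) "red" else "yellow"
}

#' Convert the apple's pixel extents to millimetres
#'
#' Width is the bounding-box extent along the image columns (x axis), height
#' along the rows (y axis), each multiplied by the pixel calibration.
#'
#' @param apple an [extract_apple()] result.
#' @param config a [grading_config()].
#' @return Named numeric vector `c(width_mm, height_mm)`.
#' @export
measure_size <- function(apple, config = grading_config()) {
  stopifnot(inherits(apple, "apple_region"))
  w_px <- apple$bbox[["col_max"]] - apple$bbox[["col_min"]]
  h_px <- apple$bbox[["row_max"]] - apple$bbox[["row_min"]]
  if (w_px <= 0 || h_px <= 0)
    ag_stop("degenerate bounding box", "applegrader_value_error")
  c(width_mm = w_px * config$pixel_length_mm,
    height_mm = h_px * config$pixel_length_mm)
}

#' Regular-vs-large size class
#'
#' `large` when the larger of the two extents reaches `size_cutoff_mm`
#' (boundary inclusive), else `regular`.
#'
#' @param width_mm,height_mm physical extents in millimetres.
#' @param config a [grading_config()].
#' @return `"regular"` or `"large"`.
#' @export
classify_size <- function(width_mm, height_mm, config = grading_config()) {
  stopifnot(width_mm > 0, height_mm > 0)
  if (max(width_mm, height_mm) >= config$size_cutoff_mm) "large" else "regular"
}

new_grade_record <- function(variety, color_group, size_class,
                             width_mm, height_mm,
                             red_fraction, yellow_fraction) {
  structure(list(variety = variety, color_group = color_group,
                 size_class = size_class,
                 width_mm = width_mm, height_mm = height_mm,
                 red_fraction = red_fraction,
                 yellow_fraction = yellow_fraction),
            class = "grade_record")
}

#' @export
print.grade_record <- function(x, ...) {
  cat(sprintf(
    "<grade_record> %s, %s/%s, %.1f x %.1f mm (red %.3f, yellow %.3f)\n",
    x$variety, x$color_group, x$size_class, x$width_mm, x$height_mm,
    x$red_fraction, x$yellow_fraction))
  invisible(x)
}

#' @export
as.data.frame.grade_record <- function(x, ...) {
  data.frame(variety = x$variety, color_group = x$color_group,
             size_class = x$size_class, width_mm = x$width_mm,
             height_mm = x$height_mm, red_fraction = x$red_fraction,
             yellow_fraction = x$yellow_fraction,
             stringsAsFactors = FALSE)
}

#' Bind grade records into a data frame
#'
#' @param records list of `grade_record` objects.
#' @param file optional character vector of source file names, prepended as a
#'   `file` column.
#' @return A data.frame with one row per record.
#' @export
grade_report <- function(records, file = NULL) {
  df <- do.call(rbind, lapply(records, as.data.frame))
  if (!is.null(file)) df <- cbind(file = file, df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Grade one apple image
#'
#' The full pipeline: compute the H..b planes, threshold S/Y/a* and take their
#' union, clean the mask, extract the largest component as the apple, measure
#' red and yellow fractions inside it, and derive variety, color group and
#' size class. Deterministic for a fixed image and configuration.
#'
#' @param image an `eight_bit` [color_image()].
#' @param config a [grading_config()].
#' @param return_masks also return the apple region and the red/yellow masks
#'   (default FALSE).
#' @return A `grade_record`, or, with `return_masks = TRUE`, a list with
#'   `record`, `apple`, `red_mask`, `yellow_mask`.
#' @examples
#' sc <- generate_scene(scene_spec(size_mm = 85, red_patch_fraction = 1, seed = 7))
#' grade_image(sc$image)
#' @export
grade_image <- function(image, config = grading_config(), return_masks = FALSE) {
  stack <- compute_planes(image, config)
  bg <- build_background_mask(stack, default_background_rules(config))
  cleaned <- clean_mask(bg, min_area_px = config$min_area_px,
                        fill_holes = config$fill_holes)
  apple <- extract_apple(cleaned)
  red <- red_region_mask(stack$planes$a, apple, config)
  yellow <- yellow_region_mask(stack$planes$Y, apple, config)
  red_fraction <- sum(red$pixels) / apple$area_px
  yellow_fraction <- sum(yellow$pixels) / apple$area_px
  size <- measure_size(apple, config)
  rec <- new_grade_record(
    variety = classify_variety(red_fraction, yellow_fraction, config),
    color_group = classify_color_group(red_fraction, yellow_fraction),
    size_class = classify_size(size[["width_mm"]], size[["height_mm"]], config),
    width_mm = size[["width_mm"]], height_mm = size[["height_mm"]],
    red_fraction = red_fraction, yellow_fraction = yellow_fraction)
  if (return_masks)
    list(record = rec, apple = apple, red_mask = red, yellow_mask = yellow)
  else rec
}
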