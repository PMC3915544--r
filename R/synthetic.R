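# Synthetic apple scenes with the statistical structure of the reference data.

#' Per-class RGB statistics of the reference data
#'
#' Unit-scale channel means and standard deviations of the three pixel
#' classes measured on the grading rig (about 5000 pixels per class): the red
#' and yellow apple surface and the dark, slightly bluish conveyor background.
#' These drive the synthetic generator and are the conditions under which the
#' default thresholds separate the classes.
#'
#' @return A data.frame with rows `red`, `yellow`, `background` and columns
#'   `mean_r`, `mean_g`, `mean_b`, `sd_r`, `sd_g`, `sd_b`.
#' @export
apple_class_stats <- function() {
  data.frame(
    row.names = c("red", "yellow", "background"),
    mean_r = c(0.099, 0.347, 0.013),
    mean_g = c(0.009, 0.288, 0.011),
    mean_b = c(0.010, 0.010, 0.023),
    sd_r   = c(0.040, 0.128, 0.004),
    sd_g   = c(0.004, 0.108, 0.003),
    sd_b   = c(0.000, 0.004, 0.006)
  )
}

#' Draw correlated class pixels
#'
#' Pixel scatter on a curved fruit under directional light is dominated by
#' shading, which scales all channels together. Each pixel is drawn as
#' `mu * t + eps` with a shared brightness factor `t ~ N(1, s_t)`,
#' `s_t = median(sd_i / mu_i)`, plus independent per-channel residuals sized
#' so the marginal channel standard deviations match the requested ones
#' (clamped at zero where the shared factor already accounts for them).
#' Results are clipped to \[0, 1\]. An iid-per-channel model would instead
#' inject hue noise far beyond what the reference per-class CIELAB scatter
#' allows; see the methods vignette.
#'
#' @param n number of pixels.
#' @param mu,sd length-3 unit-scale channel means and standard deviations.
#' @return An `n` x 3 matrix of unit-scale RGB values.
#' @export
draw_class_pixels <- function(n, mu, sd) {
  stopifnot(length(mu) == 3, length(sd) == 3, all(mu > 0), all(sd >= 0))
  s_t <- median(sd / mu)
  resid <- sqrt(pmax(0, sd^2 - (mu * s_t)^2))
  t <- rnorm(n, 1, s_t)
  out <- outer(t, mu) + matrix(rnorm(n * 3, 0, rep(resid, each = n)), n, 3)
  pmin(pmax(out, 0), 1)
}

#' Specify a synthetic apple scene
#'
#' An elliptical apple on a dark conveyor background, its surface tiled with
#' red and yellow blotches at requested area fractions. Geometry can be given
#' physically (`size_mm`, converted through `pixel_length_mm`) or directly in
#' pixels (`apple_axes`).
#'
#' @param size_mm physical diameter of the apple along its larger axis
#'   (the image x axis); ignored when `apple_axes` is given.
#' @param red_patch_fraction,yellow_patch_fraction target fractions of the
#'   apple surface; they must sum to 1 (the surface is either red or yellow).
#' @param apple_axes optional `c(semi_height, semi_width)` in pixels.
#' @param image_size optional `c(H, W)`; default fits the apple plus a margin.
#' @param apple_center optional `c(row, col)`; default frame center.
#' @param variety optional; inferred from the fractions when NULL (no red:
#'   Golden; red with no appreciable yellow: Starking; otherwise Jonagold).
#'   A Golden apple must have `red_patch_fraction = 0`.
#' @param class_color_stats per-class color statistics in the format of
#'   [apple_class_stats()] (rows `red`, `yellow`, `background`).
#' @param aspect ratio of the minor (vertical) to major (horizontal) semi-axis
#'   used when geometry comes from `size_mm` (default 0.9).
#' @param pixel_length_mm pixel calibration (default 0.312 mm).
#' @param n_patches number of Voronoi cells tiling the surface (default 40).
#' @param margin_px background margin around the apple in the default frame.
#' @param seed integer RNG seed; scenes are bit-reproducible given the spec.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(size_mm = 75,
                       red_patch_fraction = 1,
                       yellow_patch_fraction = 1 - red_patch_fraction,
                       apple_axes = NULL,
                       image_size = NULL,
                       apple_center = NULL,
                       variety = NULL,
                       class_color_stats = apple_class_stats(),
                       aspect = 0.9,
                       pixel_length_mm = 0.312,
                       n_patches = 40,
                       margin_px = 20,
                       seed = 1) {
  if (red_patch_fraction < 0 || red_patch_fraction > 1 ||
      yellow_patch_fraction < 0 || yellow_patch_fraction > 1)
    ag_stop("patch fractions must lie in [0, 1]", "applegrader_value_error")
  if (abs(red_patch_fraction + yellow_patch_fraction - 1) > 1e-9)
    ag_stop("red and yellow patch fractions must sum to 1",
            "applegrader_value_error")
  if (is.null(apple_axes)) {
    semi_w <- size_mm / pixel_length_mm / 2
    apple_axes <- c(semi_height = semi_w * aspect, semi_width = semi_w)
  } else {
    apple_axes <- c(semi_height = apple_axes[1], semi_width = apple_axes[2])
  }
  if (is.null(image_size)) {
    side <- ceiling(2 * max(apple_axes)) + 2 * margin_px
    image_size <- c(H = side, W = side)
  } else image_size <- c(H = image_size[1], W = image_size[2])
  if (is.null(apple_center))
    apple_center <- c(row = (image_size[["H"]] + 1) / 2,
                      col = (image_size[["W"]] + 1) / 2)
  else apple_center <- c(row = apple_center[1], col = apple_center[2])
  if (apple_center[["row"]] - apple_axes[["semi_height"]] < 1 ||
      apple_center[["row"]] + apple_axes[["semi_height"]] > image_size[["H"]] ||
      apple_center[["col"]] - apple_axes[["semi_width"]] < 1 ||
      apple_center[["col"]] + apple_axes[["semi_width"]] > image_size[["W"]])
    ag_stop("apple does not fit inside the frame", "applegrader_value_error")
  if (is.null(variety)) {
    variety <- if (red_patch_fraction == 0) "Golden"
      else if (yellow_patch_fraction < 0.01) "Starking" else "Jonagold"
  }
  variety <- match.arg(variety, c("Golden", "Starking", "Jonagold"))
  if (variety == "Golden" && red_patch_fraction > 0)
    ag_stop("a Golden apple cannot have red patches", "applegrader_value_error")
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(image_size = image_size, apple_center = apple_center,
                 apple_axes = apple_axes, variety = variety,
                 red_patch_fraction = red_patch_fraction,
                 yellow_patch_fraction = yellow_patch_fraction,
                 class_color_stats = class_color_stats,
                 pixel_length_mm = pixel_length_mm,
                 n_patches = n_patches, seed = as.integer(seed)),
            class = "scene_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Render a labeled synthetic scene
#'
#' Rasterizes the ellipse, tiles its interior with red/yellow Voronoi cells
#' whose cumulative area best matches the requested red fraction, draws every
#' pixel from its class color model ([draw_class_pixels()]), quantizes to
#' 8 bits, and records the ground truth. Bit-reproducible from `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return A list of class `labeled_scene` with `image` (`color_image`,
#'   eight_bit), `truth_mask` (`binary_mask` of the rasterized ellipse), and
#'   `truth_record` (a `grade_record` holding the ground-truth variety, color
#'   group, size class, extents, and achieved patch fractions).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    H <- spec$image_size[["H"]]; W <- spec$image_size[["W"]]
    st <- spec$class_color_stats
    rr <- row(matrix(0, H, W)); cc <- col(matrix(0, H, W))
    inside <- ((rr - spec$apple_center[["row"]]) / spec$apple_axes[["semi_height"]])^2 +
              ((cc - spec$apple_center[["col"]]) / spec$apple_axes[["semi_width"]])^2 <= 1
    n <- H * W
    px <- draw_class_pixels(n, as.numeric(st["background", 1:3]),
                            as.numeric(st["background", 4:6]))
    idx <- which(inside); ni <- length(idx)
    if (ni == 0) ag_stop("degenerate apple: no interior pixels",
                         "applegrader_value_error")
    # red/yellow Voronoi tiling of the interior
    if (spec$red_patch_fraction >= 1 - 1e-9) {
      isred <- rep(TRUE, ni)
    } else if (spec$red_patch_fraction <= 1e-9) {
      isred <- rep(FALSE, ni)
    } else {
      k <- min(spec$n_patches, ni)
      sel <- sample(ni, k)
      d2 <- outer(rr[idx], rr[idx][sel], "-")^2 +
            outer(cc[idx], cc[idx][sel], "-")^2
      cell <- max.col(-d2, ties.method = "first")
      sizes <- tabulate(cell, k)
      ord <- sample(k)
      cum <- cumsum(sizes[ord]) / ni
      # take cells until the red fraction is best matched
      n_red <- which.min(abs(cum - spec$red_patch_fraction))
      isred <- cell %in% ord[seq_len(n_red)]
    }
    if (any(isred))
      px[idx[isred], ] <- draw_class_pixels(sum(isred),
                                            as.numeric(st["red", 1:3]),
                                            as.numeric(st["red", 4:6]))
    if (any(!isred))
      px[idx[!isred], ] <- draw_class_pixels(sum(!isred),
                                             as.numeric(st["yellow", 1:3]),
                                             as.numeric(st["yellow", 4:6]))
    img <- color_image(array(round(px * 255), c(H, W, 3)),
                       scale = "eight_bit")
    truth_mask <- new_binary_mask(inside, list("synthetic_ellipse"))
    red_frac <- sum(isred) / ni
    yellow_frac <- 1 - red_frac
    cal <- grading_config(pixel_length_mm = spec$pixel_length_mm)
    apple <- structure(list(mask = truth_mask,
                            bbox = c(row_min = min(rr[idx]) - 1L,
                                     col_min = min(cc[idx]) - 1L,
                                     row_max = max(rr[idx]),
                                     col_max = max(cc[idx])),
                            area_px = ni), class = "apple_region")
    size <- measure_size(apple, cal)
    truth <- new_grade_record(
      variety = spec$variety,
      color_group = classify_color_group(red_frac, yellow_frac),
      size_class = classify_size(size[["width_mm"]], size[["height_mm"]], cal),
      width_mm = size[["width_mm"]], height_mm = size[["height_mm"]],
      red_fraction = red_frac, yellow_fraction = yellow_frac)
    structure(list(image = img, truth_mask = truth_mask, truth_record = truth,
                   spec = spec),
              class = "labeled_scene")
  })
}

#' @export
print.labeled_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<labeled_scene> %d x %d, truth: %s %s/%s (red %.2f)\n",
              d[1], d[2], x$truth_record$variety, x$truth_record$color_group,
              x$truth_record$size_class, x$truth_record$red_fraction))
  invisible(x)
}

#' Scene specifications for a graded batch
#'
#' Produces `n` scene specs spanning the four color/size groups at given
#' proportions (or counts). Red-group apples are predominantly red
#' (`red_patch_fraction` uniform in `red_range`, Starking-like); yellow-group
#' apples are Golden (no red). Physical sizes are drawn uniformly in the
#' per-class ranges and converted to pixel axes through `pixel_length_mm`.
#'
#' @param n number of scenes (> 0).
#' @param group_mix named proportions or counts for
#'   `red/regular`, `red/large`, `yellow/regular`, `yellow/large`;
#'   normalized internally; counts are apportioned by largest remainder so
#'   they sum exactly to `n`.
#' @param size_ranges_mm list with `regular` and `large` `c(min, max)`
#'   diameter ranges in mm; the defaults sit 5 mm clear of the 75 mm cutoff.
#' @param seed integer; per-scene seeds are drawn from it reproducibly.
#' @param red_range red fraction range of red-group apples.
#' @param pixel_length_mm pixel calibration.
#' @return A list of [scene_spec()] objects, grouped in the order of
#'   `group_mix`.
#' @export
batch_scene_specs <- function(n,
                              group_mix = c("red/regular" = 0.25,
                                            "red/large" = 0.25,
                                            "yellow/regular" = 0.25,
                                            "yellow/large" = 0.25),
                              size_ranges_mm = list(regular = c(60, 70),
                                                    large = c(80, 90)),
                              seed = 1,
                              red_range = c(0.85, 1),
                              pixel_length_mm = 0.312) {
  if (n < 1) ag_stop("empty batch requested", "applegrader_value_error")
  groups <- c("red/regular", "red/large", "yellow/regular", "yellow/large")
  if (is.null(names(group_mix))) names(group_mix) <- groups
  stopifnot(setequal(names(group_mix), groups), all(group_mix >= 0),
            sum(group_mix) > 0)
  p <- group_mix[groups] / sum(group_mix)
  counts <- floor(n * p)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * p - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L, n)
    specs <- vector("list", n)
    i <- 0
    for (g in groups) {
      if (counts[[g]] == 0) next
      parts <- strsplit(g, "/")[[1]]
      rng <- size_ranges_mm[[parts[2]]]
      for (k in seq_len(counts[[g]])) {
        i <- i + 1
        red <- if (parts[1] == "red")
          runif(1, red_range[1], red_range[2]) else 0
        specs[[i]] <- scene_spec(
          size_mm = runif(1, rng[1], rng[2]),
          red_patch_fraction = red,
          aspect = runif(1, 0.85, 1),
          pixel_length_mm = pixel_length_mm,
          seed = scene_seeds[i])
      }
    }
    specs
  })
}

#' Generate a labeled scene batch
#'
#' Convenience wrapper rendering every spec from [batch_scene_specs()]. For
#' large batches, render and grade specs one at a time instead to bound
#' memory.
#'
#' @inheritParams batch_scene_specs
#' @param ... passed to [batch_scene_specs()].
#' @return A list of `labeled_scene` objects.
#' @export
generate_batch <- function(n, ..., seed = 1) {
  lapply(batch_scene_specs(n, ..., seed = seed), generate_scene)
}

#' Write a scene batch to disk
#'
#' Writes `scene_0001.png`, ... plus a `truth.csv` with one ground-truth row
#' per scene.
#'
#' @param scenes list of `labeled_scene` objects.
#' @param dir output directory (created if needed).
#' @return The path of the truth CSV, invisibly.
#' @export
write_scene_batch <- function(scenes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("scene_%04d.png", seq_along(scenes))
  for (i in seq_along(scenes))
    write_color_image(scenes[[i]]$image, file.path(dir, files[i]))
  truth <- grade_report(lapply(scenes, `[[`, "truth_record"), file = files)
  path <- file.path(dir, "truth.csv")
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
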