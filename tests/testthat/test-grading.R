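make_region <- function(h, w, rows, cols) {
  px <- matrix(FALSE, h, w)
  px[rows, cols] <- TRUE
  extract_apple(new_mask_for_test(px))
}

test_that("red regions require a* strictly above the threshold, inside the apple", {
  cfg <- grading_config()
  apple <- make_region(4, 4, 1:3, 1:3)
  a <- matrix(0, 4, 4)
  a[1, 1] <- 29.095          # reference red-class mean
  a[2, 1] <- -4.756          # reference yellow-class mean
  a[3, 1] <- 15              # exactly at threshold
  a[4, 4] <- 40              # red but outside the apple
  m <- red_region_mask(a, apple, cfg)
  expect_true(m$pixels[1, 1])
  expect_false(m$pixels[2, 1])
  expect_false(m$pixels[3, 1])
  expect_false(m$pixels[4, 4])
  expect_error(red_region_mask(matrix(0, 2, 2), apple, cfg),
               class = "applegrader_shape_error")
})

test_that("yellow regions threshold Y inside the apple and match a loop oracle", {
  cfg <- grading_config()
  apple <- make_region(6, 6, 2:5, 2:5)
  set.seed(21)
  y <- matrix(runif(36), 6, 6)
  m <- yellow_region_mask(y, apple, cfg)
  ref <- matrix(FALSE, 6, 6)
  for (i in 1:6) for (j in 1:6)
    ref[i, j] <- y[i, j] > 0.5 && apple$mask$pixels[i, j]
  expect_identical(m$pixels, ref)
  # apple_max normalization divides by the in-apple maximum first
  cfg2 <- grading_config(y_normalization = "apple_max")
  m2 <- yellow_region_mask(y, apple, cfg2)
  mx <- max(y[apple$mask$pixels])
  expect_identical(m2$pixels, (y / mx > 0.5) & apple$mask$pixels)
})

test_that("variety and color-group rules follow the configured thresholds", {
  expect_equal(classify_variety(0.0, 0.8), "Golden")
  expect_equal(classify_variety(0.009, 0.5), "Golden")
  expect_equal(classify_variety(0.9, 0.0), "Starking")
  expect_equal(classify_variety(0.9, 0.2), "Jonagold")
  expect_equal(classify_variety(0.4, 0.4), "Jonagold")
  expect_equal(classify_color_group(0.7, 0.1), "red")
  expect_equal(classify_color_group(0.0, 0.9), "yellow")
  expect_equal(classify_color_group(0.5, 0.5), "red")  # tie goes to red
  expect_error(classify_variety(1.2, 0))
})

test_that("size measurement scales linearly with the pixel calibration", {
  apple <- make_region(300, 300, 1:150, 1:200)
  s <- measure_size(apple, grading_config())
  expect_equal(unname(s), c(200 * 0.312, 150 * 0.312))
  s2 <- measure_size(apple, grading_config(pixel_length_mm = 0.624))
  expect_equal(unname(s2), 2 * unname(s))
  one <- make_region(3, 3, 2, 2)
  expect_equal(unname(measure_size(one, grading_config())), c(0.312, 0.312))
})

test_that("size class uses the larger extent with an inclusive cutoff", {
  cfg <- grading_config(size_cutoff_mm = 75)
  expect_equal(classify_size(80, 70, cfg), "large")
  expect_equal(classify_size(60, 55, cfg), "regular")
  expect_equal(classify_size(75, 10, cfg), "large")
})

test_that("grade_image recovers ground truth on synthetic scenes", {
  red <- fixture_red_scene()
  rec <- grade_image(red$image)
  expect_equal(rec$color_group, "red")
  expect_equal(rec$size_class, "large")
  expect_equal(rec$variety, "Starking")
  expect_gt(rec$red_fraction, 0.9)
  expect_equal(rec$width_mm, red$truth_record$width_mm, tolerance = 0.02)
  yellow <- fixture_yellow_scene()
  rec <- grade_image(yellow$image)
  expect_equal(rec$color_group, "yellow")
  expect_equal(rec$size_class, "regular")
  expect_equal(rec$variety, "Golden")
  expect_lt(rec$red_fraction, 0.01)
  expect_true(rec$red_fraction >= 0 && rec$red_fraction <= 1)
  expect_true(rec$yellow_fraction >= 0 && rec$yellow_fraction <= 1)
})

test_that("grading is invariant to translating the apple in the frame", {
  sc <- fixture_yellow_scene()
  px <- sc$image$pixels
  shifted <- px[c(31:nrow(px), 1:30), c(11:ncol(px), 1:10), , drop = FALSE]
  rec1 <- grade_image(sc$image)
  rec2 <- grade_image(color_image(shifted, scale = "eight_bit"))
  expect_equal(rec1[c("variety", "color_group", "size_class", "width_mm",
                      "height_mm", "red_fraction", "yellow_fraction")],
               rec2[c("variety", "color_group", "size_class", "width_mm",
                      "height_mm", "red_fraction", "yellow_fraction")])
})

test_that("an apple-free scene signals no_apple_found", {
  set.seed(4)
  st <- apple_class_stats()
  px <- draw_class_pixels(50 * 50, as.numeric(st["background", 1:3]),
                          as.numeric(st["background", 4:6]))
  img <- color_image(array(round(px * 255), c(50, 50, 3)))
  expect_error(grade_image(img), class = "no_apple_found")
})
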