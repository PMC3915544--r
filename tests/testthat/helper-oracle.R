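# Scalar reference implementations, independent of the package's vectorized
# code paths: plain per-pixel loops with the colorimetric constants restated.

oracle_M_rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

oracle_M_hpe <- matrix(c(
   0.40024, 0.70760, -0.08081,
  -0.22630, 1.16532,  0.04570,
   0.00000, 0.00000,  0.91822
), nrow = 3, byrow = TRUE)

oracle_d65 <- c(0.95047, 1.00000, 1.08883)
oracle_d55 <- c(0.95682, 1.00000, 0.92149)

oracle_linearize <- function(c) {
  if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
}

oracle_lab_f <- function(q) {
  if (q > 0.008856) q^(1 / 3) else 7.787 * q + 16 / 116
}

# one 8-bit RGB triplet -> c(X, Y, Z, L, a, b), scalar arithmetic throughout
oracle_rgb_to_lab_d55 <- function(rgb8, linearize = TRUE) {
  rgb <- rgb8 / 255
  if (linearize) rgb <- vapply(rgb, oracle_linearize, 0)
  xyz <- as.numeric(oracle_M_rgb2xyz %*% rgb)
  resp_s <- as.numeric(oracle_M_hpe %*% oracle_d65)
  resp_d <- as.numeric(oracle_M_hpe %*% oracle_d55)
  M <- solve(oracle_M_hpe) %*% diag(resp_d / resp_s) %*% oracle_M_hpe
  xyz <- as.numeric(M %*% xyz)
  fx <- oracle_lab_f(xyz[1] / oracle_d55[1])
  fy <- oracle_lab_f(xyz[2] / oracle_d55[2])
  fz <- oracle_lab_f(xyz[3] / oracle_d55[3])
  c(X = xyz[1], Y = xyz[2], Z = xyz[3],
    L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# loop a full image through the scalar oracle
oracle_image_to_lab_d55 <- function(image8, linearize = TRUE) {
  d <- dim(image8)
  out <- array(NA_real_, c(d[1], d[2], 6))
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out[i, j, ] <- oracle_rgb_to_lab_d55(image8[i, j, ], linearize)
  out
}

random_image8 <- function(h = 16, w = 16) {
  color_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

# printed D65 -> D55 matrix of the reference rig
printed_adaptation_matrix <- matrix(c(
  1.0096, 0.0331, -0.0330,
  0.0036, 0.9973, -0.0007,
  0.0000, 0.0000,  0.8463
), nrow = 3, byrow = TRUE)

new_mask_for_test <- function(px) {
  threshold_plane(px * 1, threshold_rule("mask", 0.5))
}

# small synthetic fixtures used by several test files
fixture_red_scene <- function(seed = 7, size_mm = 85)
  generate_scene(scene_spec(size_mm = size_mm, red_patch_fraction = 1, seed = seed))

fixture_yellow_scene <- function(seed = 8, size_mm = 63)
  generate_scene(scene_spec(size_mm = size_mm, red_patch_fraction = 0, seed = seed))
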