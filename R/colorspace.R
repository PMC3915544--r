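# Color constants ------------------------------------------------------------

# sRGB (linear) -> CIE XYZ under D65, 2 degree observer.
.M_RGB2XYZ_D65 <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# XYZ -> cone response matrices. "von_kries" is the classic Hunt-Pointer-Estevez
# matrix normalized to D65; "bradford" is the sharpened Bradford transform.
.CONE_MATRICES <- list(
  von_kries = matrix(c(
     0.40024, 0.70760, -0.08081,
    -0.22630, 1.16532,  0.04570,
     0.00000, 0.00000,  0.91822
  ), nrow = 3, byrow = TRUE),
  bradford = matrix(c(
     0.8951,  0.2664, -0.1614,
    -0.7502,  1.7135,  0.0367,
     0.0389, -0.0685,  1.0296
  ), nrow = 3, byrow = TRUE)
)

# Reference whites (Y normalized to 1). D65 is the white implied by the RGB->XYZ
# matrix column sums, so that unit linear RGB maps exactly onto it; D55 is the
# 2-degree daylight white of the grading rig's 5300 K lamps.
.WHITES <- list(
  D65 = c(X = 0.95047, Y = 1.00000, Z = 1.08883),
  D55 = c(X = 0.95682, Y = 1.00000, Z = 0.92149)
)

.LAB_EPS <- 0.008856  # CIELAB cube-root / linear branch switch

#' Reference white points
#'
#' @param name `"D65"` (average daylight, the sRGB source white) or `"D55"`
#'   (the destination white of the grading rig's fluorescent lamps), or
#'   `"custom"` with `xyz` supplied.
#' @param xyz length-3 tristimulus vector for a custom white; `Y` must be 1.
#' @return A named numeric vector of class `white_point`.
#' @examples
#' white_point("D55")
#' @export
white_point <- function(name = c("D65", "D55", "custom"), xyz = NULL) {
  name <- match.arg(name)
  w <- if (name == "custom") {
    stopifnot(is.numeric(xyz), length(xyz) == 3)
    setNames(as.numeric(xyz), c("X", "Y", "Z"))
  } else .WHITES[[name]]
  if (any(w <= 0))
    ag_stop("white point components must be strictly positive",
            "applegrader_domain_error")
  if (abs(w[["Y"]] - 1) > 1e-9)
    ag_stop("white point must be normalized to Y = 1", "applegrader_domain_error")
  structure(w, class = "white_point", name = name)
}

#' Cone response models for chromatic adaptation
#'
#' @param name `"von_kries"` for the classic Hunt-Pointer-Estevez cone matrix
#'   (the package default: it reproduces the rig's printed D65 to D55 matrix),
#'   or `"bradford"`.
#' @return A list of class `cone_model` with elements `name` and `M_A`.
#' @export
cone_model <- function(name = c("von_kries", "bradford")) {
  name <- match.arg(name)
  structure(list(name = name, M_A = .CONE_MATRICES[[name]]),
            class = "cone_model")
}

# Colorspace operations --------------------------------------------------------

#' Linearize gamma-encoded sRGB
#'
#' Applies the IEC 61966-2-1 transfer function: channels at or below 0.04045
#' are divided by 12.92, larger channels map through
#' `((c + 0.055) / 1.055)^2.4`. Monotone, continuous, and fixing 0 and 1.
#'
#' @param image a unit-scale `color_image` tagged `sRGB_nonlinear`.
#' @return A unit-scale `color_image` tagged `sRGB_linear`.
#' @export
srgb_linearize <- function(image) {
  stopifnot(inherits(image, "color_image"))
  if (image$scale != "unit")
    ag_stop("srgb_linearize() expects a unit-scale image",
            "applegrader_scale_error")
  if (image$colorspace != "sRGB_nonlinear")
    ag_stop("image is already tagged linear", "applegrader_tag_error")
  color_image(srgb_transfer(image$pixels), scale = "unit",
              colorspace = "sRGB_linear")
}

# scalar/vector form of the sRGB electro-optical transfer function
srgb_transfer <- function(c) {
  ifelse(c <= 0.04045, c / 12.92, ((c + 0.055) / 1.055)^2.4)
}

#' Convert RGB to HSV planes
#'
#' Two saturation conventions are supported. `"hexcone"` is the standard
#' software definition (`S = (max - min) / max`, as in MATLAB's `rgb2hsv` and
#' `grDevices::rgb2hsv`). `"hsi"` is the cylindrical-colorimetry form
#' `S = 1 - 3 min(R,G,B) / (R+G+B)`, the convention under which the reference
#' per-class saturation statistics were measured; the segmentation pipeline
#' defaults to it (see [grading_config()]). Hue is returned as a fraction of a
#' turn in \[0, 1) with red at 0 under both conventions; black (and, for
#' `"hsi"`, a zero-sum pixel) has S = 0 and H = 0.
#'
#' @param image a unit-scale `color_image`.
#' @param saturation `"hexcone"` (default) or `"hsi"`.
#' @return A list with H, S, V matrices (V is always `max(R, G, B)`).
#' @export
rgb_to_hsv <- function(image, saturation = c("hexcone", "hsi")) {
  stopifnot(inherits(image, "color_image"))
  saturation <- match.arg(saturation)
  if (image$scale != "unit")
    ag_stop("rgb_to_hsv() expects a unit-scale image", "applegrader_scale_error")
  d <- dim(image$pixels)
  r <- matrix(image$pixels[, , 1], d[1], d[2])
  g <- matrix(image$pixels[, , 2], d[1], d[2])
  b <- matrix(image$pixels[, , 3], d[1], d[2])
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- v - mn
  h <- matrix(0, nrow(v), ncol(v))
  nz <- delta > 0
  i <- nz & v == r
  h[i] <- ((g - b)[i] / delta[i]) %% 6
  i <- nz & v == g & v != r
  h[i] <- (b - r)[i] / delta[i] + 2
  i <- nz & v == b & v != r & v != g
  h[i] <- (r - g)[i] / delta[i] + 4
  h <- h / 6
  s <- if (saturation == "hexcone") {
    ifelse(v > 0, delta / v, 0)
  } else {
    sm <- r + g + b
    ifelse(sm > 0, 1 - 3 * mn / sm, 0)
  }
  list(H = h, S = s, V = v)
}

#' Linear RGB to CIE XYZ under D65
#'
#' Per-pixel product with the sRGB-to-XYZ matrix (D65, 2 degree observer).
#' Unit linear RGB maps to the D65 white (0.95047, 1, 1.08883).
#'
#' @param image a unit-scale `color_image` tagged `sRGB_linear`.
#' @return A list with X, Y, Z matrices.
#' @export
linear_rgb_to_xyz_d65 <- function(image) {
  stopifnot(inherits(image, "color_image"))
  if (image$colorspace != "sRGB_linear")
    ag_stop("linear_rgb_to_xyz_d65() expects an sRGB_linear image",
            "applegrader_tag_error")
  rgb_matrix_to_xyz(image$pixels)
}

# matrix product without tag enforcement; shared by the strict op above and by
# the as-measured (non-linearized) pipeline convention of compute_planes()
rgb_matrix_to_xyz <- function(px) {
  d <- dim(px)
  flat <- matrix(px, d[1] * d[2], 3) %*% t(.M_RGB2XYZ_D65)
  list(X = matrix(flat[, 1], d[1], d[2]),
       Y = matrix(flat[, 2], d[1], d[2]),
       Z = matrix(flat[, 3], d[1], d[2]))
}

#' Build a von Kries chromatic adaptation matrix
#'
#' Maps tristimulus values measured under a source illuminant to their
#' appearance under a destination illuminant by scaling cone responses:
#' `M = M_A^-1 diag(rho_D/rho_S, gamma_D/gamma_S, beta_D/beta_S) M_A`,
#' where `(rho, gamma, beta) = M_A w` are the cone responses of each white.
#' By construction `M` maps the source white exactly onto the destination
#' white.
#'
#' @param source,destination [white_point()] objects.
#' @param cone a [cone_model()]; the default classic von Kries
#'   (Hunt-Pointer-Estevez) model reproduces the printed rig matrix for
#'   D65 to D55.
#' @return A list of class `adaptation_matrix` with elements `M`, `source`,
#'   `destination`, `cone_model`.
#' @examples
#' von_kries_matrix(white_point("D65"), white_point("D55"))$M
#' @export
von_kries_matrix <- function(source, destination, cone = cone_model("von_kries")) {
  stopifnot(inherits(source, "white_point"), inherits(destination, "white_point"),
            inherits(cone, "cone_model"))
  if (any(source <= 0) || any(destination <= 0))
    ag_stop("white point components must be strictly positive",
            "applegrader_domain_error")
  M_A <- cone$M_A
  if (abs(det(M_A)) < 1e-12)
    ag_stop("cone matrix is singular", "applegrader_singular_error")
  resp_s <- as.numeric(M_A %*% as.numeric(source))
  resp_d <- as.numeric(M_A %*% as.numeric(destination))
  M <- solve(M_A) %*% diag(resp_d / resp_s) %*% M_A
  structure(list(M = M, source = source, destination = destination,
                 cone_model = cone),
            class = "adaptation_matrix")
}

#' @export
print.adaptation_matrix <- function(x, ...) {
  cat(sprintf("<adaptation_matrix> %s -> %s (%s cones)\n",
              attr(x$source, "name"), attr(x$destination, "name"),
              x$cone_model$name))
  print(round(x$M, 6))
  invisible(x)
}

#' Apply a chromatic adaptation to XYZ planes
#'
#' Per-pixel 3 x 3 matrix product; linear in its input.
#'
#' @param planes list with X, Y, Z matrices of a common shape.
#' @param adaptation an [von_kries_matrix()] result (or any list with a 3 x 3
#'   matrix in `$M`).
#' @return A list with adapted X, Y, Z matrices.
#' @export
adapt_xyz <- function(planes, adaptation) {
  X <- planes$X; Y <- planes$Y; Z <- planes$Z
  if (is.null(X) || is.null(Y) || is.null(Z))
    ag_stop("`planes` must contain X, Y and Z", "applegrader_shape_error")
  if (!all(dim(X) == dim(Y)) || !all(dim(X) == dim(Z)))
    ag_stop("X, Y, Z planes must share one shape", "applegrader_shape_error")
  M <- adaptation$M
  d <- dim(X)
  flat <- cbind(as.numeric(X), as.numeric(Y), as.numeric(Z)) %*% t(M)
  list(X = matrix(flat[, 1], d[1], d[2]),
       Y = matrix(flat[, 2], d[1], d[2]),
       Z = matrix(flat[, 3], d[1], d[2]))
}

# CIELAB companding function
lab_f <- function(q) ifelse(q > .LAB_EPS, q^(1 / 3), 7.787 * q + 16 / 116)

#' CIE XYZ to CIELAB
#'
#' Standard CIELAB under an explicit reference white:
#' `L* = 116 f(Y/Yn) - 16`, `a* = 500 (f(X/Xn) - f(Y/Yn))`,
#' `b* = 200 (f(Y/Yn) - f(Z/Zn))`, with `f(q) = q^(1/3)` above 0.008856 and
#' the linear segment `7.787 q + 16/116` below.
#'
#' @param planes list with X, Y, Z matrices.
#' @param white a [white_point()]; the pipeline uses D55.
#' @return A list with L, a, b matrices.
#' @export
xyz_to_lab <- function(planes, white = white_point("D55")) {
  stopifnot(inherits(white, "white_point"))
  X <- planes$X; Y <- planes$Y; Z <- planes$Z
  if (min(X, Y, Z) < 0)
    ag_stop("negative tristimulus values", "applegrader_domain_error")
  fx <- lab_f(X / white[["X"]])
  fy <- lab_f(Y / white[["Y"]])
  fz <- lab_f(Z / white[["Z"]])
  list(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Plane stack ------------------------------------------------------------------

new_plane_stack <- function(planes, white) {
  structure(list(planes = planes, white = white), class = "plane_stack")
}

#' @export
print.plane_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<plane_stack> %d x %d, planes: %s (Lab white: %s)\n",
              d[1], d[2], paste(names(x$planes), collapse = ", "),
              attr(x$white, "name")))
  invisible(x)
}

#' Full 8-bit RGB to CIELAB (D55) conversion
#'
#' The standards-compliant composition: rescale to unit, sRGB linearization,
#' RGB to XYZ under D65, von Kries adaptation to D55, and CIELAB against the
#' D55 white. Set `linearize = FALSE` to skip the transfer function and apply
#' the RGB-to-XYZ matrix to gamma-encoded values directly; that "as-measured"
#' convention is the one the reference class statistics and the default
#' grading thresholds were established under (see the methods vignette), and
#' is the default of the grading pipeline itself.
#'
#' @param image an `eight_bit` [color_image()].
#' @param cone a [cone_model()] for the adaptation step.
#' @param linearize apply the IEC 61966-2-1 transfer function (default TRUE).
#' @return A `plane_stack` with X, Y, Z (D55-adapted) and L, a, b planes.
#' @examples
#' px <- array(c(255, 0, 0), c(1, 1, 3))
#' rgb_to_lab_d55(color_image(px))$planes$a  # saturated red: large positive a*
#' @export
rgb_to_lab_d55 <- function(image, cone = cone_model("von_kries"),
                           linearize = TRUE) {
  img <- normalize_rgb(image)
  px <- if (linearize) srgb_linearize(img)$pixels else img$pixels
  xyz <- rgb_matrix_to_xyz(px)
  adapted <- adapt_xyz(xyz, von_kries_matrix(white_point("D65"),
                                             white_point("D55"), cone))
  lab <- xyz_to_lab(adapted, white_point("D55"))
  new_plane_stack(c(adapted, lab), white_point("D55"))
}

#' Compute every plane the grading pipeline consumes
#'
#' Derives H, S, V, X, Y, Z, L, a, b from an 8-bit image under the conventions
#' in `config`: the saturation form (`saturation_method`), whether the sRGB
#' transfer function is applied before the XYZ matrix (`linearize`), and the
#' cone model of the D65 to D55 adaptation (`cone_model`). X, Y, Z are the
#' D55-adapted tristimulus planes, relative to a reference white of Y = 1.
#'
#' @param image an `eight_bit` [color_image()].
#' @param config a [grading_config()].
#' @return A `plane_stack` with all nine named planes.
#' @export
compute_planes <- function(image, config = grading_config()) {
  img <- normalize_rgb(image)
  hsv <- rgb_to_hsv(img, saturation = config$saturation_method)
  px <- if (config$linearize) srgb_linearize(img)$pixels else img$pixels
  xyz <- rgb_matrix_to_xyz(px)
  adapted <- adapt_xyz(xyz, von_kries_matrix(white_point("D65"),
                                             white_point("D55"),
                                             cone_model(config$cone_model)))
  lab <- xyz_to_lab(adapted, white_point("D55"))
  new_plane_stack(c(hsv, adapted, lab), white_point("D55"))
}
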