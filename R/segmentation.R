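# Binary masks and background removal.

new_binary_mask <- function(pixels, provenance = list()) {
  structure(list(pixels = pixels, provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px; provenance: %s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              paste(vapply(x$provenance, format_provenance, ""),
                    collapse = " | ")))
  invisible(x)
}

format_provenance <- function(p) {
  if (inherits(p, "threshold_rule"))
    sprintf("%s > %g", p$plane, p$threshold)
  else as.character(p)
}

#' A single-plane threshold rule
#'
#' @param plane plane name (one of H, S, V, X, Y, Z, L, a, b).
#' @param threshold threshold value in the plane's units.
#' @param direction only `"greater"` is defined: a pixel passes when its value
#'   strictly exceeds the threshold.
#' @return A list of class `threshold_rule`.
#' @export
threshold_rule <- function(plane, threshold, direction = "greater") {
  stopifnot(is.character(plane), length(plane) == 1,
            is.numeric(threshold), length(threshold) == 1, is.finite(threshold))
  direction <- match.arg(direction, "greater")
  structure(list(plane = plane, threshold = threshold, direction = direction),
            class = "threshold_rule")
}

#' Threshold one plane into a binary mask
#'
#' A pixel is foreground iff its value strictly exceeds the rule's threshold.
#'
#' @param plane numeric matrix.
#' @param rule a [threshold_rule()].
#' @return A `binary_mask` whose provenance records the rule.
#' @export
threshold_plane <- function(plane, rule) {
  stopifnot(is.matrix(plane), inherits(rule, "threshold_rule"))
  if (anyNA(plane) || any(!is.finite(plane)))
    ag_stop("plane contains NA/NaN/Inf values", "applegrader_value_error")
  new_binary_mask(plane > rule$threshold, list(rule))
}

#' Default background-removal rules
#'
#' Foreground (apple) pixels fire at least one of: saturation above
#' `s_threshold` (vivid surface vs the desaturated dark conveyor), luminance Y
#' above `y_threshold` (bright yellow flesh), or a* above `a_star_threshold`
#' (red flesh). The union of the three single-plane masks is the apple mask.
#'
#' @param config a [grading_config()].
#' @return A list of [threshold_rule()] objects for the S, Y and a planes.
#' @export
default_background_rules <- function(config = grading_config()) {
  list(threshold_rule("S", config$s_threshold),
       threshold_rule("Y", config$y_threshold),
       threshold_rule("a", config$a_star_threshold))
}

#' Combine per-plane thresholds into one apple mask
#'
#' Logical union of the single-plane masks: red regions fire the a* rule,
#' yellow regions the Y (and S) rules, and the whole fruit fires the S rule
#' against the desaturated background, so a union keeps both color classes
#' while an intersection would erase one.
#'
#' @param stack a `plane_stack` from [compute_planes()].
#' @param rules non-empty list of [threshold_rule()]s referencing planes
#'   present in `stack`.
#' @return A `binary_mask` whose provenance lists every contributing rule.
#' @export
build_background_mask <- function(stack, rules = default_background_rules()) {
  stopifnot(inherits(stack, "plane_stack"))
  if (length(rules) == 0)
    ag_stop("at least one threshold rule is required", "applegrader_value_error")
  acc <- NULL
  for (rule in rules) {
    if (is.null(stack$planes[[rule$plane]]))
      ag_stop(sprintf("plane '%s' not present in stack", rule$plane),
              "applegrader_value_error")
    m <- threshold_plane(stack$planes[[rule$plane]], rule)
    acc <- if (is.null(acc)) m$pixels else acc | m$pixels
  }
  new_binary_mask(acc, rules)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that touch
# diagonally are merged with a union-find pass over label adjacencies.
label_components <- function(pixels) {
  lab <- EBImage::bwlabel(pixels)
  lab <- matrix(as.integer(lab), nrow(pixels), ncol(pixels))
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]  # down-left diagonal
  pairs <- rbind(cbind(as.integer(a1), as.integer(b1)),
                 cbind(as.integer(a2), as.integer(b2)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  # compact labels to 1..k in first-appearance (column-major scan) order
  u <- unique(lab[lab > 0L])
  remap <- integer(max(u)); remap[u] <- seq_along(u)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Remove specks and fill holes in a mask
#'
#' Deletes 8-connected foreground components smaller than `min_area_px` and,
#' optionally, fills interior holes. Idempotent.
#'
#' @param mask a `binary_mask`.
#' @param min_area_px minimum component area kept, in pixels.
#' @param fill_holes fill enclosed background holes (default TRUE).
#' @return A cleaned `binary_mask`; provenance gains a cleanup entry.
#' @export
clean_mask <- function(mask, min_area_px = 100, fill_holes = TRUE) {
  stopifnot(inherits(mask, "binary_mask"))
  px <- mask$pixels
  if (min_area_px > 1 && any(px)) {
    lab <- label_components(px)
    sizes <- tabulate(lab[lab > 0L])
    px <- matrix(lab > 0L & sizes[pmax(lab, 1L)] >= min_area_px,
                 nrow(px), ncol(px))
    px[is.na(px)] <- FALSE
  }
  if (fill_holes && any(px)) {
    filled <- EBImage::fillHull(EBImage::Image(px * 1))
    px <- matrix(as.numeric(filled) > 0, nrow(px), ncol(px))
  }
  new_binary_mask(px, c(mask$provenance,
                        sprintf("clean(min_area_px=%g, fill_holes=%s)",
                                min_area_px, fill_holes)))
}

#' Extract the apple as the largest connected component
#'
#' Selects the largest 8-connected foreground component; ties are broken in
#' favor of the component whose first pixel comes earliest in row-major scan
#' order. The bounding box is 0-based and half-open: `(row_min, col_min,
#' row_max, col_max)` with `row_max`/`col_max` one past the last pixel.
#'
#' @param mask a `binary_mask`.
#' @return A list of class `apple_region` with `mask`, `bbox`, `area_px`.
#' @export
extract_apple <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$pixels))
    ag_stop("no apple found: mask is empty", "no_apple_found")
  lab <- label_components(mask$pixels)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # earliest first pixel in row-major order wins
    ord <- order(row(lab)[lab > 0L] * 1e9 + col(lab)[lab > 0L])
    first_seen <- lab[lab > 0L][ord]
    best <- first_seen[first_seen %in% best][1]
  }
  px <- lab == best
  rows <- range(row(px)[px]); cols <- range(col(px)[px])
  structure(list(
    mask = new_binary_mask(px, c(mask$provenance, "largest_component")),
    bbox = c(row_min = rows[1] - 1L, col_min = cols[1] - 1L,
             row_max = rows[2], col_max = cols[2]),
    area_px = sum(px)
  ), class = "apple_region")
}

#' @export
print.apple_region <- function(x, ...) {
  cat(sprintf("<apple_region> area %d px, bbox [%d, %d) x [%d, %d)\n",
              x$area_px, x$bbox[["row_min"]], x$bbox[["row_max"]],
              x$bbox[["col_min"]], x$bbox[["col_max"]]))
  invisible(x)
}

#' Write a binary mask as a 0/255 grayscale PNG
#'
#' @param mask a `binary_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}

#' Read a 0/255 PNG as a binary mask
#'
#' @param path PNG path; any value above 0.5 becomes foreground.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  new_binary_mask(px > 0.5, list(sprintf("read_mask(%s)", basename(path))))
}
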