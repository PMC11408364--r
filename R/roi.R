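#' Axis-aligned region-of-interest box
#'
#' A rectangular sub-volume restricting which voxels enter the analysis.
#' Coordinates are 0-based, half-open voxel intervals `[min, max)` per axis
#' in `(z, y, x)` order — standard array-slicing semantics, so a box with
#' `min = (0,0,0)` and `max = dims` is the whole stack. Boxes may be given in
#' physical units (microns) instead; they are converted to voxel indices with
#' the stack's `voxel_spacing` at crop time.
#'
#' @param min_corner,max_corner numeric `(z, y, x)` corners with
#'   `min_corner <= max_corner` componentwise.
#' @param units `"voxel"` (default) or `"micron"`.
#' @return an object of class `roi_box`.
#' @examples
#' roi_box(c(0, 0, 0), c(2, 8, 8))  # first two slices of an 8x8 stack
#' @export
roi_box <- function(min_corner, max_corner, units = c("voxel", "micron")) {
  units <- match.arg(units)
  min_corner <- as.numeric(min_corner); max_corner <- as.numeric(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L)
    stop("ROI corners must be (z, y, x) triples", call. = FALSE)
  if (any(is.na(min_corner)) || any(is.na(max_corner)))
    stop("ROI corners must be numeric", call. = FALSE)
  if (any(min_corner > max_corner))
    stop("ROI min corner exceeds max corner", call. = FALSE)
  structure(list(min_corner = min_corner, max_corner = max_corner,
                 units = units),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> [%s) x [%s) x [%s) (%s units, z/y/x)\n",
              paste(c(x$min_corner[1], x$max_corner[1]), collapse = ", "),
              paste(c(x$min_corner[2], x$max_corner[2]), collapse = ", "),
              paste(c(x$min_corner[3], x$max_corner[3]), collapse = ", "),
              x$units))
  invisible(x)
}

# resolve a box against stack dims: clamp to the extent, return integer
# 0-based half-open bounds; error if the intersection is empty
.resolve_box <- function(stack, box) {
  if (is.null(box)) box <- roi_box(c(0, 0, 0), stack$dims)
  stopifnot(inherits(box, "roi_box"))
  lo <- box$min_corner; hi <- box$max_corner
  if (box$units == "micron") {
    sp <- stack$voxel_spacing
    if (is.null(sp))
      stop("ROI given in microns but the stack has no voxel_spacing",
           call. = FALSE)
    lo <- lo / sp; hi <- hi / sp
  }
  lo <- pmax(floor(lo), 0)
  hi <- pmin(ceiling(hi), stack$dims)
  if (any(hi <= lo))
    stop("ROI outside volume: box does not intersect the stack extent",
         call. = FALSE)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Crop a z-stack to an ROI box
#'
#' Extracts the sub-volume of every channel whose voxel coordinates lie
#' inside the box. All channels are cropped identically; labels, bit depth
#' and voxel spacing are preserved. Boxes partially outside the stack are
#' clamped to the extent (mirroring dragging a box handle beyond the volume);
#' a box that misses the stack entirely is an error.
#'
#' @param stack a [zstack].
#' @param box an [roi_box], or `NULL` for the full extent (identity crop).
#' @return the cropped [zstack].
#' @export
crop_stack <- function(stack, box = NULL) {
  stopifnot(inherits(stack, "zstack"))
  b <- .resolve_box(stack, box)
  zi <- (b$lo[1L] + 1L):b$hi[1L]
  yi <- (b$lo[2L] + 1L):b$hi[2L]
  xi <- (b$lo[3L] + 1L):b$hi[3L]
  chans <- lapply(stack$channels,
                  function(v) v[zi, yi, xi, drop = FALSE])
  zstack(chans, bit_depth = stack$bit_depth, name = stack$name,
         labels = stack$labels, voxel_spacing = stack$voxel_spacing)
}
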