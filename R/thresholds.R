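#' Per-channel intensity threshold range
#'
#' A closed pair `(lower, upper)` of raw intensity values bounding the
#' "meaningful signal" band of one channel. A voxel with intensity `v` carries
#' valid signal when `lower < v <= upper`: strict at the lower bound,
#' inclusive at the upper. The same pair drives two distinct semantics:
#' binarisation into a [weight_mask()] for the intersection coefficients, and
#' the clip-and-subtract preprocessing ([preprocess_for_pcc()]) applied
#' before Pearson correlation. Equal bounds (`lower == upper`) therefore
#' admit no voxel at all and yield an empty mask.
#'
#' @param lower,upper numeric intensity bounds, `lower <= upper`, in the raw
#'   units of the channel (never normalised).
#' @return an object of class `threshold_range`.
#' @export
threshold_range <- function(lower, upper) {
  lower <- as.numeric(lower)[1L]; upper <- as.numeric(upper)[1L]
  if (is.na(lower) || is.na(upper))
    stop("threshold bounds must be numeric", call. = FALSE)
  if (lower > upper)
    stop("lower threshold (", lower, ") exceeds upper (", upper, ")",
         call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "threshold_range")
}

#' @export
print.threshold_range <- function(x, ...) {
  cat(sprintf("<threshold_range> (%g, %g]\n", x$lower, x$upper))
  invisible(x)
}

#' Full original intensity range of a channel
#'
#' The default threshold on load: the channel's own minimum and maximum, so
#' that every voxel strictly above the minimum is treated as signal.
#'
#' @param voxels a channel's 3D intensity array (or any numeric vector).
#' @return a [threshold_range] spanning `range(voxels)`.
#' @export
full_range <- function(voxels) {
  threshold_range(min(voxels), max(voxels))
}

#' Binary weight mask of a channel
#'
#' Binarises a channel against its threshold range: weight 1 where
#' `lower < v <= upper`, 0 elsewhere. The mask is the co-occurrence view of
#' the channel — every intersection coefficient depends on the channels only
#' through these masks, never through raw intensities.
#'
#' @param voxels a channel's 3D intensity array.
#' @param t a [threshold_range].
#' @param source_channel optional 1-based index of the originating channel,
#'   carried for reporting.
#' @return an object of class `weight_mask` with fields `weights` (numeric
#'   array of exactly 0/1, same shape as `voxels`), `source_channel` and
#'   `threshold`.
#' @examples
#' m <- weight_mask(array(c(1, 3, 6), c(1, 1, 3)), threshold_range(2, 5))
#' as.vector(m$weights)  # 0 1 0
#' @export
weight_mask <- function(voxels, t, source_channel = NA_integer_) {
  stopifnot(inherits(t, "threshold_range"))
  w <- array(as.numeric(voxels > t$lower & voxels <= t$upper), dim(voxels))
  structure(list(weights = w,
                 source_channel = as.integer(source_channel),
                 threshold = t),
            class = "weight_mask")
}

# weights array from a weight_mask or a bare 0/1 array
.mask_weights <- function(m) {
  if (inherits(m, "weight_mask")) return(m$weights)
  w <- m
  if (is.logical(w)) { w <- array(as.numeric(w), dim(m)) }
  if (!all(w == 0 | w == 1))
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  w
}

#' Clip-and-subtract preprocessing for Pearson correlation
#'
#' The intensity transform applied to each channel before its correlation is
#' computed: intensities above the upper threshold are set to 0 (oversaturated
#' voxels removed), then the lower threshold is subtracted from the remaining
#' intensities and any negative result is set to 0. In symbols,
#' `v' = 0` if `v > upper`, else `max(v - lower, 0)`.
#'
#' Note the asymmetry with [weight_mask()]: a voxel exactly at `lower`
#' contributes weight 0 to the masks and value 0 here, but a voxel below
#' `lower` is zeroed here while still occupying a grid position — the
#' correlation is computed over every voxel of the (cropped) grid, zeros
#' included.
#'
#' @param voxels a channel's 3D intensity array.
#' @param t a [threshold_range].
#' @return a numeric array of the same shape, all values >= 0.
#' @examples
#' preprocess_for_pcc(array(c(1, 3, 6), c(1, 1, 3)), threshold_range(2, 5))
#' @export
preprocess_for_pcc <- function(voxels, t) {
  stopifnot(inherits(t, "threshold_range"))
  out <- pmax(voxels - t$lower, 0)
  out[voxels > t$upper] <- 0
  array(out, dim(voxels))
}

#' Automatic threshold range from the intensity distribution
#'
#' Assigns a threshold range that excludes the darkest and brightest 0.1% of
#' all voxel intensities: `lower` is the 0.1st percentile and `upper` the
#' 99.9th percentile of the channel's value distribution, both taken by the
#' nearest-rank rule on the sorted values (`s[ceiling(p * n)]`), which is
#' reproducible across platforms and free of interpolation dialects.
#'
#' @param voxels a channel's 3D intensity array (>= 1 voxel).
#' @return a [threshold_range].
#' @export
auto_threshold <- function(voxels) {
  v <- sort(as.vector(voxels))
  n <- length(v)
  if (n < 1L) stop("channel has no voxels", call. = FALSE)
  lo <- v[max(1L, ceiling(0.001 * n))]
  hi <- v[max(1L, ceiling(0.999 * n))]
  threshold_range(lo, hi)
}
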