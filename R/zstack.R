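#' Multi-channel z-stack container
#'
#' A `zstack` bundles the ordered grayscale channel volumes of a confocal
#' z-stack on a shared voxel grid. Each channel is a 3D numeric array indexed
#' `[z, y, x]` (0-based coordinates in the API, 1-based storage as usual in R).
#' Intensities are kept exactly as acquired: integer counts for 8/16-bit
#' stacks, raw floats for 32-bit stacks. Channels are addressed by 1-based
#' index; display labels default to `"Channel <index>"`.
#'
#' @param channels list of 3D numeric arrays, all with identical `dim()`.
#' @param bit_depth voxel bit depth: 8, 16 or 32, all unsigned with
#'   intensity range `[0, 2^bit_depth - 1]`.
#' @param name display name of the stack (used as diagram title and report
#'   header).
#' @param labels character vector of channel display labels; defaults to
#'   `"Channel 1"`, `"Channel 2"`, ...
#' @param voxel_spacing optional numeric `(dz, dy, dx)` physical spacing in
#'   microns. Carried as metadata only: all coefficients are voxel counts.
#' @return an object of class `zstack` with fields `name`, `channels`,
#'   `labels`, `dims` (`(nz, ny, nx)`), `bit_depth`, `voxel_spacing`.
#' @examples
#' ch <- array(0:23, dim = c(2, 3, 4))
#' s <- zstack(list(ch, ch * 2L), bit_depth = 8, name = "demo")
#' n_channels(s)
#' @export
zstack <- function(channels, bit_depth, name = "stack", labels = NULL,
                   voxel_spacing = NULL) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("`channels` must be a non-empty list of 3D arrays", call. = FALSE)
  if (length(channels) > 15L)
    stop("a z-stack may hold at most 15 channels (got ",
         length(channels), ")", call. = FALSE)
  if (!bit_depth %in% c(8, 16, 32))
    stop("`bit_depth` must be 8, 16 or 32", call. = FALSE)
  dims <- dim(channels[[1L]])
  if (is.null(dims) || length(dims) != 3L)
    stop("each channel must be a 3D array (z, y, x)", call. = FALSE)
  for (k in seq_along(channels)) {
    dk <- dim(channels[[k]])
    if (is.null(dk) || length(dk) != 3L || any(dk != dims))
      stop("channel ", k, " dimensions differ from channel 1", call. = FALSE)
    v <- channels[[k]]
    if (anyNA(v)) stop("channel ", k, " contains NA voxels", call. = FALSE)
    maxv <- 2^bit_depth - 1
    if (min(v) < 0 || max(v) > maxv)
      stop("channel ", k, " has intensities outside [0, ", maxv,
           "] for bit depth ", bit_depth, call. = FALSE)
    storage.mode(channels[[k]]) <- "double"
  }
  if (is.null(labels)) labels <- paste("Channel", seq_along(channels))
  if (length(labels) != length(channels))
    stop("`labels` length must equal the number of channels", call. = FALSE)
  if (!is.null(voxel_spacing)) {
    voxel_spacing <- as.numeric(voxel_spacing)
    if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
      stop("`voxel_spacing` must be positive (dz, dy, dx)", call. = FALSE)
  }
  structure(
    list(name = as.character(name)[1L], channels = channels,
         labels = as.character(labels), dims = as.integer(dims),
         bit_depth = as.integer(bit_depth), voxel_spacing = voxel_spacing),
    class = "zstack")
}

#' Number of channels in a z-stack
#' @param stack a [zstack].
#' @return integer channel count.
#' @export
n_channels <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  length(stack$channels)
}

#' Extract one channel volume
#' @param stack a [zstack].
#' @param index 1-based channel index.
#' @return the channel's 3D intensity array.
#' @export
channel <- function(stack, index) {
  stopifnot(inherits(stack, "zstack"))
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 1L ||
      index > length(stack$channels))
    stop("channel index ", index, " out of range 1..",
         length(stack$channels), call. = FALSE)
  stack$channels[[index]]
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("<zstack> %s: %d channel(s), dims (%s), %d-bit\n",
              x$name, length(x$channels),
              paste(x$dims, collapse = ", "), x$bit_depth))
  for (k in seq_along(x$channels))
    cat(sprintf("  [%d] %-12s range [%g, %g]\n", k, x$labels[k],
                min(x$channels[[k]]), max(x$channels[[k]])))
  invisible(x)
}

# top of the unsigned intensity scale for a bit depth
.int_max <- function(bit_depth) 2^bit_depth - 1

#' Read a multi-channel TIFF z-stack
#'
#' Loads a multi-page grayscale TIFF into a [zstack]. Pages are interpreted
#' in channel-fastest order (page `(z - 1) * channels + c` holds slice `z` of
#' channel `c`), the interleave written by [write_zstack()] and by ImageJ
#' hyperstacks saved in the default XYCZT order. The TIFF container itself
#' does not state the channel count for arbitrary acquisition software, so it
#' is supplied with `channels` (default 1: a plain single-channel stack).
#'
#' Intensities are returned exactly as stored, never rescaled: raw unsigned
#' integer counts at every supported depth (8-, 16- or 32-bit). 32-bit pages
#' are decoded from their normalized sample values back to the
#' `[0, 2^32 - 1]` count scale.
#'
#' @param path path to a readable TIFF file.
#' @param channels number of interleaved channels (1..15); the page count
#'   must be a multiple of it.
#' @param name stack display name; defaults to the file name without
#'   extension.
#' @param labels optional channel labels.
#' @param voxel_spacing optional `(dz, dy, dx)` spacing in microns.
#' @return a [zstack].
#' @export
read_zstack <- function(path, channels = 1L, name = NULL, labels = NULL,
                        voxel_spacing = NULL) {
  if (!file.exists(path))
    stop("TIFF file not found: ", path, call. = FALSE)
  channels <- as.integer(channels)
  if (is.na(channels) || channels < 1L || channels > 15L)
    stop("`channels` must be between 1 and 15 (got ", channels, ")",
         call. = FALSE)
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE, all = TRUE),
                   error = function(e)
                     stop("not a readable TIFF file: ", path, " (",
                          conditionMessage(e), ")", call. = FALSE))
  bits <- unique(info$bits.per.sample)
  if (length(bits) != 1L || !bits %in% c(8L, 16L, 32L))
    stop("unsupported bit depth: ", paste(bits, collapse = "/"),
         " (must be uniform 8, 16 or 32)", call. = FALSE)
  if (length(unique(info$width)) != 1L || length(unique(info$length)) != 1L)
    stop("TIFF pages have mismatched dimensions", call. = FALSE)
  if (any(info$samples.per.pixel != 1L))
    stop("TIFF pages must be grayscale (one sample per pixel)",
         call. = FALSE)
  n_pages <- nrow(info)
  if (n_pages %% channels != 0L)
    stop("page count ", n_pages, " is not a multiple of ", channels,
         " channels", call. = FALSE)
  # as.is returns raw integer samples for 8/16-bit; uint32 samples overflow
  # R's 32-bit integers, so 32-bit pages are read normalized and rescaled
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (bits != 32L))
  nz <- n_pages %/% channels
  ny <- info$length[1L]; nx <- info$width[1L]
  chans <- vector("list", channels)
  for (c in seq_len(channels)) {
    vol <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) {
      pg <- pages[[(z - 1L) * channels + c]]
      storage.mode(pg) <- "double"
      if (bits == 32L) pg <- round(pg * 2^32)  # uint32 samples / 2^32
      vol[z, , ] <- pg
    }
    chans[[c]] <- vol
  }
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(path))
  zstack(chans, bit_depth = bits, name = name, labels = labels,
         voxel_spacing = voxel_spacing)
}

#' Write a z-stack to a multi-page TIFF
#'
#' Writes one grayscale page per slice and channel, channel-fastest (slice 1
#' channel 1, slice 1 channel 2, ..., slice 2 channel 1, ...), so that
#' `read_zstack(path, channels = n_channels(stack))` reproduces the stack
#' voxel-exactly. Samples are stored as unsigned integers of the stack's bit
#' width; non-integer intensities would be quantized to that grid by the
#' TIFF encoder, so keep counts integral if exact round-trips matter.
#'
#' @param stack a [zstack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  nz <- stack$dims[1L]; n_ch <- length(stack$channels)
  scale <- .int_max(stack$bit_depth)
  pages <- vector("list", nz * n_ch)
  for (z in seq_len(nz))
    for (c in seq_len(n_ch)) {
      pg <- stack$channels[[c]][z, , ]
      if (stack$bit_depth == 32) {
        # the encoder truncates v * (2^32 - 1) to a uint32 sample; a
        # half-step offset makes every integer count land exactly
        pg <- ifelse(pg >= scale, 1, (pg + 0.5) / scale)
      } else {
        pg <- pg / scale
      }
      pages[[(z - 1L) * n_ch + c]] <- pg
    }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                    compression = "LZW", reduce = FALSE),
    error = function(e)
      stop("cannot write TIFF at ", path, " (", conditionMessage(e), ")",
           call. = FALSE))
  invisible(path)
}
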