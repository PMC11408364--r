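#' Specification of a synthetic validation stack
#'
#' Describes a multi-channel stack built from solid geometric shapes
#' (spheres and boxes) on a flat background, with optional Gaussian noise.
#' Because shape membership is decided at voxel centers, every channel's
#' true signal mask — and hence every overlap volume and intersection
#' coefficient — is known exactly in advance, which makes the whole pipeline
#' testable without any acquired data.
#'
#' Shapes are lists: `list(type = "box", min = c(z,y,x), max = c(z,y,x))`
#' (0-based half-open bounds) or
#' `list(type = "sphere", center = c(z,y,x), radius = r)` (0-based center;
#' a voxel belongs when its center is within `radius`, inclusive). Each
#' shape may carry its own `intensity`; otherwise `plateau` applies.
#'
#' @param dims `(nz, ny, nx)` voxel counts.
#' @param bit_depth 8 or 16.
#' @param shapes list with one element per channel; each element is a list
#'   of shape descriptors (may be empty for a blank channel).
#' @param plateau default in-shape intensity.
#' @param background_level background intensity (default 0).
#' @param noise_sd standard deviation of additive Gaussian noise (default
#'   0: analytically exact stack). Requires
#'   `plateau > background_level + 5 * noise_sd` so that thresholding at the
#'   midpoint still recovers the true masks reliably.
#' @param seed integer RNG seed making generation reproducible.
#' @param name stack name.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(dims, bit_depth = 8, shapes, plateau = 200,
                         background_level = 0, noise_sd = 0, seed = 1L,
                         name = "synthetic") {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  if (!bit_depth %in% c(8, 16))
    stop("synthetic stacks are 8- or 16-bit", call. = FALSE)
  if (!is.list(shapes) || length(shapes) < 1L || length(shapes) > 15L)
    stop("`shapes` must list 1..15 channels", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  maxv <- 2^bit_depth - 1
  for (ch in seq_along(shapes)) {
    for (sh in shapes[[ch]]) {
      inten <- if (is.null(sh$intensity)) plateau else sh$intensity
      if (inten <= background_level + 5 * noise_sd)
        stop("channel ", ch, ": shape intensity ", inten,
             " must exceed background + 5*noise_sd (",
             background_level + 5 * noise_sd, ")", call. = FALSE)
      if (inten > maxv)
        stop("channel ", ch, ": shape intensity exceeds the ", bit_depth,
             "-bit range", call. = FALSE)
      if (identical(sh$type, "box")) {
        if (any(sh$min < 0) || any(sh$max > dims) || any(sh$min >= sh$max))
          stop("channel ", ch, ": box must lie inside dims with min < max",
               call. = FALSE)
      } else if (identical(sh$type, "sphere")) {
        if (any(sh$center - sh$radius < 0) ||
            any(sh$center + sh$radius > dims - 1))
          stop("channel ", ch, ": sphere must lie inside dims",
               call. = FALSE)
      } else stop("channel ", ch, ": unknown shape type '", sh$type, "'",
                  call. = FALSE)
    }
  }
  structure(list(dims = dims, bit_depth = as.integer(bit_depth),
                 shapes = shapes, plateau = plateau,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed), name = name),
            class = "fixture_spec")
}

# logical membership array of one shape on a dims grid (voxel centers at
# integer 0-based coordinates)
.shape_mask <- function(sh, dims) {
  z <- seq_len(dims[1L]) - 1L; y <- seq_len(dims[2L]) - 1L
  x <- seq_len(dims[3L]) - 1L
  if (identical(sh$type, "box")) {
    inz <- z >= sh$min[1L] & z < sh$max[1L]
    iny <- y >= sh$min[2L] & y < sh$max[2L]
    inx <- x >= sh$min[3L] & x < sh$max[3L]
    outer(outer(inz, iny, `&`), inx, `&`)
  } else {
    dz2 <- (z - sh$center[1L])^2; dy2 <- (y - sh$center[2L])^2
    dx2 <- (x - sh$center[3L])^2
    outer(outer(dz2, dy2, `+`), dx2, `+`) <= sh$radius^2
  }
}

#' Generate a synthetic stack with known ground truth
#'
#' Realises a [fixture_spec()]: each channel is
#' `background + shape plateaus + Gaussian noise`, rounded to integers and
#' clipped to the bit-depth range. The returned ground-truth masks are the
#' exact shape-membership indicators; with `noise_sd = 0`, thresholding each
#' channel at the midpoint between background and plateau reproduces them
#' voxel-for-voxel, so every coefficient computed downstream has a
#' closed-form expected value from the geometry. Identical seeds give
#' identical stacks.
#'
#' @param spec a [fixture_spec()].
#' @return list with `stack` (a [zstack]), `masks` (list of logical
#'   ground-truth arrays per channel), `counts` (list: per-channel voxel
#'   counts `volume`, plus `pairwise` and `triple` overlap counts), and
#'   `midpoint_thresholds` (list of [threshold_range]s that recover the
#'   masks on a noiseless stack).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- length(spec$shapes)
  maxv <- 2^spec$bit_depth - 1
  masks <- vector("list", k)
  chans <- vector("list", k)
  set.seed(spec$seed)
  for (ch in seq_len(k)) {
    m <- array(FALSE, spec$dims)
    v <- array(spec$background_level, spec$dims)
    for (sh in spec$shapes[[ch]]) {
      sm <- .shape_mask(sh, spec$dims)
      inten <- if (is.null(sh$intensity)) spec$plateau else sh$intensity
      v[sm] <- inten
      m <- m | sm
    }
    if (spec$noise_sd > 0)
      v <- v + stats::rnorm(length(v), sd = spec$noise_sd)
    v <- pmin(pmax(round(v), 0), maxv)
    masks[[ch]] <- m
    chans[[ch]] <- array(v, spec$dims)
  }
  pairwise <- list()
  if (k >= 2L)
    for (p in utils::combn(k, 2L, simplify = FALSE))
      pairwise[[paste(p, collapse = "&")]] <-
        sum(masks[[p[1L]]] & masks[[p[2L]]])
  triple <- if (k >= 3L)
    sum(Reduce(`&`, masks[1:3])) else NA_integer_
  mid <- (spec$background_level + spec$plateau) / 2
  list(stack = zstack(chans, bit_depth = spec$bit_depth, name = spec$name),
       masks = masks,
       counts = list(volume = vapply(masks, sum, numeric(1L)),
                     pairwise = pairwise, triple = triple),
       midpoint_thresholds = replicate(k, threshold_range(mid, maxv),
                                       simplify = FALSE))
}

#' Write a synthetic stack plus its ground-truth sidecar
#'
#' Convenience wrapper used by the command-line `synth` subcommand: writes
#' the generated TIFF and a JSON sidecar holding the spec echo and the exact
#' per-channel volumes and overlap counts, so downstream runs can be checked
#' against the known geometry.
#'
#' @param spec a [fixture_spec()].
#' @param tiff_path output TIFF path.
#' @param json_path sidecar path; defaults to `tiff_path` with `.json`.
#' @return the [generate_stack()] result, invisibly.
#' @export
write_synthetic_stack <- function(spec, tiff_path,
                                  json_path = paste0(
                                    tools::file_path_sans_ext(tiff_path),
                                    ".json")) {
  gen <- generate_stack(spec)
  write_zstack(gen$stack, tiff_path)
  sidecar <- list(
    name = spec$name, dims = spec$dims, bit_depth = spec$bit_depth,
    n_channels = length(spec$shapes), seed = spec$seed,
    background_level = spec$background_level, noise_sd = spec$noise_sd,
    channel_volumes = as.numeric(gen$counts$volume),
    pairwise_overlaps = gen$counts$pairwise,
    triple_overlap = gen$counts$triple,
    midpoint_lower = gen$midpoint_thresholds[[1L]]$lower,
    midpoint_upper = gen$midpoint_thresholds[[1L]]$upper)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(gen)
}
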