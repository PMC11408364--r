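#' Venn region fractions of thresholded channel masks
#'
#' Partitions the union of 2 or 3 weight masks into its exclusive regions
#' (one per non-empty channel subset: 3 regions for two channels, 7 for
#' three) and expresses every region's voxel count as a fraction of the
#' union volume, so the displayed areas sum to 100%. The all-channels region
#' fraction equals the global intersection coefficient `I` by construction:
#' both divide the full-intersection count by the same union volume.
#'
#' @param masks list of 2 or 3 [weight_mask()] objects (or 0/1 arrays) on
#'   one grid.
#' @param channel_indices 1-based channel indices used in the region keys;
#'   defaults to `1:length(masks)`.
#' @return an object of class `venn_regions` with fields `region_fractions`
#'   (named numeric; names are sorted channel indices joined with `"&"`,
#'   e.g. `"1"`, `"2"`, `"1&2"`), `region_counts` (integer voxel counts),
#'   `union_volume`, and `channel_indices`. All fractions are `NA` when the
#'   union is empty.
#' @examples
#' a <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
#' b <- array(c(0, 0, 1, 1, 1, 0, 0, 0), c(2, 2, 2))
#' venn_regions(list(a, b))$region_fractions
#' @export
venn_regions <- function(masks, channel_indices = seq_along(masks)) {
  k <- length(masks)
  if (k < 2L || k > 3L)
    stop("Venn regions are defined for 2 or 3 masks", call. = FALSE)
  w <- lapply(masks, .mask_weights)
  d <- dim(w[[1L]])
  for (j in seq_len(k))
    if (!identical(dim(w[[j]]), d))
      stop("masks must share one grid", call. = FALSE)
  channel_indices <- as.integer(channel_indices)
  stopifnot(length(channel_indices) == k)

  subsets <- lapply(seq_len(2^k - 1L), function(code)
    which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L))
  counts <- vapply(subsets, function(s) {
    inside <- Reduce(`*`, w[s])
    if (length(s) < k) {
      outside <- Reduce(`*`, lapply(w[-s], function(m) 1 - m))
      sum(inside * outside)
    } else sum(inside)
  }, numeric(1L))
  names(counts) <- vapply(subsets, function(s)
    paste(channel_indices[s], collapse = "&"), character(1L))
  union_volume <- sum(counts)
  fractions <- if (union_volume > 0) counts / union_volume
               else rep(NA_real_, length(counts))
  names(fractions) <- names(counts)
  structure(list(region_fractions = fractions,
                 region_counts = counts,
                 union_volume = union_volume,
                 channel_indices = channel_indices),
            class = "venn_regions")
}

#' @export
print.venn_regions <- function(x, ...) {
  cat(sprintf("<venn_regions> union volume %g voxels\n", x$union_volume))
  for (nm in names(x$region_fractions))
    cat(sprintf("  {%s}: %s voxels (%s%%)\n", nm, x$region_counts[[nm]],
                .percent4(x$region_fractions[[nm]])))
  invisible(x)
}

# percentage string with four decimal places ("40.0000"), "n/a" if undefined
.percent4 <- function(frac) {
  if (is.na(frac)) return("n/a")
  formatC(round(100 * frac, 4), format = "f", digits = 4)
}

# default channel pseudo-colors: red, green, blue as in merged renderings
.channel_colors <- function(k)
  c("#E41A1C", "#4DAF4A", "#377EB8")[seq_len(k)]

#' Render an unweighted Venn diagram of channel overlap
#'
#' Draws a two- or three-circle Venn diagram (equal-sized circles, no area
#' weighting) with each region labelled by its volume percentage of the
#' union, printed with four decimal places. Circle colors follow the channel
#' pseudo-colors (red/green/blue); the title is the stack's display name and
#' the circle labels are the channel name labels. A CSV table of the region
#' counts and fractions is written alongside the image.
#'
#' @param regions a [venn_regions()] result.
#' @param channel_labels character labels for the circles; defaults to
#'   `"Channel <index>"`.
#' @param title diagram title (typically the stack name).
#' @param out_path output PNG path; the CSV twin replaces the extension with
#'   `.csv`.
#' @param colors optional circle colors (one per channel).
#' @return named list with the `png` and `csv` paths, invisibly.
#' @export
render_venn <- function(regions, channel_labels = NULL, title = "",
                        out_path, colors = NULL) {
  stopifnot(inherits(regions, "venn_regions"))
  k <- length(regions$channel_indices)
  if (is.null(channel_labels))
    channel_labels <- paste("Channel", regions$channel_indices)
  stopifnot(length(channel_labels) == k)
  if (is.null(colors)) colors <- .channel_colors(k)

  # fixed circle geometry; label anchor per region signature
  if (k == 2L) {
    centers <- cbind(x = c(-0.45, 0.45), y = c(0, 0)); r <- 0.85
    anchors <- list("1" = c(-0.75, 0), "2" = c(0.75, 0), "1&2" = c(0, 0))
  } else {
    centers <- cbind(x = c(-0.5, 0.5, 0), y = c(0.35, 0.35, -0.55)); r <- 0.85
    anchors <- list("1" = c(-0.85, 0.6), "2" = c(0.85, 0.6),
                    "3" = c(0, -1.0),
                    "1&2" = c(0, 0.65), "1&3" = c(-0.6, -0.35),
                    "2&3" = c(0.6, -0.35), "1&2&3" = c(0, 0.05))
  }
  sig_of <- function(nm) {  # map region key (channel indices) to anchor key
    idx <- match(as.integer(strsplit(nm, "&", fixed = TRUE)[[1L]]),
                 regions$channel_indices)
    paste(sort(idx), collapse = "&")
  }

  grDevices::png(out_path, width = 900, height = 760, res = 130)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(-1.8, 1.8), ylim = c(-1.9, 1.8), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = title)
  th <- seq(0, 2 * pi, length.out = 240)
  for (j in seq_len(k))
    graphics::polygon(centers[j, "x"] + r * cos(th),
                      centers[j, "y"] + r * sin(th),
                      col = grDevices::adjustcolor(colors[j], alpha.f = 0.35),
                      border = colors[j], lwd = 2)
  for (nm in names(regions$region_fractions)) {
    at <- anchors[[sig_of(nm)]]
    graphics::text(at[1L], at[2L],
                   paste0(.percent4(regions$region_fractions[[nm]]), "%"),
                   cex = 0.75)
  }
  lab_at <- if (k == 2L) cbind(centers[, "x"], centers[, "y"] + r + 0.18)
            else rbind(c(-1.0, 1.35), c(1.0, 1.35), c(0, -1.6))
  for (j in seq_len(k))
    graphics::text(lab_at[j, 1L], lab_at[j, 2L], channel_labels[j],
                   col = colors[j], font = 2, cex = 0.9)

  csv_path <- paste0(tools::file_path_sans_ext(out_path), ".csv")
  utils::write.csv(
    data.frame(region = names(regions$region_counts),
               voxels = as.numeric(regions$region_counts),
               fraction = as.numeric(regions$region_fractions),
               percent = vapply(regions$region_fractions, .percent4,
                                character(1L)),
               stringsAsFactors = FALSE),
    csv_path, row.names = FALSE)
  invisible(list(png = out_path, csv = csv_path))
}
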