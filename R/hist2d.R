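#' Background-excluded 2D intensity histogram (fluorogram)
#'
#' Builds the joint intensity histogram of a channel pair: each voxel's
#' `(a, b)` raw intensity pair defines a coordinate whose bin count is
#' incremented by one. Background voxels — those whose intensities are
#' outside the valid threshold band (`lower < v <= upper`) in *both*
#' channels — are not plotted; a voxel is counted iff at least one channel
#' is in range. The valid bands are the same ones that drive the weight
#' masks, so the histogram decomposes exactly into the three regions of the
#' matching two-channel Venn diagram: valid-in-both, only-a, only-b.
#'
#' Raw intensities are binned (no clip-and-subtract preprocessing); the
#' x-axis is the first channel, the y-axis the second. Bin edges are linear
#' over `[0, axis max]` per axis and recorded in the result.
#'
#' @param ch_a,ch_b 3D intensity arrays on one grid.
#' @param t_a,t_b the channels' [threshold_range]s.
#' @param bins number of bins per axis (>= 2). 256 suits 8-bit data; 512 is
#'   the usual choice for deeper stacks.
#' @param axis_max optional `(max_a, max_b)` axis extents; defaults to each
#'   channel's observed maximum (or its upper threshold if larger).
#' @return an object of class `histogram2d`: `counts` (`bins x bins` matrix,
#'   `[i, j]` = voxels in x-bin i, y-bin j), `breaks_a`/`breaks_b` (bin
#'   edges), `axis_ranges`, `thresholds`, `n_plotted`, and the per-region
#'   voxel counts `n_both`, `n_only_a`, `n_only_b`.
#' @export
build_histogram2d <- function(ch_a, ch_b, t_a, t_b, bins = 256L,
                              axis_max = NULL) {
  if (!identical(dim(ch_a), dim(ch_b)))
    stop("channels must share one grid", call. = FALSE)
  stopifnot(inherits(t_a, "threshold_range"), inherits(t_b, "threshold_range"))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L)
    stop("`bins` must be at least 2", call. = FALSE)

  a <- as.vector(ch_a); b <- as.vector(ch_b)
  valid_a <- a > t_a$lower & a <= t_a$upper
  valid_b <- b > t_b$lower & b <= t_b$upper
  keep <- valid_a | valid_b

  if (is.null(axis_max))
    axis_max <- c(max(max(a), t_a$upper), max(max(b), t_b$upper))
  axis_max <- pmax(as.numeric(axis_max), .Machine$double.eps)
  breaks_a <- seq(0, axis_max[1L], length.out = bins + 1L)
  breaks_b <- seq(0, axis_max[2L], length.out = bins + 1L)

  counts <- matrix(0L, nrow = bins, ncol = bins)
  if (any(keep)) {
    # left-closed bins [e_i, e_{i+1}), last bin closed on the right
    ia <- pmin(findInterval(a[keep], breaks_a, rightmost.closed = TRUE), bins)
    ib <- pmin(findInterval(b[keep], breaks_b, rightmost.closed = TRUE), bins)
    tab <- table(factor(ia, levels = seq_len(bins)),
                 factor(ib, levels = seq_len(bins)))
    counts <- matrix(as.integer(tab), nrow = bins)
  }
  structure(
    list(counts = counts, breaks_a = breaks_a, breaks_b = breaks_b,
         axis_ranges = list(a = c(0, axis_max[1L]), b = c(0, axis_max[2L])),
         thresholds = list(a = t_a, b = t_b),
         n_plotted = sum(keep),
         n_both = sum(valid_a & valid_b),
         n_only_a = sum(valid_a & !valid_b),
         n_only_b = sum(valid_b & !valid_a)),
    class = "histogram2d")
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(sprintf(paste0("<histogram2d> %d x %d bins, %d voxels plotted ",
                     "(both %d, only-x %d, only-y %d)\n"),
              nrow(x$counts), ncol(x$counts), x$n_plotted,
              x$n_both, x$n_only_a, x$n_only_b))
  invisible(x)
}

#' Render a fluorogram as a static image and interactive HTML
#'
#' Writes the 2D histogram twice: a PNG heat map with a count color bar
#' (optionally log-scaled), and a standalone interactive HTML page that
#' redraws the same counts on a canvas with hover read-out of bin
#' coordinates and counts. The HTML embeds the counts directly and needs no
#' network or external assets.
#'
#' @param h a [build_histogram2d()] result.
#' @param out_path_static PNG output path.
#' @param out_path_interactive HTML output path.
#' @param labels axis labels, `(x, y)`.
#' @param title plot title.
#' @param log_counts color-scale counts as `log10(1 + n)`; the color bar
#'   still reports raw counts.
#' @return named list of the two paths, invisibly.
#' @export
render_histogram2d <- function(h, out_path_static, out_path_interactive,
                               labels = c("Channel 1", "Channel 2"),
                               title = "2D histogram", log_counts = FALSE) {
  stopifnot(inherits(h, "histogram2d"))
  z <- h$counts
  zz <- if (log_counts) log10(1 + z) else z
  max_count <- max(z)
  pal <- grDevices::hcl.colors(64, "viridis")

  grDevices::png(out_path_static, width = 980, height = 820, res = 130)
  graphics::layout(matrix(c(1, 2), nrow = 1), widths = c(5, 1))
  graphics::par(mar = c(4, 4, 3, 1))
  mids_a <- (h$breaks_a[-1L] + h$breaks_a[-length(h$breaks_a)]) / 2
  mids_b <- (h$breaks_b[-1L] + h$breaks_b[-length(h$breaks_b)]) / 2
  graphics::image(mids_a, mids_b, zz, col = pal,
                  xlab = labels[1L], ylab = labels[2L], main = title,
                  useRaster = TRUE)
  graphics::abline(v = h$thresholds$a$lower, h = h$thresholds$b$lower,
                   col = "grey70", lty = 2)
  graphics::par(mar = c(4, 1, 3, 3))
  ramp <- seq(0, max(zz), length.out = 64)
  graphics::image(1, ramp, matrix(ramp, nrow = 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  ticks <- pretty(c(0, max_count), 5)
  tick_at <- if (log_counts) log10(1 + ticks) else ticks
  graphics::axis(4, at = tick_at, labels = ticks, las = 1)
  graphics::mtext("voxels", side = 3, line = 0.3, cex = 0.8)
  grDevices::dev.off()

  .write_hist2d_html(h, out_path_interactive, labels, title, log_counts)
  invisible(list(png = out_path_static, html = out_path_interactive))
}

# standalone HTML fluorogram: counts embedded as JSON, canvas renderer
.write_hist2d_html <- function(h, path, labels, title, log_counts) {
  payload <- jsonlite::toJSON(list(
    counts = h$counts, breaks_a = h$breaks_a, breaks_b = h$breaks_b,
    labels = labels, title = title, log = isTRUE(log_counts),
    n_plotted = h$n_plotted, max_count = max(h$counts)),
    auto_unbox = TRUE, digits = NA)
  html <- paste0('<!DOCTYPE html>\n<html><head><meta charset="utf-8">',
'<title>', title, '</title><style>',
'body{font-family:sans-serif;margin:20px}#tip{margin-top:8px;color:#333}',
'</style></head><body>\n<h3>', title, '</h3>\n',
'<canvas id="cv" width="640" height="640" style="border:1px solid #aaa">',
'</canvas>\n<div id="tip">hover for bin counts</div>\n',
'<script>\nconst D = ', payload, ';\n',
'const cv = document.getElementById("cv"), cx = cv.getContext("2d");\n',
'const nb = D.counts.length, cell = cv.width / nb;\n',
'const vmax = D.log ? Math.log10(1 + D.max_count) : D.max_count;\n',
'function shade(v){ const t = vmax > 0 ? (D.log ? Math.log10(1+v) : v)/vmax : 0;\n',
'  const r = Math.round(68 + t*(253-68)), g = Math.round(1 + t*(231-1)),\n',
'        b = Math.round(84 + t*(37-84)); return `rgb(${r},${g},${b})`; }\n',
'for (let i = 0; i < nb; i++) for (let j = 0; j < nb; j++) {\n',
'  cx.fillStyle = shade(D.counts[i][j]);\n',
'  cx.fillRect(i*cell, cv.height-(j+1)*cell, cell, cell); }\n',
'cv.addEventListener("mousemove", ev => {\n',
'  const r = cv.getBoundingClientRect();\n',
'  const i = Math.min(nb-1, Math.floor((ev.clientX-r.left)/cell));\n',
'  const j = Math.min(nb-1, Math.floor((cv.height-(ev.clientY-r.top))/cell));\n',
'  const a0 = D.breaks_a[i].toFixed(1), a1 = D.breaks_a[i+1].toFixed(1);\n',
'  const b0 = D.breaks_b[j].toFixed(1), b1 = D.breaks_b[j+1].toFixed(1);\n',
'  document.getElementById("tip").textContent =\n',
'    `${D.labels[0]} [${a0}, ${a1}) x ${D.labels[1]} [${b0}, ${b1}): ` +\n',
'    `${D.counts[i][j]} voxels`; });\n',
'</script>\n<p>', h$n_plotted,
' voxels plotted (background excluded).</p>\n</body></html>\n')
  writeLines(html, path)
  invisible(path)
}
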