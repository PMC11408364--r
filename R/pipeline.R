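#' Parse an ROI string
#'
#' Parses the textual box form `"z0:z1,y0:y1,x0:x1"` (0-based, half-open)
#' into an [roi_box()].
#'
#' @param spec the ROI string, or `NULL`/`""` for no box.
#' @return an [roi_box()], or `NULL`.
#' @export
parse_roi <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(NULL)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("ROI must be 'z0:z1,y0:y1,x0:x1' (got '", spec, "')",
         call. = FALSE)
  bounds <- lapply(parts, function(p) {
    ab <- suppressWarnings(as.numeric(strsplit(p, ":", fixed = TRUE)[[1L]]))
    if (length(ab) != 2L || anyNA(ab))
      stop("bad ROI axis range '", p, "'", call. = FALSE)
    ab
  })
  roi_box(vapply(bounds, `[`, numeric(1L), 1L),
          vapply(bounds, `[`, numeric(1L), 2L))
}

#' Run the full analysis pipeline and write every output
#'
#' The one-call equivalent of a complete run: analyses the selected channels
#' of a stack (thresholds + ROI), renders the Venn diagram and a fluorogram
#' for every selected channel pair (static PNG + interactive HTML each), and
#' writes the results workbook with its CSV twin. Output files are named
#' after the stack.
#'
#' @param stack a [zstack].
#' @param selected 2 or 3 channel indices.
#' @param thresholds threshold specification, as in [analyze_coloc()].
#' @param box optional [roi_box()].
#' @param out_dir output directory (created if needed).
#' @param annotation free-text annotation stored in the report.
#' @param bins histogram bins per axis; default 256 for 8-bit stacks, 512
#'   otherwise.
#' @param timestamp ISO-8601 timestamp recorded in the report; pass a fixed
#'   value for reproducible file names and bytes.
#' @return list with `result` (the [analyze_coloc()] output) and `paths`
#'   (all files written), invisibly.
#' @export
run_pipeline <- function(stack, selected, thresholds = "full", box = NULL,
                         out_dir = ".", annotation = "", bins = NULL,
                         timestamp = format(Sys.time(),
                                            "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC")) {
  stopifnot(inherits(stack, "zstack"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(bins)) bins <- if (stack$bit_depth == 8) 256L else 512L

  result <- analyze_coloc(stack, selected, thresholds, box)
  stem <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", stack$name))

  venn_png <- paste0(stem, "_venn.png")
  venn_files <- render_venn(result$venn,
                            channel_labels = result$channel_labels,
                            title = stack$name, out_path = venn_png)

  cropped <- crop_stack(stack, box)
  artifacts <- c(venn_files$png, venn_files$csv)
  sel <- result$selected_channels
  for (p in utils::combn(seq_along(sel), 2L, simplify = FALSE)) {
    ia <- sel[p[1L]]; ib <- sel[p[2L]]
    h <- build_histogram2d(channel(cropped, ia), channel(cropped, ib),
                           result$thresholds[[p[1L]]],
                           result$thresholds[[p[2L]]], bins = bins)
    png_path <- sprintf("%s_hist2d_ch%d_ch%d.png", stem, ia, ib)
    html_path <- sprintf("%s_hist2d_ch%d_ch%d.html", stem, ia, ib)
    render_histogram2d(h, png_path, html_path,
                       labels = stack$labels[c(ia, ib)],
                       title = sprintf("%s: %s vs %s", stack$name,
                                       stack$labels[ia], stack$labels[ib]))
    artifacts <- c(artifacts, png_path, html_path)
  }

  report <- run_report(result, annotation = annotation,
                       timestamp = timestamp, artifact_paths = artifacts)
  report_files <- write_report(report, out_dir)
  invisible(list(result = result,
                 paths = c(list(venn = venn_files$png),
                           report_files,
                           list(artifacts = artifacts))))
}
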