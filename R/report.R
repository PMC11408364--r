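#' Assemble a run report
#'
#' Bundles everything one colocalization run produced — thresholds, ROI,
#' coefficients, annotation and the generated diagram files — into a single
#' object that [write_report()] serialises. The timestamp is passed in (not
#' sampled internally) so that writing the same report twice is
#' byte-reproducible.
#'
#' @param result a `coloc_result` from [analyze_coloc()].
#' @param annotation free-text note for the run ("" for none).
#' @param timestamp ISO-8601 timestamp string; defaults to the current UTC
#'   time.
#' @param artifact_paths character vector of generated image/HTML files to
#'   reference; files that do not exist are rejected.
#' @return an object of class `run_report`.
#' @export
run_report <- function(result, annotation = "",
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC"),
                       artifact_paths = character()) {
  stopifnot(inherits(result, "coloc_result"))
  artifact_paths <- as.character(artifact_paths)
  missing <- artifact_paths[!file.exists(artifact_paths)]
  if (length(missing))
    stop("artifact file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(stack_name = result$stack_name,
                 annotation = as.character(annotation)[1L],
                 timestamp = as.character(timestamp)[1L],
                 result = result,
                 artifact_paths = artifact_paths),
            class = "run_report")
}

# results table shared by the CSV twin and the workbook Results sheet;
# all coefficient cells are 4-decimal strings or "n/a"
.report_results_table <- function(result) {
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value,
                                             stringsAsFactors = FALSE)
  for (nm in names(result$pcc))
    add(paste0("PCC ", sub("~", " vs ", nm, fixed = TRUE)),
        format_coeff(result$pcc[[nm]]))
  add("Global intersection I", format_coeff(result$global_intersection))
  for (nm in names(result$per_channel_intersection))
    add(paste0("Intersection i", nm),
        format_coeff(result$per_channel_intersection[[nm]]))
  for (nm in names(result$venn_fractions))
    add(paste0("Venn region {", nm, "}"),
        format_coeff(result$venn_fractions[[nm]]))
  do.call(rbind, rows)
}

.report_summary_table <- function(report) {
  res <- report$result
  roi_str <- sprintf("z %d:%d, y %d:%d, x %d:%d",
                     res$roi$lo[1L], res$roi$hi[1L],
                     res$roi$lo[2L], res$roi$hi[2L],
                     res$roi$lo[3L], res$roi$hi[3L])
  rows <- data.frame(
    field = c("Stack", "Timestamp", "Annotation", "Selected channels",
              "ROI (half-open voxel bounds)", "Voxels analysed"),
    value = c(report$stack_name, report$timestamp, report$annotation,
              paste(res$selected_channels, collapse = ", "),
              roi_str, as.character(res$n_voxels)),
    stringsAsFactors = FALSE)
  for (i in seq_along(res$selected_channels))
    rows <- rbind(rows, data.frame(
      field = sprintf("Threshold channel %d (%s)",
                      res$selected_channels[i], res$channel_labels[i]),
      value = sprintf("(%g, %g]", res$thresholds[[i]]$lower,
                      res$thresholds[[i]]$upper),
      stringsAsFactors = FALSE))
  if (length(report$artifact_paths))
    rows <- rbind(rows, data.frame(
      field = paste0("Artifact ", seq_along(report$artifact_paths)),
      value = report$artifact_paths, stringsAsFactors = FALSE))
  rows
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

# one SpreadsheetML <Worksheet> from a 2-column character data.frame
.sheet_xml <- function(name, df) {
  rows <- vapply(seq_len(nrow(df)), function(i) paste0(
    "   <Row>",
    paste0('<Cell><Data ss:Type="String">',
           .xml_escape(as.character(df[i, ])), "</Data></Cell>",
           collapse = ""),
    "</Row>"), character(1L))
  header <- paste0(
    "   <Row>",
    paste0('<Cell><Data ss:Type="String">', .xml_escape(names(df)),
           "</Data></Cell>", collapse = ""),
    "</Row>")
  paste0(' <Worksheet ss:Name="', .xml_escape(name), '">\n  <Table>\n',
         header, "\n", paste(rows, collapse = "\n"),
         "\n  </Table>\n </Worksheet>")
}

#' Write the results workbook and its CSV twin
#'
#' Serialises a [run_report()] into two files in `out_dir`:
#' \describe{
#'   \item{workbook}{`<stack>_<timestamp>_coloc.xml` — a two-sheet
#'     SpreadsheetML workbook (plain-text XML; opens in Excel and
#'     LibreOffice). The *Summary* sheet holds metadata, thresholds, the ROI
#'     bounds, the annotation and the paths of the generated diagrams; the
#'     *Results* sheet holds every coefficient (PCC per pair, I, per-channel
#'     i_k, Venn region fractions) displayed with four decimal places,
#'     undefined values as `"n/a"`.}
#'   \item{CSV twin}{`<stack>_<timestamp>_coloc.csv` — the Results sheet as
#'     plain CSV with the same rounded strings, byte-stable across repeated
#'     writes of the same report.}
#' }
#'
#' @param report a [run_report()].
#' @param out_dir output directory (created if missing).
#' @return named list with `workbook` and `csv` paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stamp <- gsub("[:]", "", gsub("[-T]", "", report$timestamp))
  stem <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                         report$stack_name),
                                    "_", stamp, "_coloc"))
  results <- .report_results_table(report$result)
  summary <- .report_summary_table(report)

  csv_path <- paste0(stem, ".csv")
  utils::write.csv(results, csv_path, row.names = FALSE, quote = TRUE)

  wb_path <- paste0(stem, ".xml")
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<?mso-application progid="Excel.Sheet"?>\n',
    '<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet"\n',
    ' xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">\n',
    .sheet_xml("Summary", summary), "\n",
    .sheet_xml("Results", results), "\n",
    "</Workbook>\n")
  writeLines(xml, wb_path, sep = "")
  invisible(list(workbook = wb_path, csv = csv_path))
}
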