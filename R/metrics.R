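#' Pearson's correlation between two thresholded channels
#'
#' Computes the correlation coefficient between the voxel intensities of two
#' channels after each is passed through the clip-and-subtract rule
#' ([preprocess_for_pcc()]) with its own threshold range. The sums run over
#' every voxel of the shared (already ROI-cropped) grid, including voxels
#' zeroed by preprocessing — out-of-range intensities are set to 0, not
#' excluded. The result lies in [-1, +1]: +1 for perfectly linearly
#' correlated channels, -1 for perfectly inversely correlated ones, 0 for
#' uncorrelated distributions.
#'
#' When either preprocessed channel is constant (zero variance — e.g. a
#' threshold band that silences every voxel) the coefficient is undefined and
#' `NA` is returned; it is reported downstream as `"n/a"`, never coerced
#' to 0.
#'
#' @param ch_a,ch_b 3D intensity arrays on one grid.
#' @param t_a,t_b the channels' [threshold_range]s; default full range, under
#'   which the preprocessing subtracts each channel's minimum and the
#'   coefficient equals the plain Pearson correlation of the raw intensities.
#' @return a single numeric value in [-1, 1], or `NA` if undefined.
#' @examples
#' a <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2))
#' pearson_coloc(a, 2 * a + 3)   # +1
#' pearson_coloc(a, max(a) - a)  # -1
#' @export
pearson_coloc <- function(ch_a, ch_b, t_a = full_range(ch_a),
                          t_b = full_range(ch_b)) {
  if (!identical(dim(ch_a), dim(ch_b)))
    stop("channels must share one grid", call. = FALSE)
  a <- as.vector(preprocess_for_pcc(ch_a, t_a))
  b <- as.vector(preprocess_for_pcc(ch_b, t_b))
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Intersection coefficients for two thresholded channels
#'
#' Co-occurrence metrics computed from the binary weight masks alone. With
#' voxel sums `Sa`, `Sb` of the two masks and `Sab` of their elementwise
#' product:
#' \describe{
#'   \item{`I`}{global intersection coefficient, `Sab / (Sa + Sb - Sab)`:
#'     the intersecting volume as a fraction of the union volume of both
#'     thresholded channels. Multiplied by 100 it reads as the
#'     intersection's volume percentage.}
#'   \item{`i1`, `i2`}{per-channel coefficients `Sab / Sa` and `Sab / Sb`:
#'     the fraction of each channel's own thresholded volume that lies in
#'     the intersection.}
#' }
#' An empty union leaves all three undefined (`NA`). A single empty channel
#' leaves only its own `i_k` undefined; `I` is then 0.
#'
#' @param mask_a,mask_b [weight_mask()] objects (or bare 0/1 arrays) on one
#'   grid.
#' @return named list `(I, i1, i2)`, each in [0, 1] or `NA`.
#' @export
intersection_2ch <- function(mask_a, mask_b) {
  wa <- .mask_weights(mask_a); wb <- .mask_weights(mask_b)
  if (!identical(dim(wa), dim(wb)))
    stop("masks must share one grid", call. = FALSE)
  sa <- sum(wa); sb <- sum(wb); sab <- sum(wa * wb)
  denom <- sa + sb - sab
  list(I  = if (denom == 0) NA_real_ else sab / denom,
       i1 = if (sa == 0) NA_real_ else sab / sa,
       i2 = if (sb == 0) NA_real_ else sab / sb)
}

#' Intersection coefficients for three thresholded channels
#'
#' Extends [intersection_2ch()] to three channels. The numerator is the
#' triple-product sum `Sabc` (voxels with valid signal in all three
#' channels); the denominator is the union volume by the inclusion-exclusion
#' principle, `Sa + Sb + Sc - Sab - Sac - Sbc + Sabc`. Per-channel
#' coefficients are `i_k = Sabc / Sk`.
#'
#' @param mask_a,mask_b,mask_c [weight_mask()] objects (or bare 0/1 arrays)
#'   on one grid.
#' @return named list `(I, i1, i2, i3)`, each in [0, 1] or `NA`.
#' @export
intersection_3ch <- function(mask_a, mask_b, mask_c) {
  wa <- .mask_weights(mask_a); wb <- .mask_weights(mask_b)
  wc <- .mask_weights(mask_c)
  if (!identical(dim(wa), dim(wb)) || !identical(dim(wa), dim(wc)))
    stop("masks must share one grid", call. = FALSE)
  sa <- sum(wa); sb <- sum(wb); sc <- sum(wc)
  sab <- sum(wa * wb); sac <- sum(wa * wc); sbc <- sum(wb * wc)
  sabc <- sum(wa * wb * wc)
  union_vol <- sa + sb + sc - sab - sac - sbc + sabc
  list(I  = if (union_vol == 0) NA_real_ else sabc / union_vol,
       i1 = if (sa == 0) NA_real_ else sabc / sa,
       i2 = if (sb == 0) NA_real_ else sabc / sb,
       i3 = if (sc == 0) NA_real_ else sabc / sc)
}

# resolve one threshold spec against channel voxels:
# a threshold_range, "auto", "full", or a numeric (lower, upper) pair
.resolve_threshold <- function(spec, voxels) {
  if (inherits(spec, "threshold_range")) return(spec)
  if (is.character(spec) && length(spec) == 1L) {
    if (spec == "auto") return(auto_threshold(voxels))
    if (spec == "full") return(full_range(voxels))
    parts <- strsplit(spec, ",", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) {
      vals <- suppressWarnings(as.numeric(parts))
      if (!anyNA(vals)) return(threshold_range(vals[1L], vals[2L]))
    }
    stop("unrecognised threshold spec: '", spec,
         "' (use 'auto', 'full' or 'lower,upper')", call. = FALSE)
  }
  if (is.numeric(spec) && length(spec) == 2L)
    return(threshold_range(spec[1L], spec[2L]))
  stop("thresholds must be threshold_range objects, (lower, upper) pairs, ",
       "'auto' or 'full'", call. = FALSE)
}

#' Full colocalization analysis of selected channels
#'
#' The end-to-end computation for one run: crops the stack to the ROI box,
#' resolves each selected channel's thresholds, builds the weight masks, and
#' computes Pearson's correlation for every pair among the selected channels
#' (ascending index order), the global and per-channel intersection
#' coefficients (two- or three-channel form as appropriate) and the Venn
#' region fractions of the union volume.
#'
#' @param stack a [zstack].
#' @param selected 2 or 3 distinct 1-based channel indices.
#' @param thresholds per-channel threshold specification: a single keyword
#'   (`"full"`, `"auto"`) applied to every selected channel, or a list with
#'   one entry per selected channel (in `selected` order; a named list with
#'   names equal to channel indices is also accepted). Entries may be
#'   [threshold_range]s, `(lower, upper)` numeric pairs, `"auto"` or
#'   `"full"`. Defaults to each channel's full original range.
#' @param box optional [roi_box]; `NULL` analyses the whole stack.
#' @return an object of class `coloc_result` with fields
#'   `selected_channels`, `channel_labels`, `thresholds` (resolved ranges),
#'   `roi` (resolved 0-based half-open bounds), `pcc` (named vector, names
#'   like `"1~2"`), `global_intersection`, `per_channel_intersection`
#'   (named by channel index), `venn` (a [venn_regions()] result),
#'   `venn_fractions`, `n_voxels`, and `stack_name`.
#' @examples
#' a <- array(rep(c(0, 10), each = 4), c(2, 2, 2))
#' b <- array(rep(c(0, 10), times = 4), c(2, 2, 2))
#' s <- zstack(list(a, b), bit_depth = 8)
#' r <- analyze_coloc(s, c(1, 2), thresholds = list(c(5, 10), c(5, 10)))
#' r$global_intersection
#' @export
analyze_coloc <- function(stack, selected, thresholds = "full", box = NULL) {
  stopifnot(inherits(stack, "zstack"))
  selected <- as.integer(selected)
  if (length(selected) < 2L || length(selected) > 3L)
    stop("colocalization runs on 2 or 3 selected channels (got ",
         length(selected), ")", call. = FALSE)
  if (anyDuplicated(selected))
    stop("selected channel indices must be distinct", call. = FALSE)
  if (any(selected < 1L) || any(selected > n_channels(stack)))
    stop("selected channel index out of range 1..", n_channels(stack),
         call. = FALSE)

  b <- .resolve_box(stack, box)
  cropped <- crop_stack(stack, box)

  if (is.character(thresholds) && length(thresholds) == 1L)
    thresholds <- rep(list(thresholds), length(selected))
  if (!is.list(thresholds) || length(thresholds) != length(selected))
    stop("`thresholds` must be one keyword or a list with one entry per ",
         "selected channel", call. = FALSE)
  if (!is.null(names(thresholds)) && all(names(thresholds) != ""))
    thresholds <- thresholds[as.character(selected)]

  k <- length(selected)
  t_res <- vector("list", k)
  masks <- vector("list", k)
  for (j in seq_len(k)) {
    vox <- channel(cropped, selected[j])
    t_res[[j]] <- .resolve_threshold(thresholds[[j]], vox)
    masks[[j]] <- weight_mask(vox, t_res[[j]], source_channel = selected[j])
  }
  names(t_res) <- as.character(selected)

  pairs <- utils::combn(seq_len(k), 2L)
  pcc <- numeric(ncol(pairs))
  pcc_names <- character(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    ja <- pairs[1L, p]; jb <- pairs[2L, p]
    pcc[p] <- pearson_coloc(channel(cropped, selected[ja]),
                            channel(cropped, selected[jb]),
                            t_res[[ja]], t_res[[jb]])
    pcc_names[p] <- paste0(selected[ja], "~", selected[jb])
  }
  names(pcc) <- pcc_names

  inter <- if (k == 2L) intersection_2ch(masks[[1L]], masks[[2L]])
           else intersection_3ch(masks[[1L]], masks[[2L]], masks[[3L]])
  per_ch <- unlist(inter[-1L])
  names(per_ch) <- as.character(selected)

  vr <- venn_regions(masks, channel_indices = selected)

  structure(
    list(selected_channels = selected,
         channel_labels = stack$labels[selected],
         thresholds = t_res,
         roi = b,
         pcc = pcc,
         global_intersection = inter$I,
         per_channel_intersection = per_ch,
         venn = vr,
         venn_fractions = vr$region_fractions,
         n_voxels = prod(cropped$dims),
         stack_name = stack$name),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s: channels %s, %d voxels analysed\n",
              x$stack_name, paste(x$selected_channels, collapse = ", "),
              x$n_voxels))
  for (i in seq_along(x$selected_channels))
    cat(sprintf("  threshold ch%d: (%g, %g]\n", x$selected_channels[i],
                x$thresholds[[i]]$lower, x$thresholds[[i]]$upper))
  for (nm in names(x$pcc))
    cat(sprintf("  PCC %-6s = %s\n", nm, format_coeff(x$pcc[[nm]])))
  cat(sprintf("  I (global) = %s\n", format_coeff(x$global_intersection)))
  for (nm in names(x$per_channel_intersection))
    cat(sprintf("  i%s        = %s\n", nm,
                format_coeff(x$per_channel_intersection[[nm]])))
  invisible(x)
}

#' Format a coefficient for display
#'
#' Four decimal places (round-half-even), with undefined values rendered as
#' the literal `"n/a"` — an undefined coefficient is a first-class outcome,
#' never a silent zero.
#'
#' @param x numeric vector (may contain `NA`).
#' @return character vector.
#' @export
format_coeff <- function(x) {
  out <- ifelse(is.na(x), "n/a",
                formatC(round(as.numeric(x), 4), format = "f", digits = 4))
  as.character(out)
}
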