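## Physical-area measurement, the CFR/SLR ratio statistics, and per-slide
## aggregation.

#' Physical area of a binary mask
#'
#' @param mask logical matrix.
#' @param scale_um_per_px pixel size in micrometres per pixel.
#' @return area in square micrometres: `sum(mask) * scale_um_per_px^2`.
#' @examples
#' measure_area(matrix(TRUE, 2, 5), 4.55)  # 10 px -> 207.025 um^2
#' @export
measure_area <- function(mask, scale_um_per_px) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!is.numeric(scale_um_per_px) || scale_um_per_px <= 0)
    stop("scale_um_per_px must be positive", call. = FALSE)
  sum(mask) * scale_um_per_px^2
}

#' Centrilobular fibrosis ratio and sinusoidal lumen ratio
#'
#' Both ratios are percentages of the tissue area, defined as the ROI area
#' minus the excluded centrilobular vein:
#' `CFR% = 100 * fibrosis / (total - vein)` and
#' `SLR% = 100 * lumen / (total - vein)`. Setting `include_vein = TRUE`
#' keeps the vein in the denominator, for sensitivity analysis only.
#'
#' @param fibrosis_area,lumen_area,total_area,vein_area areas in consistent
#'   units (conventionally um^2).
#' @param include_vein if `TRUE`, the denominator is `total_area` rather
#'   than the vein-free tissue area.
#' @return list with `cfr_percent` and `slr_percent`.
#' @examples
#' compute_ratios(100, 200, 1100, 100)  # CFR 10%, SLR 20%
#' @export
compute_ratios <- function(fibrosis_area, lumen_area, total_area, vein_area = 0,
                           include_vein = FALSE) {
  stopifnot(fibrosis_area >= 0, lumen_area >= 0, total_area >= 0,
            vein_area >= 0)
  if (vein_area > total_area)
    stop("vein area exceeds total ROI area", call. = FALSE)
  denom <- if (include_vein) total_area else total_area - vein_area
  if (denom <= 0)
    stop("tissue area is zero (vein fills the ROI): CFR/SLR are undefined",
         call. = FALSE)
  if (fibrosis_area > denom || lumen_area > denom)
    stop("component area exceeds tissue area", call. = FALSE)
  list(cfr_percent = 100 * fibrosis_area / denom,
       slr_percent = 100 * lumen_area / denom)
}

#' Measure one ROI
#'
#' Converts the fibrosis and lumen masks of a ROI to physical areas and
#' computes CFR and SLR; the result is a one-row data frame, the unit from
#' which result tables and slide summaries are built.
#'
#' @param roi a [roi_image()].
#' @param fibrosis_mask,lumen_mask logical matrices matching the ROI.
#' @param include_vein passed to [compute_ratios()].
#' @return one-row data frame with columns `roi_id`, `total_area_um2`,
#'   `vein_area_um2`, `tissue_area_um2`, `fibrosis_area_um2`,
#'   `lumen_area_um2`, `cfr_percent`, `slr_percent`.
#' @export
measure_roi <- function(roi, fibrosis_mask, lumen_mask, include_vein = FALSE) {
  stopifnot(inherits(roi, "roi_image"))
  check_mask_dims(fibrosis_mask, roi$pixels, "fibrosis mask")
  check_mask_dims(lumen_mask, roi$pixels, "lumen mask")
  s <- roi$scale_um_per_px
  total <- prod(dim(roi$pixels)[1:2]) * s^2
  vein <- if (is.null(roi$vein_mask)) 0 else measure_area(roi$vein_mask, s)
  fib <- measure_area(fibrosis_mask, s)
  lum <- measure_area(lumen_mask, s)
  r <- compute_ratios(fib, lum, total, vein, include_vein = include_vein)
  data.frame(roi_id = roi$roi_id,
             total_area_um2 = total,
             vein_area_um2 = vein,
             tissue_area_um2 = total - vein,
             fibrosis_area_um2 = fib,
             lumen_area_um2 = lum,
             cfr_percent = r$cfr_percent,
             slr_percent = r$slr_percent,
             stringsAsFactors = FALSE)
}

#' Aggregate ROI measurements into a slide summary
#'
#' The per-slide statistic is the arithmetic mean of the ROI-level CFR and
#' SLR values (conventionally five ROIs per slide). All rows must belong to
#' one slide.
#'
#' @param measurements data frame of ROI measurements (as from
#'   [measure_roi()]), with a `slide_id` column or a single `slide_id`
#'   supplied explicitly.
#' @param slide_id slide identifier; defaults to the unique value of
#'   `measurements$slide_id`.
#' @return one-row data frame: `slide_id`, `n_rois`, `mean_cfr_percent`,
#'   `mean_slr_percent`.
#' @export
aggregate_slide <- function(measurements, slide_id = NULL) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0L)
    stop("measurements must be a non-empty data frame", call. = FALSE)
  if (is.null(slide_id)) {
    if (is.null(measurements$slide_id))
      stop("supply slide_id or a slide_id column", call. = FALSE)
    ids <- unique(measurements$slide_id)
    if (length(ids) != 1L)
      stop("measurements mix several slides: ",
           paste(ids, collapse = ", "), call. = FALSE)
    slide_id <- ids
  } else if (!is.null(measurements$slide_id) &&
             !all(measurements$slide_id == slide_id)) {
    stop("measurements contain rows from other slides", call. = FALSE)
  }
  data.frame(slide_id = as.character(slide_id),
             n_rois = nrow(measurements),
             mean_cfr_percent = mean(measurements$cfr_percent),
             mean_slr_percent = mean(measurements$slr_percent),
             stringsAsFactors = FALSE)
}

#' Summarise all slides in a result table
#'
#' Groups ROI measurements by `slide_id` and applies [aggregate_slide()] to
#' each group; slides are ordered lexicographically.
#'
#' @param measurements data frame with a `slide_id` column.
#' @return data frame of slide summaries, one row per slide.
#' @export
aggregate_slides <- function(measurements) {
  if (!is.data.frame(measurements) || is.null(measurements$slide_id))
    stop("measurements must have a slide_id column", call. = FALSE)
  ids <- sort(unique(measurements$slide_id))
  do.call(rbind, lapply(ids, function(id)
    aggregate_slide(measurements[measurements$slide_id == id, , drop = FALSE], id)))
}
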