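## Per-ROI segmentation: vein exclusion, fibrosis and sinusoidal-lumen masks.

#' Construct a region-of-interest image
#'
#' The unit of analysis: one RGB tile centred on a centrilobular vein, with a
#' physical pixel calibration and (optionally) a vein mask and a flag saying
#' the sinusoidal lumens have already been filled with black pixels by
#' upstream annotation.
#'
#' @param pixels RGB array, height x width x 3, integer values 0-255.
#' @param scale_um_per_px physical pixel size in micrometres per pixel
#'   (default 4.55).
#' @param vein_mask optional logical matrix marking the centrilobular vein;
#'   dimensions must match `pixels`.
#' @param lumen_annotated logical; `TRUE` when lumens are pre-filled black.
#' @param roi_id identifier used in result tables.
#' @return an object of class `roi_image`.
#' @export
roi_image <- function(pixels, scale_um_per_px = 4.55, vein_mask = NULL,
                      lumen_annotated = FALSE, roi_id = "roi") {
  validate_rgb(pixels)
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      is.na(scale_um_per_px) || scale_um_per_px <= 0)
    stop("scale_um_per_px must be a single positive number", call. = FALSE)
  if (!is.null(vein_mask)) check_mask_dims(vein_mask, pixels, "vein mask")
  structure(list(pixels = pixels,
                 scale_um_per_px = scale_um_per_px,
                 vein_mask = vein_mask,
                 lumen_annotated = isTRUE(lumen_annotated),
                 roi_id = as.character(roi_id)),
            class = "roi_image")
}

check_mask_dims <- function(mask, pixels, what) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(what, " must be a logical matrix", call. = FALSE)
  if (nrow(mask) != dim(pixels)[1] || ncol(mask) != dim(pixels)[2])
    stop(sprintf("%s dimensions (%d x %d) do not match image (%d x %d)",
                 what, nrow(mask), ncol(mask), dim(pixels)[1], dim(pixels)[2]),
         call. = FALSE)
  invisible(mask)
}

#' @export
print.roi_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ROI '%s': %d x %d px at %.3g um/px (%.3g x %.3g um)\n",
              x$roi_id, d[2], d[1], x$scale_um_per_px,
              d[2] * x$scale_um_per_px, d[1] * x$scale_um_per_px))
  cat(sprintf("  vein mask: %s; lumens annotated: %s\n",
              if (is.null(x$vein_mask)) "none"
              else sprintf("%d px", sum(x$vein_mask)),
              if (x$lumen_annotated) "yes" else "no"))
  invisible(x)
}

#' Exclude the centrilobular vein from a ROI
#'
#' Fills the pixels under `vein` with pure white (255, 255, 255) and records
#' the mask on the ROI. White pixels fall outside both the fibrosis band
#' (brightness 255 > 248) and the lumen band (brightness 255 > 50), so the
#' vein can never contribute to either component. The vein outline itself is
#' drawn manually upstream; this package consumes it as a mask.
#'
#' @param roi a [roi_image()].
#' @param vein logical matrix, same dimensions as the ROI.
#' @return the modified `roi_image`.
#' @export
exclude_vein <- function(roi, vein) {
  stopifnot(inherits(roi, "roi_image"))
  check_mask_dims(vein, roi$pixels, "vein mask")
  px <- roi$pixels
  for (k in 1:3) {
    ch <- px[, , k]
    ch[vein] <- 255L
    px[, , k] <- ch
  }
  roi$pixels <- px
  roi$vein_mask <- vein
  roi
}

#' Fill annotated sinusoidal lumens with black pixels
#'
#' The mask-input counterpart of the manual lumen extraction step: pixels
#' under `lumen` are set to (0, 0, 0) and the ROI is flagged as annotated,
#' which is the precondition of [segment_lumen_annotated()].
#'
#' @param roi a [roi_image()].
#' @param lumen logical matrix of manually annotated lumen pixels.
#' @return the modified `roi_image` with `lumen_annotated = TRUE`.
#' @export
annotate_lumens <- function(roi, lumen) {
  stopifnot(inherits(roi, "roi_image"))
  check_mask_dims(lumen, roi$pixels, "lumen mask")
  px <- roi$pixels
  for (k in 1:3) {
    ch <- px[, , k]
    ch[lumen] <- 0L
    px[, , k] <- ch
  }
  roi$pixels <- px
  roi$lumen_annotated <- TRUE
  roi
}

#' Segment centrilobular fibrosis
#'
#' Smooths the RGB image with a 3x3 mean filter (configurable), converts to
#' HSB and keeps pixels inside the collagen band (hue 140-190, saturation
#' 0-255, brightness 0-248). Vein pixels, when a vein mask is attached, are
#' always removed from the result.
#'
#' @param roi a [roi_image()] with the vein already excluded (or no vein by
#'   declaration).
#' @param band threshold band, default [fibrosis_band()].
#' @param smoothing apply the 3x3 mean filter before thresholding
#'   (default `TRUE`).
#' @return logical fibrosis mask.
#' @export
segment_fibrosis <- function(roi, band = fibrosis_band(), smoothing = TRUE) {
  stopifnot(inherits(roi, "roi_image"))
  px <- if (isTRUE(smoothing)) smooth_rgb(roi$pixels) else roi$pixels
  mask <- threshold_hsb(rgb_to_hsb(px), band)
  if (!is.null(roi$vein_mask)) mask[roi$vein_mask] <- FALSE
  mask
}

#' Segment annotated sinusoidal lumens
#'
#' Thresholds the (unsmoothed) image with the lumen band (hue 0-255,
#' saturation 0-255, brightness 0-50), which selects exactly the black-filled
#' annotation pixels; requires the ROI to be annotated via
#' [annotate_lumens()] or loaded with pre-filled lumens.
#'
#' @param roi an annotated [roi_image()].
#' @param band threshold band, default [lumen_band()].
#' @return logical lumen mask.
#' @export
segment_lumen_annotated <- function(roi, band = lumen_band()) {
  stopifnot(inherits(roi, "roi_image"))
  if (!isTRUE(roi$lumen_annotated))
    stop("ROI is not lumen-annotated: fill lumens with black pixels first ",
         "(see annotate_lumens()) or use detect_lumen_candidates()",
         call. = FALSE)
  mask <- threshold_hsb(rgb_to_hsb(roi$pixels), band)
  if (!is.null(roi$vein_mask)) mask[roi$vein_mask] <- FALSE
  mask
}

#' Automated sinusoidal-lumen candidate detection
#'
#' Experimental, candidate-quality replacement for manual lumen annotation:
#' selects near-white unstained pixels (brightness >= `bri_min` and
#' saturation <= `sat_max`), removes vein pixels, and discards 8-connected
#' components smaller than `min_area_px`. Candidates cannot distinguish
#' sinusoidal lumens from other unstained structures such as fat droplets
#' (microvesicular steatosis), so the returned area is an upper bound on the
#' true lumen area whenever such confounders are present; the annotated
#' route remains the reference method.
#'
#' @param roi a [roi_image()] with the vein excluded.
#' @param bri_min minimum brightness, 0-255 (default 230).
#' @param sat_max maximum saturation, 0-255 (default 40).
#' @param min_area_px smallest component retained, in pixels (default 4).
#' @return logical candidate-lumen mask.
#' @export
detect_lumen_candidates <- function(roi, bri_min = 230L, sat_max = 40L,
                                    min_area_px = 4L) {
  stopifnot(inherits(roi, "roi_image"))
  stopifnot(bri_min >= 0, bri_min <= 255, sat_max >= 0, sat_max <= 255,
            min_area_px >= 0)
  hsb <- rgb_to_hsb(roi$pixels)
  cand <- hsb[, , 3] >= bri_min & hsb[, , 2] <= sat_max
  if (!is.null(roi$vein_mask)) cand[roi$vein_mask] <- FALSE
  if (min_area_px > 1L && any(cand)) {
    lab <- label_components(cand)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area_px)
    cand <- matrix(lab %in% keep, nrow(cand), ncol(cand))
  }
  cand
}
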