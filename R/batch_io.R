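## Raster and mask I/O, batch configuration, and the batch engine.

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format '", ext, "' (use PNG or TIFF): ", path,
         call. = FALSE)
  }
}

#' Read / write a binary component mask
#'
#' Masks are stored as single-channel 8-bit PNG or TIFF rasters with 0 for
#' background and 255 for the component; the round trip is bit-exact.
#'
#' @param path file path (`.png`, `.tif` or `.tiff`).
#' @param mask logical matrix.
#' @return `read_mask` returns a logical matrix; `write_mask` returns the
#'   path invisibly.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  m <- read_raster(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (ext == "png") png::writePNG(m, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(m, path, bits.per.sample = 8L)
  else stop("unsupported mask format '", ext, "'", call. = FALSE)
  invisible(path)
}

#' Load a ROI image from disk
#'
#' Reads an 8-bit RGB PNG or TIFF, attaches the physical scale and an
#' optional vein mask (which is immediately applied as a white fill).
#' Sixteen-bit and non-RGB rasters are rejected.
#'
#' @param path image file.
#' @param scale_um_per_px micrometres per pixel (default 4.55).
#' @param vein_mask_path optional mask file for the centrilobular vein.
#' @param roi_id identifier; defaults to the file-name stem.
#' @return a [roi_image()].
#' @export
load_roi <- function(path, scale_um_per_px = 4.55, vein_mask_path = NULL,
                     roi_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  a <- read_raster(path)
  if (length(dim(a)) != 3L || dim(a)[3] < 3L)
    stop("expected 3-channel RGB image: ", path, call. = FALSE)
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  v <- a * 255
  if (max(abs(v - round(v))) > 1e-6)
    stop("expected 8-bit RGB raster (16-bit input rejected): ", path,
         call. = FALSE)
  px <- array(as.integer(round(v)), dim = dim(a))
  roi <- roi_image(px, scale_um_per_px, roi_id = roi_id)
  if (!is.null(vein_mask_path)) {
    vm <- read_mask(vein_mask_path)
    roi <- exclude_vein(roi, vm)
  }
  roi
}

#' Batch configuration
#'
#' Mirrors the settings of the recorded-macro workflow: input folder,
#' optional mask folder (`<stem>_vein.png` / `<stem>_lumen.png` files),
#' pixel scale, the two threshold bands, whether fibrosis smoothing is on,
#' and how lumens are obtained (`"annotated"`: black-filled from the lumen
#' mask — the reference route; `"automated"`: candidate detection).
#'
#' @param input_dir directory of ROI images (PNG/TIFF).
#' @param mask_dir directory of vein/lumen masks; defaults to `input_dir`.
#' @param output_csv,summary_csv optional paths for the per-ROI and
#'   per-slide CSV outputs.
#' @param scale_um_per_px micrometres per pixel.
#' @param fibrosis_band,lumen_band [hsb_band()] objects.
#' @param smoothing apply 3x3 mean smoothing before fibrosis thresholding.
#' @param lumen_mode `"annotated"` or `"automated"`.
#' @param bri_min,sat_max,min_area_px automated-detection parameters.
#' @param manifest optional CSV with columns `file` and `slide_id`
#'   overriding the `slideID_roiN` file-name convention.
#' @param random_seed seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `batch_config`.
#' @export
batch_config <- function(input_dir, mask_dir = input_dir, output_csv = NULL,
                         summary_csv = NULL, scale_um_per_px = 4.55,
                         fibrosis_band = mtmorph::fibrosis_band(),
                         lumen_band = mtmorph::lumen_band(),
                         smoothing = TRUE,
                         lumen_mode = c("annotated", "automated"),
                         bri_min = 230L, sat_max = 40L, min_area_px = 4L,
                         manifest = NULL, random_seed = 1L,
                         log_level = "info") {
  lumen_mode <- match.arg(lumen_mode)
  stopifnot(inherits(fibrosis_band, "hsb_band"), inherits(lumen_band, "hsb_band"),
            scale_um_per_px > 0)
  structure(list(input_dir = input_dir, mask_dir = mask_dir,
                 output_csv = output_csv, summary_csv = summary_csv,
                 scale_um_per_px = scale_um_per_px,
                 fibrosis_band = fibrosis_band, lumen_band = lumen_band,
                 smoothing = isTRUE(smoothing), lumen_mode = lumen_mode,
                 bri_min = as.integer(bri_min), sat_max = as.integer(sat_max),
                 min_area_px = as.integer(min_area_px),
                 manifest = manifest, random_seed = as.integer(random_seed),
                 log_level = log_level),
            class = "batch_config")
}

#' Read / write a batch configuration as flat `key = value` text
#'
#' Band fields are serialised as comma-separated sextuples; this keeps the
#' "macro settings" reviewable as plain text.
#'
#' @param config a [batch_config()].
#' @param path text file path.
#' @return `read_batch_config` returns a `batch_config`; `write_batch_config`
#'   the path, invisibly.
#' @export
write_batch_config <- function(config, path) {
  stopifnot(inherits(config, "batch_config"))
  fmt_band <- function(b) paste(unlist(b), collapse = ",")
  kv <- c(input_dir = config$input_dir, mask_dir = config$mask_dir,
          output_csv = config$output_csv %||% "",
          summary_csv = config$summary_csv %||% "",
          scale_um_per_px = config$scale_um_per_px,
          fibrosis_band = fmt_band(config$fibrosis_band),
          lumen_band = fmt_band(config$lumen_band),
          smoothing = tolower(config$smoothing),
          lumen_mode = config$lumen_mode,
          bri_min = config$bri_min, sat_max = config$sat_max,
          min_area_px = config$min_area_px,
          manifest = config$manifest %||% "",
          random_seed = config$random_seed, log_level = config$log_level)
  writeLines(paste(names(kv), kv, sep = " = "), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_batch_config
#' @export
read_batch_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                          vapply(kv, `[[`, "", 1L))
  band <- function(s) do.call(hsb_band, as.list(as.integer(strsplit(s, ",")[[1]])))
  blank_null <- function(s) if (!nzchar(s)) NULL else s
  batch_config(input_dir = vals[["input_dir"]], mask_dir = vals[["mask_dir"]],
               output_csv = blank_null(vals[["output_csv"]]),
               summary_csv = blank_null(vals[["summary_csv"]]),
               scale_um_per_px = as.numeric(vals[["scale_um_per_px"]]),
               fibrosis_band = band(vals[["fibrosis_band"]]),
               lumen_band = band(vals[["lumen_band"]]),
               smoothing = vals[["smoothing"]] == "true",
               lumen_mode = vals[["lumen_mode"]],
               bri_min = as.integer(vals[["bri_min"]]),
               sat_max = as.integer(vals[["sat_max"]]),
               min_area_px = as.integer(vals[["min_area_px"]]),
               manifest = blank_null(vals[["manifest"]]),
               random_seed = as.integer(vals[["random_seed"]]),
               log_level = vals[["log_level"]])
}

#' Analyse a single ROI end to end
#'
#' The per-image pipeline the batch engine applies: segment fibrosis
#' (smoothing per config), obtain the lumen mask (annotated fill or
#' automated candidates), and measure areas and ratios.
#'
#' @param roi a [roi_image()] with the vein already excluded if applicable.
#' @param lumen_mask logical matrix of annotated lumens (required in
#'   annotated mode unless the ROI is already flagged annotated).
#' @param config a [batch_config()]; bands, smoothing and lumen mode are
#'   taken from it.
#' @return one-row measurement data frame (see [measure_roi()]).
#' @export
analyze_roi <- function(roi, lumen_mask = NULL,
                        config = batch_config(".")) {
  stopifnot(inherits(roi, "roi_image"), inherits(config, "batch_config"))
  fib <- segment_fibrosis(roi, config$fibrosis_band, config$smoothing)
  if (config$lumen_mode == "annotated") {
    if (!is.null(lumen_mask)) roi <- annotate_lumens(roi, lumen_mask)
    lum <- segment_lumen_annotated(roi, config$lumen_band)
  } else {
    lum <- detect_lumen_candidates(roi, config$bri_min, config$sat_max,
                                   config$min_area_px)
  }
  measure_roi(roi, fib, lum)
}

slide_of <- function(stem) sub("_[^_]*$", "", stem)

#' Run the batch engine over a folder of ROI images
#'
#' Processes every PNG/TIFF in `input_dir` in lexicographic file-name order,
#' writes one result row per image, groups rows into slide summaries by the
#' `slideID_roiN` file-name convention (or a manifest CSV), and records a
#' per-image status log. A failure on one image flags its row and is counted,
#' never silently skipped; the run is fully deterministic, so repeated runs
#' on the same inputs produce identical tables.
#'
#' @param config a [batch_config()].
#' @return object of class `batch_result`: list with `results` (per-ROI data
#'   frame with `slide_id` and `status` columns), `summaries` (per-slide data
#'   frame), `n_failed`, and `log` (character vector).
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  if (!dir.exists(config$input_dir))
    stop("input directory does not exist: ", config$input_dir, call. = FALSE)
  files <- list.files(config$input_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE)
  ## mask files live alongside images; never process them as ROIs
  files <- files[!grepl("_(vein|lumen|fibrosis)\\.(png|tif|tiff)$", files,
                        ignore.case = TRUE)]
  files <- sort(files)
  if (length(files) == 0L)
    stop("no ROI images found in ", config$input_dir, call. = FALSE)

  slide_map <- NULL
  if (!is.null(config$manifest)) {
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    if (is.null(man$file) ||
        is.null(man$slide_id %||% man$animal_id))
      stop("manifest must have columns 'file' and 'slide_id' (or 'animal_id')",
           call. = FALSE)
    slide_map <- stats::setNames(man$slide_id %||% man$animal_id, man$file)
  }

  log <- c(sprintf("mtmorph %s batch run", as.character(utils::packageVersion("mtmorph"))),
           sprintf("input_dir=%s mask_dir=%s", config$input_dir, config$mask_dir),
           sprintf("scale_um_per_px=%g smoothing=%s lumen_mode=%s",
                   config$scale_um_per_px, config$smoothing, config$lumen_mode),
           sprintf("fibrosis_band=%s", paste(unlist(config$fibrosis_band), collapse = ",")),
           sprintf("lumen_band=%s", paste(unlist(config$lumen_band), collapse = ",")),
           sprintf("n_images=%d", length(files)))

  empty_row <- function(id) data.frame(
    roi_id = id, total_area_um2 = NA_real_, vein_area_um2 = NA_real_,
    tissue_area_um2 = NA_real_, fibrosis_area_um2 = NA_real_,
    lumen_area_um2 = NA_real_, cfr_percent = NA_real_, slr_percent = NA_real_,
    stringsAsFactors = FALSE)

  rows <- vector("list", length(files))
  for (k in seq_along(files)) {
    f <- files[k]
    stem <- tools::file_path_sans_ext(f)
    res <- tryCatch({
      vein_path <- file.path(config$mask_dir, paste0(stem, "_vein.png"))
      roi <- load_roi(file.path(config$input_dir, f), config$scale_um_per_px,
                      vein_mask_path = if (file.exists(vein_path)) vein_path,
                      roi_id = stem)
      lmask <- NULL
      if (config$lumen_mode == "annotated") {
        lumen_path <- file.path(config$mask_dir, paste0(stem, "_lumen.png"))
        if (!file.exists(lumen_path))
          stop("annotated lumen mask not found: ", lumen_path, call. = FALSE)
        lmask <- read_mask(lumen_path)
      }
      r <- analyze_roi(roi, lmask, config)
      r$status <- "ok"
      list(row = r, msg = sprintf("%s: ok (CFR %.2f%%, SLR %.2f%%)",
                                  f, r$cfr_percent, r$slr_percent))
    }, error = function(e) {
      r <- empty_row(stem)
      r$status <- paste("error:", conditionMessage(e))
      list(row = r, msg = sprintf("%s: ERROR %s", f, conditionMessage(e)))
    })
    log <- c(log, res$msg)
    row <- res$row
    row$slide_id <- if (!is.null(slide_map) && f %in% names(slide_map))
      slide_map[[f]] else slide_of(stem)
    rows[[k]] <- row
  }
  results <- do.call(rbind, rows)
  ok <- results$status == "ok"
  n_failed <- sum(!ok)
  summaries <- if (any(ok)) aggregate_slides(results[ok, , drop = FALSE])
               else data.frame(slide_id = character(), n_rois = integer(),
                               mean_cfr_percent = numeric(),
                               mean_slr_percent = numeric())
  log <- c(log, sprintf("done: %d ok, %d failed", sum(ok), n_failed))

  if (!is.null(config$output_csv))
    write_results_csv(results, config$output_csv,
                      "per-ROI measurements; areas in um^2, ratios in percent of vein-free tissue area")
  if (!is.null(config$summary_csv))
    write_results_csv(summaries, config$summary_csv,
                      "per-slide summaries; mean CFR/SLR over the slide's ROIs, percent")
  if (identical(config$log_level, "info")) message(paste(log, collapse = "\n"))

  structure(list(results = results, summaries = summaries,
                 n_failed = n_failed, log = log),
            class = "batch_result")
}

write_results_csv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, 2))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("Batch result: %d ROIs (%d failed), %d slides\n",
              nrow(x$results), x$n_failed, nrow(x$summaries)))
  if (nrow(x$summaries)) {
    cat(sprintf("  mean CFR %.2f%%, mean SLR %.2f%% across slides\n",
                mean(x$summaries$mean_cfr_percent),
                mean(x$summaries$mean_slr_percent)))
  }
  invisible(x)
}
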