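make_batch_fixture <- function(n_slides = 2, rois = 2, side = 101, seed = 31) {
  dir <- file.path(tempdir(), paste0("batch_", seed, "_", n_slides, "_", rois))
  unlink(dir, recursive = TRUE)
  generate_cohort(n_animals = n_slides, rois_per_slide = rois, side_px = side,
                  dir = dir, seed = seed)
  dir
}

test_that("ROI loading enforces the 8-bit RGB contract", {
  dir <- tempdir()
  gray <- file.path(dir, "gray.png")
  png::writePNG(matrix(runif(16), 4, 4), gray)
  expect_error(load_roi(gray), "RGB")

  deep <- file.path(dir, "deep.tif")
  tiff::writeTIFF(array(runif(4 * 4 * 3) * 0.99, dim = c(4, 4, 3)), deep,
                  bits.per.sample = 16L)
  expect_error(load_roi(deep), "16-bit")

  expect_error(load_roi(file.path(dir, "nope.png")), "not found")
  unlink(c(gray, deep))
})

test_that("batch processing yields one row per image and groups slides by name", {
  dir <- make_batch_fixture(n_slides = 3, rois = 2)
  on.exit(unlink(dir, recursive = TRUE))
  out_csv <- file.path(dir, "results.csv")
  sum_csv <- file.path(dir, "summaries.csv")
  cfg <- batch_config(dir, output_csv = out_csv, summary_csv = sum_csv,
                      log_level = "quiet")
  res <- run_batch(cfg)
  expect_s3_class(res, "batch_result")
  expect_equal(nrow(res$results), 6)
  expect_equal(nrow(res$summaries), 3)
  expect_equal(res$n_failed, 0)
  expect_true(all(res$results$status == "ok"))
  expect_equal(res$summaries$n_rois, rep(2L, 3))
  expect_equal(sort(unique(res$results$slide_id)),
               c("animal01", "animal02", "animal03"))
  expect_true(file.exists(out_csv) && file.exists(sum_csv))
  tab <- utils::read.csv(out_csv, comment.char = "#")
  expect_equal(nrow(tab), 6)
})

test_that("single-image analysis and the batch engine agree bit for bit", {
  dir <- make_batch_fixture(n_slides = 1, rois = 2, seed = 55)
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- batch_config(dir, log_level = "quiet")
  res <- run_batch(cfg)

  f <- "animal01_roi2"
  roi <- load_roi(file.path(dir, paste0(f, ".png")),
                  vein_mask_path = file.path(dir, paste0(f, "_vein.png")))
  single <- analyze_roi(roi, read_mask(file.path(dir, paste0(f, "_lumen.png"))),
                        cfg)
  got <- res$results[res$results$roi_id == f, names(single)[names(single) != "status"]]
  rownames(got) <- NULL
  expect_identical(got, single[names(got)])
})

test_that("reruns on identical inputs produce identical result tables", {
  dir <- make_batch_fixture(n_slides = 2, rois = 2, seed = 19)
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- batch_config(dir, log_level = "quiet")
  r1 <- run_batch(cfg)
  r2 <- run_batch(cfg)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$summaries, r2$summaries)
})

test_that("a missing lumen mask flags the row instead of killing the run", {
  dir <- make_batch_fixture(n_slides = 2, rois = 1, seed = 23)
  on.exit(unlink(dir, recursive = TRUE))
  unlink(file.path(dir, "animal02_roi1_lumen.png"))
  res <- run_batch(batch_config(dir, log_level = "quiet"))
  expect_equal(nrow(res$results), 2)
  expect_equal(res$n_failed, 1)
  bad <- res$results[res$results$roi_id == "animal02_roi1", ]
  expect_match(bad$status, "error")
  expect_true(is.na(bad$cfr_percent))
  expect_equal(nrow(res$summaries), 1)  # only the intact slide is summarised
})

test_that("automated lumen mode runs without annotation masks", {
  dir <- make_batch_fixture(n_slides = 1, rois = 2, seed = 61)
  on.exit(unlink(dir, recursive = TRUE))
  file.remove(list.files(dir, pattern = "_lumen", full.names = TRUE))
  res <- run_batch(batch_config(dir, lumen_mode = "automated",
                                log_level = "quiet"))
  expect_equal(res$n_failed, 0)
  expect_true(all(res$results$slr_percent > 0))
})

test_that("an empty input directory is an error", {
  dir <- file.path(tempdir(), "empty_batch")
  dir.create(dir, showWarnings = FALSE)
  on.exit(unlink(dir, recursive = TRUE))
  expect_error(run_batch(batch_config(dir, log_level = "quiet")), "no ROI images")
})

test_that("a manifest CSV overrides the file-name grouping convention", {
  dir <- make_batch_fixture(n_slides = 2, rois = 1, seed = 83)
  on.exit(unlink(dir, recursive = TRUE))
  man <- file.path(dir, "regroup.csv")
  utils::write.csv(data.frame(
    file = c("animal01_roi1.png", "animal02_roi1.png"),
    slide_id = c("groupX", "groupX")), man, row.names = FALSE)
  res <- run_batch(batch_config(dir, manifest = man, log_level = "quiet"))
  expect_equal(nrow(res$summaries), 1)
  expect_equal(res$summaries$slide_id, "groupX")
  expect_equal(res$summaries$n_rois, 2L)
})

test_that("batch configuration round-trips through the flat text format", {
  cfg <- batch_config("in", "masks", "out.csv", "sum.csv",
                      scale_um_per_px = 2.27,
                      fibrosis_band = hsb_band(120, 200, 10, 250, 0, 240),
                      smoothing = FALSE, lumen_mode = "automated",
                      bri_min = 220, sat_max = 35, min_area_px = 9,
                      random_seed = 99, log_level = "quiet")
  p <- tempfile(fileext = ".cfg")
  write_batch_config(cfg, p)
  back <- read_batch_config(p)
  expect_equal(back, cfg)
  unlink(p)
})
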