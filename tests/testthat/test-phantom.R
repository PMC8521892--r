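test_that("phantom generation is bit-reproducible given the seed", {
  a <- quick_phantom(seed = 42, side = 101)
  b <- quick_phantom(seed = 42, side = 101)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_fibrosis, b$truth_fibrosis)
  c <- quick_phantom(seed = 43, side = 101)
  expect_false(identical(a$image, c$image))
})

test_that("realized truth fractions hit the requested fractions by exact count", {
  for (f in c(0, 0.05, 0.25)) {
    ph <- quick_phantom(seed = 3, side = 171, fib = f, lum = 0.06)
    tissue <- prod(dim(ph$truth_vein)) - sum(ph$truth_vein)
    expect_equal(sum(ph$truth_fibrosis), round(f * tissue))
    expect_equal(sum(ph$truth_lumen), round(0.06 * tissue))
    expect_lt(abs(100 * sum(ph$truth_fibrosis) / tissue - 100 * f), 0.5)
  }
})

test_that("truth masks are pairwise disjoint and the vein is a centred disk", {
  ph <- quick_phantom(seed = 5, side = 171, perisinusoidal = TRUE)
  expect_false(any(ph$truth_fibrosis & ph$truth_lumen))
  expect_false(any(ph$truth_fibrosis & ph$truth_vein))
  expect_false(any(ph$truth_lumen & ph$truth_vein))
  ctr <- (171 + 1) / 2
  expect_true(ph$truth_vein[ctr, ctr])
  expect_false(ph$truth_vein[1, 1])
})

test_that("an empty phantom yields zero CFR and SLR through the pipeline", {
  ph <- quick_phantom(seed = 8, side = 101, fib = 0, lum = 0)
  expect_equal(sum(ph$truth_fibrosis), 0)
  expect_equal(sum(ph$truth_lumen), 0)
  m <- pipeline_cfr(ph)
  expect_equal(m$cfr_percent, 0)
  expect_equal(m$slr_percent, 0)
})

test_that("infeasible fraction combinations are rejected", {
  expect_error(phantom_spec(fibrosis_fraction = 0.6, lumen_fraction = 0.35),
               "below 0.9")
  expect_error(phantom_spec(side_px = 100, vein_radius_px = 60), "fit")
  # a near-full vein leaves fewer free pixels than the requested lumens
  expect_error(generate_phantom(
    phantom_spec(side_px = 101, vein_radius_px = 50,
                 fibrosis_fraction = 0, lumen_fraction = 0.85)),
    "infeasible")
})

test_that("noise degrades fibrosis recovery on average", {
  err_at <- function(sd) {
    mean(vapply(1:6, function(s) {
      ph <- generate_phantom(phantom_spec(side_px = 121, fibrosis_fraction = 0.15,
                                          lumen_fraction = 0.05, noise_sd = sd,
                                          seed = 100 + s))
      m <- pipeline_cfr(ph)
      tn <- sum(!ph$truth_vein)
      abs(m$cfr_percent - 100 * sum(ph$truth_fibrosis) / tn)
    }, 0))
  }
  expect_lt(err_at(0), err_at(60))
})

test_that("phantom files round-trip and a written cohort feeds the batch engine", {
  dir <- file.path(tempdir(), "ph_rt")
  on.exit(unlink(dir, recursive = TRUE))
  ph <- quick_phantom(seed = 12, side = 101)
  write_phantom(ph, dir, "slideA_roi1")
  img <- load_roi(file.path(dir, "slideA_roi1.png"),
                  vein_mask_path = file.path(dir, "slideA_roi1_vein.png"))
  expect_identical(dim(img$pixels), dim(ph$image))
  expect_identical(read_mask(file.path(dir, "slideA_roi1_lumen.png")),
                   ph$truth_lumen)
  spec_json <- jsonlite::read_json(file.path(dir, "slideA_roi1.json"))
  expect_equal(spec_json$seed, 12)
})

test_that("cohort generation is reproducible and matches the requested design", {
  co1 <- generate_cohort(n_animals = 6, rois_per_slide = 2, side_px = 101,
                         seed = 77)
  co2 <- generate_cohort(n_animals = 6, rois_per_slide = 2, side_px = 101,
                         seed = 77)
  expect_identical(co1$truth, co2$truth)
  expect_equal(nrow(co1$truth), 12)
  expect_true(all(co1$truth$chfs %in% 0:2))
  expect_true(all(co1$truth$true_cfr_percent >= 0 &
                  co1$truth$true_cfr_percent < 90))
  expect_error(generate_cohort(n_animals = 5, chfs_probs = c(0.5, 0.4)),
               "sum to 1")
  all0 <- generate_cohort(n_animals = 4, chfs_probs = c(1, 0, 0),
                          rois_per_slide = 1, side_px = 101, seed = 1)
  expect_true(all(all0$truth$chfs == 0))
})

test_that("cohort CFR recovers the generating group mean on small samples", {
  co <- generate_cohort(n_animals = 8, chfs_probs = c(0, 0, 1),
                        rois_per_slide = 2, side_px = 121, seed = 5)
  mu <- mean(co$truth$true_cfr_percent)
  # mean of truncated-normal draws around 14.55 with sd 6.62
  expect_lt(abs(mu - 14.55), 2 * 6.62 / sqrt(nrow(co$truth)) + 1)
})
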