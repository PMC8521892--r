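## Synthetic Masson's-trichrome phantoms with exact ground-truth masks.
##
## The phantom emulates the morphology of a centrilobular ROI: a central
## vein (white disk), thin near-white sinusoid channels radiating from it,
## a pericentral collagen ring (plus optional 1-px perisinusoidal sleeves),
## and red/pink/purple parenchyma elsewhere. Component pixels are placed by
## exact count, so the ground-truth fractions equal the requested fractions
## up to the 1-pixel rounding of `round(fraction * tissue)`.

#' Specification of a synthetic trichrome phantom
#'
#' @param side_px image side in pixels (square image).
#' @param scale_um_per_px physical pixel size (default 4.55 um/px).
#' @param vein_radius_px radius of the central vein disk; must fit inside
#'   the image. Default scales with the image (about 1/12 of the side).
#' @param fibrosis_fraction,lumen_fraction target fractions of the tissue
#'   (non-vein) area in `[0, 1)`; their sum must stay below 0.9 so the
#'   geometry remains feasible.
#' @param perisinusoidal also lay 1-px collagen sleeves along the sinusoid
#'   channels (the fine perisinusoidal-fibrosis pattern).
#' @param fat_droplet_count number of near-white fat-droplet confounders
#'   painted into the parenchyma (not part of any truth mask).
#' @param noise_sd standard deviation of additive Gaussian RGB noise
#'   (0-255 units), clipped to the valid range.
#' @param seed integer seed; phantoms are bit-reproducible given the seed.
#' @param hard_mode narrow the color margins towards the band edges to
#'   probe threshold-boundary behavior (collagen hue spans 141-189 instead
#'   of 150-185).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(side_px = 341L, scale_um_per_px = 4.55,
                         vein_radius_px = max(8L, round(side_px / 12)),
                         fibrosis_fraction = 0.10, lumen_fraction = 0.08,
                         perisinusoidal = FALSE, fat_droplet_count = 0L,
                         noise_sd = 0, seed = 1L, hard_mode = FALSE) {
  stopifnot(side_px >= 16, scale_um_per_px > 0,
            fibrosis_fraction >= 0, fibrosis_fraction < 1,
            lumen_fraction >= 0, lumen_fraction < 1,
            fat_droplet_count >= 0, noise_sd >= 0)
  if (fibrosis_fraction + lumen_fraction >= 0.9)
    stop("fibrosis_fraction + lumen_fraction must stay below 0.9", call. = FALSE)
  if (2 * vein_radius_px >= side_px)
    stop("vein disk does not fit inside the image", call. = FALSE)
  structure(list(side_px = as.integer(side_px),
                 scale_um_per_px = scale_um_per_px,
                 vein_radius_px = as.integer(vein_radius_px),
                 fibrosis_fraction = fibrosis_fraction,
                 lumen_fraction = lumen_fraction,
                 perisinusoidal = isTRUE(perisinusoidal),
                 fat_droplet_count = as.integer(fat_droplet_count),
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 hard_mode = isTRUE(hard_mode)),
            class = "phantom_spec")
}

## inverse hexcone: hue/sat/bri on 0-255 -> RGB 0-255 (vectorised)
hsb_to_rgb <- function(h, s, b) {
  hd <- (h * 360 / 255) %% 360
  sf <- s / 255
  vf <- b / 255
  c_ <- vf * sf
  x <- c_ * (1 - abs((hd / 60) %% 2 - 1))
  m <- vf - c_
  sector <- floor(hd / 60) %% 6
  r <- g <- bb <- numeric(length(hd))
  idx <- function(k) sector == k
  r[idx(0)] <- c_[idx(0)]; g[idx(0)] <- x[idx(0)]
  r[idx(1)] <- x[idx(1)];  g[idx(1)] <- c_[idx(1)]
  g[idx(2)] <- c_[idx(2)]; bb[idx(2)] <- x[idx(2)]
  g[idx(3)] <- x[idx(3)];  bb[idx(3)] <- c_[idx(3)]
  r[idx(4)] <- x[idx(4)];  bb[idx(4)] <- c_[idx(4)]
  r[idx(5)] <- c_[idx(5)]; bb[idx(5)] <- x[idx(5)]
  cbind(round_half_up((r + m) * 255),
        round_half_up((g + m) * 255),
        round_half_up((bb + m) * 255))
}

## paint HSB samples into linear pixel indices of an RGB array
paint_px <- function(img, lin, h, s, b) {
  n <- prod(dim(img)[1:2])
  rgb <- hsb_to_rgb(h, s, b)
  img[lin] <- rgb[, 1]
  img[lin + n] <- rgb[, 2]
  img[lin + 2L * n] <- rgb[, 3]
  img
}

#' Generate a trichrome phantom with ground truth
#'
#' Deterministic given `spec$seed`. Returns the RGB image together with the
#' exact truth masks for the vein, the sinusoidal lumens and the fibrosis,
#' which are pairwise disjoint by construction.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`: list with `image`,
#'   `truth_fibrosis`, `truth_lumen`, `truth_vein`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$side_px
  c0 <- (n + 1) / 2
  rr <- matrix(seq_len(n) - c0, n, n)
  cc <- t(rr)
  D <- sqrt(rr^2 + cc^2)
  vein <- D <= spec$vein_radius_px
  tissue_n <- n * n - sum(vein)

  k_lum <- round(spec$lumen_fraction * tissue_n)
  k_fib <- round(spec$fibrosis_fraction * tissue_n)

  ## Outer radius the pericentral collagen ring will reach; the sinusoid
  ## channels start beyond it (3-px guard band) so that, outside the
  ## perisinusoidal mode, collagen and near-white lumen pixels are never
  ## within the 3x3 smoothing neighborhood of each other.
  d_sorted <- sort(D[!vein])
  r_ring <- if (k_fib > 0) d_sorted[min(k_fib, length(d_sorted))]
            else spec$vein_radius_px

  ## --- sinusoid channels: thin rays radiating outward -------------------
  lumen <- matrix(FALSE, n, n)
  if (k_lum > 0) {
    ray_order <- integer(0)
    max_rays <- 600L
    ray <- 0L
    a0 <- runif(1, 0, 2 * pi)
    golden <- pi * (3 - sqrt(5))
    r0 <- max(spec$vein_radius_px, r_ring) + 3
    rmax <- sqrt(2) * n / 2 - 1
    if (r0 >= rmax)
      stop("infeasible spec: fibrosis ring leaves no room for lumens",
           call. = FALSE)
    while (length(ray_order) < k_lum && ray < max_rays) {
      ray <- ray + 1L
      th <- a0 + ray * golden
      t_seq <- seq(r0, rmax, by = 0.45)
      i <- round_half_up(c0 + t_seq * sin(th))
      j <- round_half_up(c0 + t_seq * cos(th))
      ok <- i >= 1 & i <= n & j >= 1 & j <= n
      lin <- unique((j[ok] - 1L) * n + i[ok])
      lin <- lin[!vein[lin] & !lumen[lin]]
      lumen[lin] <- TRUE
      ray_order <- c(ray_order, lin)
    }
    if (length(ray_order) < k_lum)
      stop("infeasible spec: lumen_fraction too large for the geometry",
           call. = FALSE)
    lumen[] <- FALSE
    lumen[ray_order[seq_len(k_lum)]] <- TRUE
  }

  ## --- fibrosis: perisinusoidal sleeves first, then pericentral ring ----
  fibrosis <- matrix(FALSE, n, n)
  if (k_fib > 0) {
    taken <- vein | lumen
    order_lin <- integer(0)
    if (spec$perisinusoidal && any(lumen)) {
      sleeve <- dilate1(lumen) & !taken
      order_lin <- sample(which(sleeve))
    }
    free <- setdiff(which(!taken), order_lin)
    ring <- free[order(D[free], free)]   # annulus growing out from the vein
    order_lin <- c(order_lin, ring)
    if (length(order_lin) < k_fib)
      stop("infeasible spec: fibrosis_fraction too large for the geometry",
           call. = FALSE)
    fibrosis[order_lin[seq_len(k_fib)]] <- TRUE
  }

  ## --- paint ------------------------------------------------------------
  img <- array(0L, dim = c(n, n, 3))
  npx <- n * n
  all_lin <- seq_len(npx)

  ## parenchyma everywhere first: red/pink/purple, hue well outside the
  ## collagen band (235-255 and 0-15 on the 0-255 hue circle)
  h_par <- (runif(npx, -21, 16)) %% 256
  img <- paint_px(img, all_lin, h_par, runif(npx, 70, 190), runif(npx, 150, 225))

  hue_lo <- if (spec$hard_mode) 141 else 150
  hue_hi <- if (spec$hard_mode) 189 else 185
  fl <- which(fibrosis)
  if (length(fl))
    img <- paint_px(img, fl, runif(length(fl), hue_lo, hue_hi),
                    runif(length(fl), 80, 200), runif(length(fl), 120, 220))
  ll <- which(lumen)
  if (length(ll))
    img <- paint_px(img, ll, (runif(length(ll), -20, 10)) %% 256,
                    runif(length(ll), 0, 25), runif(length(ll), 235, 255))

  ## fat-droplet confounders: near-white disks in free parenchyma
  if (spec$fat_droplet_count > 0) {
    occupied <- vein | lumen | fibrosis
    placed <- 0L
    tries <- 0L
    while (placed < spec$fat_droplet_count && tries < 50L * spec$fat_droplet_count) {
      tries <- tries + 1L
      rad <- sample(2:5, 1)
      ci <- sample(seq_len(n), 1); cj <- sample(seq_len(n), 1)
      di <- matrix(seq_len(n) - ci, n, n); dj <- t(matrix(seq_len(n) - cj, n, n))
      disk <- di^2 + dj^2 <= rad^2
      if (any(disk & occupied)) next
      dl <- which(disk)
      img <- paint_px(img, dl, (runif(length(dl), -20, 10)) %% 256,
                      runif(length(dl), 0, 25), runif(length(dl), 235, 255))
      placed <- placed + 1L
    }
  }

  ## vein: pure white disk
  vl <- which(vein)
  if (length(vl)) img <- paint_px(img, vl, rep(0, length(vl)),
                                  rep(0, length(vl)), rep(255, length(vl)))

  if (spec$noise_sd > 0) {
    img <- img + rnorm(length(img), 0, spec$noise_sd)
    img[] <- pmin(255, pmax(0, round_half_up(img)))
  }
  storage.mode(img) <- "integer"

  structure(list(image = img,
                 truth_fibrosis = fibrosis,
                 truth_lumen = lumen,
                 truth_vein = vein,
                 spec = spec),
            class = "phantom")
}

## 1-px 8-neighborhood dilation
dilate1 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  sh <- function(mk, di, dj) {
    r <- matrix(FALSE, n, m)
    ri <- seq_len(n) + di; rj <- seq_len(m) + dj
    ok_i <- ri >= 1 & ri <= n; ok_j <- rj >= 1 & rj <= m
    r[which(ok_i), which(ok_j)] <- mk[ri[ok_i], rj[ok_j]]
    r
  }
  for (di in -1:1) for (dj in -1:1)
    if (di != 0 || dj != 0) out <- out | sh(mask, di, dj)
  out
}

#' @export
print.phantom <- function(x, ...) {
  sp <- x$spec
  tn <- prod(dim(x$truth_vein)) - sum(x$truth_vein)
  cat(sprintf("Trichrome phantom %d x %d px (seed %d)\n",
              sp$side_px, sp$side_px, sp$seed))
  cat(sprintf("  vein %d px; fibrosis %d px (%.2f%% of tissue); lumen %d px (%.2f%% of tissue)\n",
              sum(x$truth_vein), sum(x$truth_fibrosis),
              100 * sum(x$truth_fibrosis) / tn,
              sum(x$truth_lumen), 100 * sum(x$truth_lumen) / tn))
  invisible(x)
}

#' @export
plot.phantom <- function(x, ...) {
  img <- x$image / 255
  op <- graphics::par(mar = c(0, 0, 1, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1)
  graphics::title(sprintf("phantom seed %d", x$spec$seed))
  invisible(x)
}

#' Convert a phantom to a ROI ready for the pipeline
#'
#' Attaches the scale and the truth vein mask (the manual vein-extraction
#' step is answered by ground truth here) and applies the white vein fill.
#'
#' @param phantom a [generate_phantom()] result.
#' @param roi_id identifier for result tables.
#' @return a [roi_image()].
#' @export
as_roi <- function(phantom, roi_id = sprintf("phantom_%d", phantom$spec$seed)) {
  stopifnot(inherits(phantom, "phantom"))
  roi <- roi_image(phantom$image, phantom$spec$scale_um_per_px,
                   roi_id = roi_id)
  exclude_vein(roi, phantom$truth_vein)
}

#' Write a phantom to disk
#'
#' Emits `<id>.png` (the RGB image), `<id>_vein.png`, `<id>_lumen.png`,
#' `<id>_fibrosis.png` (8-bit masks, 0 = background, 255 = component) and a
#' `<id>.json` sidecar with the generating parameters.
#'
#' @param phantom a phantom.
#' @param dir output directory (created if needed).
#' @param id file-name stem.
#' @return invisibly, the image path.
#' @export
write_phantom <- function(phantom, dir, id) {
  stopifnot(inherits(phantom, "phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(id, ".png"))
  png::writePNG(phantom$image / 255, img_path)
  write_mask(phantom$truth_vein, file.path(dir, paste0(id, "_vein.png")))
  write_mask(phantom$truth_lumen, file.path(dir, paste0(id, "_lumen.png")))
  write_mask(phantom$truth_fibrosis, file.path(dir, paste0(id, "_fibrosis.png")))
  jsonlite::write_json(unclass(phantom$spec),
                       file.path(dir, paste0(id, ".json")), auto_unbox = TRUE)
  invisible(img_path)
}

#' Generate a graded cohort of phantom slides
#'
#' Emulates a study design of `n_animals` slides with `rois_per_slide` ROIs
#' each: every animal receives a congestive-hepatic-fibrosis score drawn
#' from `chfs_probs`, and each of its ROIs a target fibrosis fraction drawn
#' from the score's normal distribution (`cfr_means`/`cfr_sds`, percent
#' scale) truncated to `[0, 0.9)`. Defaults reproduce a monocrotaline-type
#' design: 50 animals, score probabilities (0.46, 0.32, 0.22) and CFR
#' summaries 1.32 +/- 1.07, 8.00 +/- 4.45 and 14.55 +/- 6.62 percent.
#'
#' @param n_animals number of animals (slides).
#' @param chfs_probs probability of each score 0..(k-1); must sum to 1.
#' @param cfr_means,cfr_sds per-score mean and sd of the ROI fibrosis
#'   percentage.
#' @param rois_per_slide ROIs generated per slide (default 5).
#' @param side_px phantom side in pixels.
#' @param lumen_mean,lumen_sd distribution of the per-ROI lumen fraction
#'   (score-independent).
#' @param dir if non-`NULL`, phantoms and their vein/lumen masks are written
#'   there (file names `animalNN_roiM.png`) and only the truth table is
#'   returned; otherwise phantoms are returned in memory.
#' @param seed integer seed; the whole cohort is reproducible.
#' @return list with `truth` (data frame: `animal_id`, `chfs`, `roi`,
#'   `file`, `true_cfr_percent`, `true_slr_percent`) and, when `dir` is
#'   `NULL`, `phantoms` (list of phantom objects in truth-table order).
#' @export
generate_cohort <- function(n_animals = 50L,
                            chfs_probs = c(0.46, 0.32, 0.22),
                            cfr_means = c(1.32, 8.00, 14.55),
                            cfr_sds = c(1.07, 4.45, 6.62),
                            rois_per_slide = 5L, side_px = 341L,
                            lumen_mean = 0.08, lumen_sd = 0.02,
                            dir = NULL, seed = 1L) {
  if (abs(sum(chfs_probs) - 1) > 1e-9 || any(chfs_probs < 0))
    stop("chfs_probs must be non-negative and sum to 1", call. = FALSE)
  if (length(cfr_means) != length(chfs_probs) ||
      length(cfr_sds) != length(chfs_probs))
    stop("cfr_means and cfr_sds must match chfs_probs in length", call. = FALSE)
  stopifnot(n_animals >= 1, rois_per_slide >= 1)
  set.seed(seed)
  scores <- sample(seq_along(chfs_probs) - 1L, n_animals, replace = TRUE,
                   prob = chfs_probs)
  rtrunc <- function(mu, sdv, lo, hi) {
    for (i in 1:1000) {
      x <- rnorm(1, mu, sdv)
      if (x >= lo && x < hi) return(x)
    }
    min(max(mu, lo), hi - 1e-6)
  }
  rows <- vector("list", n_animals * rois_per_slide)
  phantoms <- if (is.null(dir)) vector("list", n_animals * rois_per_slide)
  k <- 0L
  for (a in seq_len(n_animals)) {
    animal <- sprintf("animal%02d", a)
    for (r in seq_len(rois_per_slide)) {
      k <- k + 1L
      sc <- scores[a]
      ffrac <- rtrunc(cfr_means[sc + 1L] / 100, cfr_sds[sc + 1L] / 100, 0, 0.9)
      lfrac <- rtrunc(lumen_mean, lumen_sd, 0, 0.5)
      sub_seed <- (seed * 100003L + k * 7919L) %% 2147483629L
      sp <- phantom_spec(side_px = side_px, fibrosis_fraction = ffrac,
                         lumen_fraction = lfrac, seed = sub_seed)
      ph <- generate_phantom(sp)
      id <- sprintf("%s_roi%d", animal, r)
      tn <- prod(dim(ph$truth_vein)) - sum(ph$truth_vein)
      rows[[k]] <- data.frame(
        animal_id = animal, chfs = sc, roi = r,
        file = paste0(id, ".png"),
        true_cfr_percent = 100 * sum(ph$truth_fibrosis) / tn,
        true_slr_percent = 100 * sum(ph$truth_lumen) / tn,
        stringsAsFactors = FALSE)
      if (is.null(dir)) phantoms[[k]] <- ph else write_phantom(ph, dir, id)
    }
  }
  truth <- do.call(rbind, rows)
  if (!is.null(dir)) {
    utils::write.csv(truth, file.path(dir, "manifest.csv"), row.names = FALSE)
    list(truth = truth)
  } else {
    list(truth = truth, phantoms = phantoms)
  }
}
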