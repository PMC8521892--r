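## Color-model conversion and box thresholding on the 0-255 HSB scale.
##
## Images are integer arrays of dimension height x width x 3 with values in
## [0, 255]; masks are logical matrices of the same height x width.

round_half_up <- function(x) floor(x + 0.5)

#' Validate an RGB raster
#'
#' Checks that `img` is a height x width x 3 numeric array with all values in
#' \[0, 255\]. Used internally by every operation that consumes RGB pixels.
#'
#' @param img candidate array.
#' @return the array, invisibly, with storage mode integer.
#' @keywords internal
validate_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an RGB array of dimension height x width x 3", call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop("image must have width and height >= 1", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

#' HSB threshold band
#'
#' A box in hue/saturation/brightness space, each channel on the integer
#' 0-255 scale of the color-threshold tooling this package reproduces. All
#' bounds are inclusive. The hue interval may wrap around the circle
#' (`hue_lo > hue_hi`), in which case a pixel passes when
#' `H >= hue_lo | H <= hue_hi`; saturation and brightness bounds must be
#' ordered.
#'
#' @param hue_lo,hue_hi,sat_lo,sat_hi,bri_lo,bri_hi integer bounds in
#'   \[0, 255\].
#' @return an object of class `hsb_band`.
#' @examples
#' fibrosis_band()           # hue 140-190, saturation 0-255, brightness 0-248
#' lumen_band()              # hue 0-255, saturation 0-255, brightness 0-50
#' hsb_band(240, 20, 0, 255, 0, 255)  # wraparound red hue band
#' @export
hsb_band <- function(hue_lo, hue_hi, sat_lo, sat_hi, bri_lo, bri_hi) {
  b <- c(hue_lo = hue_lo, hue_hi = hue_hi, sat_lo = sat_lo, sat_hi = sat_hi,
         bri_lo = bri_lo, bri_hi = bri_hi)
  if (anyNA(b) || any(b < 0) || any(b > 255) || any(b != round(b)))
    stop("all band bounds must be integers in [0, 255]", call. = FALSE)
  if (sat_lo > sat_hi) stop("sat_lo must not exceed sat_hi", call. = FALSE)
  if (bri_lo > bri_hi) stop("bri_lo must not exceed bri_hi", call. = FALSE)
  structure(as.list(as.integer(b)), names = names(b), class = "hsb_band")
}

#' @export
print.hsb_band <- function(x, ...) {
  wrap <- if (x$hue_lo > x$hue_hi) " (wraparound)" else ""
  cat(sprintf("HSB band: hue %d-%d%s, saturation %d-%d, brightness %d-%d\n",
              x$hue_lo, x$hue_hi, wrap, x$sat_lo, x$sat_hi, x$bri_lo, x$bri_hi))
  invisible(x)
}

#' Fixed segmentation bands
#'
#' The empirically established threshold settings for Masson's-trichrome
#' collagen (`fibrosis_band`: hue 140-190, saturation 0-255, brightness
#' 0-248) and for black-filled sinusoidal lumens (`lumen_band`: hue 0-255,
#' saturation 0-255, brightness 0-50).
#'
#' @return an `hsb_band`.
#' @export
fibrosis_band <- function() hsb_band(140L, 190L, 0L, 255L, 0L, 248L)

#' @rdname fibrosis_band
#' @export
lumen_band <- function() hsb_band(0L, 255L, 0L, 255L, 0L, 50L)

#' Convert an RGB image to HSB on the 0-255 integer scale
#'
#' Standard hexcone conversion: brightness is the channel maximum, saturation
#' is `255 * (max - min) / max` (0 when max = 0), and hue is the usual
#' piecewise angle in degrees mapped onto 0-255 by `h * 255 / 360` and
#' rounded half-up. Achromatic pixels (max = min) get hue 0, so white and
#' black are controlled purely through the brightness bound of a band.
#'
#' @param img RGB array (height x width x 3, values 0-255).
#' @return integer array of the same dimensions; slices are hue, saturation,
#'   brightness.
#' @examples
#' px <- array(c(0, 0, 255), dim = c(1, 1, 3))
#' rgb_to_hsb(px)[1, 1, ]  # 170 255 255: pure blue, 240 degrees
#' @export
rgb_to_hsb <- function(img) {
  validate_rgb(img)
  h0 <- dim(img)[1]; w0 <- dim(img)[2]
  r <- matrix(img[, , 1], h0, w0)
  g <- matrix(img[, , 2], h0, w0)
  b <- matrix(img[, , 3], h0, w0)
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(mx), ncol(mx))
  ch <- d > 0
  if (any(ch)) {
    dr <- d[ch]
    hr <- numeric(sum(ch))
    ir <- mx[ch] == r[ch]
    ig <- !ir & mx[ch] == g[ch]
    ib <- !ir & !ig
    hr[ir] <- ((g[ch][ir] - b[ch][ir]) / dr[ir]) %% 6
    hr[ig] <- (b[ch][ig] - r[ch][ig]) / dr[ig] + 2
    hr[ib] <- (r[ch][ib] - g[ch][ib]) / dr[ib] + 4
    h[ch] <- hr * 60
  }
  s <- matrix(0, nrow(mx), ncol(mx))
  nz <- mx > 0
  s[nz] <- 255 * d[nz] / mx[nz]
  ## Hue and saturation are rationals with denominator <= 2*255*6; exact
  ## .5 ties must round up, but floating point can land a hair below the
  ## tie. The epsilon is far smaller than the gap to any non-tie value
  ## (>= 1/1530), so it only repairs ties, never shifts a true value.
  half_up_exact <- function(x) floor(x + 0.5 + 1e-9)
  out <- array(0L, dim = dim(img))
  out[, , 1] <- as.integer(half_up_exact(h * 255 / 360))
  out[, , 2] <- as.integer(half_up_exact(s))
  out[, , 3] <- as.integer(round_half_up(mx))
  out
}

#' Select pixels inside an HSB band
#'
#' All six bounds are inclusive. With a wraparound hue band
#' (`hue_lo > hue_hi`) the hue test is `H >= hue_lo | H <= hue_hi`.
#'
#' @param hsb HSB array as produced by [rgb_to_hsb()].
#' @param band an [hsb_band()].
#' @return logical matrix, `TRUE` where the pixel lies inside the band.
#' @export
threshold_hsb <- function(hsb, band) {
  if (!inherits(band, "hsb_band")) stop("band must be an hsb_band", call. = FALSE)
  if (!is.array(hsb) || length(dim(hsb)) != 3L || dim(hsb)[3] != 3L)
    stop("expected an HSB array of dimension height x width x 3", call. = FALSE)
  dh <- dim(hsb)[1]; dw <- dim(hsb)[2]
  h <- matrix(hsb[, , 1], dh, dw)
  s <- matrix(hsb[, , 2], dh, dw)
  b <- matrix(hsb[, , 3], dh, dw)
  hue_ok <- if (band$hue_lo <= band$hue_hi)
    h >= band$hue_lo & h <= band$hue_hi
  else
    h >= band$hue_lo | h <= band$hue_hi
  hue_ok & s >= band$sat_lo & s <= band$sat_hi &
    b >= band$bri_lo & b <= band$bri_hi
}

#' 3x3 mean smoothing
#'
#' Per-channel unweighted 3x3 mean filter; at image edges the mean is taken
#' over the in-image part of the neighborhood only. Channel means are rounded
#' half-up back to integers. Applied before fibrosis thresholding to reduce
#' staining noise.
#'
#' @param img RGB array (height x width x 3, values 0-255).
#' @return smoothed RGB integer array of the same dimensions.
#' @export
smooth_rgb <- function(img) {
  validate_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  i0 <- pmax(seq_len(h) - 1L, 1L); i1 <- pmin(seq_len(h) + 1L, h)
  j0 <- pmax(seq_len(w) - 1L, 1L); j1 <- pmin(seq_len(w) + 1L, w)
  cnt <- outer(i1 - i0 + 1L, j1 - j0 + 1L)
  out <- array(0L, dim = dim(img))
  for (k in 1:3) {
    m <- matrix(img[, , k], h, w)
    ii <- matrix(0, h + 1L, w + 1L)
    cs_cols <- matrix(apply(m, 2L, cumsum), h, w)
    ii[-1L, -1L] <- t(matrix(apply(cs_cols, 1L, cumsum), w, h))
    sums <- ii[i1 + 1L, j1 + 1L, drop = FALSE] - ii[i0, j1 + 1L, drop = FALSE] -
            ii[i1 + 1L, j0, drop = FALSE] + ii[i0, j0, drop = FALSE]
    out[, , k] <- as.integer(round_half_up(sums / cnt))
  }
  out
}
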