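# Independent scalar hexcone oracle in exact integer arithmetic.
# hue255 = round_half_up(h_deg * 255 / 360) computed as num*85 / (2d) with
# integer quotient/remainder, so rational .5 ties are rounded without any
# floating-point involvement.
hsb_oracle_px <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  if (d == 0L) {
    hue <- 0L
  } else {
    num <- if (mx == r) (g - b) %% (6L * d)
           else if (mx == g) (b - r) + 2L * d
           else (r - g) + 4L * d
    q <- num * 85L
    hue <- q %/% (2L * d) + as.integer((q %% (2L * d)) >= d)
  }
  sat <- if (mx == 0L) 0L else {
    q <- 255L * d
    q %/% mx + as.integer(2L * (q %% mx) >= mx)
  }
  c(hue, sat, mx)
}

hsb_oracle <- function(triples) {
  res <- t(apply(triples, 1, function(p) hsb_oracle_px(p[1], p[2], p[3])))
  storage.mode(res) <- "integer"
  unname(res)
}

# package conversion of an n x 3 matrix of triples, as n x 3 HSB matrix
hsb_pkg <- function(triples) {
  img <- array(0L, dim = c(nrow(triples), 1, 3))
  img[, 1, ] <- as.integer(triples)
  out <- rgb_to_hsb(img)
  matrix(out, nrow(triples), 3)
}

single_px <- function(r, g, b) array(as.integer(c(r, g, b)), dim = c(1, 1, 3))

# flat-color image builder
flat_img <- function(r, g, b, h = 8, w = 8) {
  img <- array(0L, dim = c(h, w, 3))
  img[, , 1] <- as.integer(r); img[, , 2] <- as.integer(g)
  img[, , 3] <- as.integer(b)
  img
}

# small quick phantom for pipeline tests
quick_phantom <- function(seed = 1, side = 171, fib = 0.10, lum = 0.08, ...) {
  generate_phantom(phantom_spec(side_px = side, fibrosis_fraction = fib,
                                lumen_fraction = lum, seed = seed, ...))
}

# run the reference pipeline (annotated lumens from ground truth) on a phantom
pipeline_cfr <- function(ph) {
  roi <- as_roi(ph)
  fib <- segment_fibrosis(roi)
  lum <- segment_lumen_annotated(annotate_lumens(roi, ph$truth_lumen))
  measure_roi(roi, fib, lum)
}
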