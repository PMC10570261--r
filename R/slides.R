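#' Synthetic Masson's-trichrome slide with known fibrosis fraction
#'
#' Builds an RGB raster (8-bit, values 0-255) of red/pink-dominant "muscle"
#' with blue-dominant "collagen" blobs.  The blob geometry comes from a
#' smooth random field (sum of Gaussian bumps); the ground-truth mask is the
#' top `round(fraction * npix)` field pixels, so the truth fraction matches
#' the request to well under 0.5 percentage points.
#'
#' @param shape `c(height, width)` in pixels.
#' @param fibrosis_fraction requested collagen area fraction in `[0, 1]`.
#' @param blob_scale Gaussian bump SD in pixels (default 8).
#' @param seed optional integer seed.
#' @return a `synthetic_slide` list: `pixels` (h x w x 3 array),
#'   `truth_mask` (h x w logical), `truth_fraction`.
#' @export
generate_trichrome_slide <- function(shape = c(96, 96), fibrosis_fraction,
                                     blob_scale = 8, seed = NULL) {
  check_that(fibrosis_fraction >= 0 && fibrosis_fraction <= 1,
             "fibrosis_fraction must be in [0, 1]")
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  check_that(h > 0 && w > 0, "shape must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  npix <- h * w
  n_pos <- round(fibrosis_fraction * npix)

  field <- matrix(0, h, w)
  if (n_pos > 0L && n_pos < npix) {
    nb <- max(10L, ceiling(npix / (blob_scale^2 * 8)))
    cx <- stats::runif(nb, 1, w); cy <- stats::runif(nb, 1, h)
    amp <- stats::runif(nb, 0.5, 1.5)
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    for (k in seq_len(nb))
      field <- field + amp[k] *
        exp(-((xs - cx[k])^2 + (ys - cy[k])^2) / (2 * blob_scale^2))
    field <- field + matrix(stats::rnorm(npix, 0, 1e-6), h, w)  # break ties
  }
  mask <- matrix(FALSE, h, w)
  if (n_pos >= npix) {
    mask[] <- TRUE
  } else if (n_pos > 0L) {
    mask[order(field, decreasing = TRUE)[seq_len(n_pos)]] <- TRUE
  }

  px <- array(0, dim = c(h, w, 3L))
  noise <- function() matrix(stats::rnorm(npix, 0, 6), h, w)
  # muscle: pink (R >> B); collagen: blue (B >> R)
  px[, , 1L] <- ifelse(mask, 90, 200) + noise()
  px[, , 2L] <- ifelse(mask, 105, 120) + noise()
  px[, , 3L] <- ifelse(mask, 200, 125) + noise()
  px <- round(pmin(pmax(px, 0), 255))

  structure(list(pixels = px, truth_mask = mask,
                 truth_fraction = sum(mask) / npix),
            class = "synthetic_slide")
}

#' Synthetic punctate-fluorescence slide
#'
#' Grayscale raster (16-bit range) of Gaussian spots over a low-level noisy
#' background, standing in for high-intensity punctate immunostaining.  The
#' spot centers and amplitudes are returned as ground truth.
#'
#' @param shape `c(height, width)` in pixels.
#' @param n_puncta number of spots (>= 0).
#' @param amplitude peak spot amplitude above background (default 20000).
#' @param background_sd background Gaussian noise SD (default 200).
#' @param spot_sigma spot Gaussian SD in pixels (default 1.8).
#' @param bg_mean background mean level (default 1000).
#' @param seed optional integer seed.
#' @return a `synthetic_slide` list: `pixels` (h x w integer matrix),
#'   `truth_spots` (data.frame row, col, amplitude), `n_puncta`.
#' @export
generate_puncta_slide <- function(shape = c(96, 96), n_puncta, amplitude = 20000,
                                  background_sd = 200, spot_sigma = 1.8,
                                  bg_mean = 1000, seed = NULL) {
  check_that(n_puncta >= 0, "n_puncta must be >= 0")
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  check_that(h > 0 && w > 0, "shape must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  npix <- h * w
  img <- matrix(bg_mean + stats::rnorm(npix, 0, background_sd), h, w)
  margin <- min(ceiling(3 * spot_sigma), floor((min(h, w) - 1) / 2))
  spots <- data.frame(row = numeric(0), col = numeric(0), amplitude = numeric(0))
  if (n_puncta > 0L) {
    rows <- stats::runif(n_puncta, 1 + margin, h - margin)
    cols <- stats::runif(n_puncta, 1 + margin, w - margin)
    half <- ceiling(4 * spot_sigma)
    for (k in seq_len(n_puncta)) {
      r0 <- max(1L, floor(rows[k] - half)); r1 <- min(h, ceiling(rows[k] + half))
      c0 <- max(1L, floor(cols[k] - half)); c1 <- min(w, ceiling(cols[k] + half))
      rr <- r0:r1; cc <- c0:c1
      patch <- amplitude * outer(exp(-(rr - rows[k])^2 / (2 * spot_sigma^2)),
                                 exp(-(cc - cols[k])^2 / (2 * spot_sigma^2)))
      img[rr, cc] <- img[rr, cc] + patch
    }
    spots <- data.frame(row = rows, col = cols, amplitude = amplitude)
  }
  img <- round(pmin(pmax(img, 0), 65535))
  structure(list(pixels = img, truth_spots = spots, n_puncta = n_puncta),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (length(d) == 3L) "RGB" else "grayscale"
  cat(sprintf("<synthetic_slide %s %dx%d>\n", kind, d[1L], d[2L]))
  invisible(x)
}
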