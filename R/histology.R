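#' Gray-level histogram of an image
#'
#' @param image numeric matrix of integer-valued gray levels.
#' @param n_levels number of gray levels (256 for 8-bit input; intensities
#'   are clamped into `0:(n_levels-1)` after rounding).
#' @return a `gray_histogram` list: `counts` (length `n_levels`), `levels`
#'   (`0:(n_levels-1)`), `total`.
#' @export
gray_histogram <- function(image, n_levels = 256L) {
  check_that(length(image) > 0, "empty image", "degenerate_input")
  g <- pmin(pmax(round(as.numeric(image)), 0), n_levels - 1L)
  counts <- tabulate(g + 1L, nbins = n_levels)
  structure(list(counts = counts, levels = 0:(n_levels - 1L), total = sum(counts)),
            class = "gray_histogram")
}

as_gray_histogram <- function(hist) {
  if (inherits(hist, "gray_histogram")) return(hist)
  counts <- as.numeric(hist)
  structure(list(counts = counts, levels = seq_along(counts) - 1L,
                 total = sum(counts)), class = "gray_histogram")
}

# Renyi entropy sum (background + foreground) for every candidate threshold.
# Returns a vector over thresholds 0..(L-1); -Inf where a class is empty.
# For alpha = 1 this is the Shannon (maximum-entropy) limit.
renyi_criterion <- function(p, alpha) {
  L <- length(p)
  P1 <- cumsum(p)
  out <- rep(-Inf, L)
  for (t in seq_len(L)) {
    p1 <- P1[t]; p2 <- 1 - p1
    if (p1 <= 0 || p2 <= 0) next
    b <- p[1:t]; b <- b[b > 0]
    f <- p[(t + 1L):L]; f <- f[f > 0]
    if (alpha == 1) {
      hb <- -sum((b / p1) * log(b / p1))
      hf <- -sum((f / p2) * log(f / p2))
    } else {
      hb <- log(sum((b / p1)^alpha)) / (1 - alpha)
      hf <- log(sum((f / p2)^alpha)) / (1 - alpha)
    }
    out[t] <- hb + hf
  }
  out
}

#' Renyi-entropy threshold selection
#'
#' For each order alpha in \{0.5, 1, 2\} the gray level maximizing the sum of
#' background and foreground Renyi entropies of the class-normalized
#' histogram is selected (alpha = 1 is the Shannon/maximum-entropy limit;
#' ties break toward the lowest level).  The three candidates are then
#' combined with the standard beta-weighting rule of the three-threshold
#' Renyi method, matching the behaviour of the widely used ImageJ
#' "RenyiEntropy" auto-threshold: with sorted candidates `t1 <= t2 <= t3`,
#' cumulative probability `P(.)` and `omega = P(t3) - P(t1)`, the weights
#' `(b1, b2, b3)` are `(1, 2, 1)` when the candidates agree within 5 levels
#' at both gaps or at neither, `(0, 1, 3)` when only the lower pair is
#' close, `(3, 1, 0)` when only the upper pair is close, and the combined
#' threshold is
#' `t1 (P(t1) + omega b1 / 4) + t2 omega b2 / 4 + t3 (1 - P(t3) + omega b3 / 4)`
#' truncated to an integer gray level.
#'
#' @param hist a [gray_histogram()] (or a bare counts vector).
#' @return a `threshold_result` list: `threshold` (combined),
#'   `per_alpha_thresholds` (named: `alpha_0.5`, `alpha_1`, `alpha_2`).
#' @export
renyi_threshold <- function(hist) {
  h <- as_gray_histogram(hist)
  check_that(sum(h$counts > 0) >= 2L,
             "histogram needs at least two nonzero bins", "degenerate_input")
  p <- h$counts / sum(h$counts)
  alphas <- c(0.5, 1, 2)
  tstars <- vapply(alphas, function(a) {
    crit <- renyi_criterion(p, a)
    h$levels[which.max(crit)]  # which.max -> lowest level on ties
  }, numeric(1))
  names(tstars) <- paste0("alpha_", c("0.5", "1", "2"))

  ts <- sort(tstars)
  t1 <- ts[1L]; t2 <- ts[2L]; t3 <- ts[3L]
  close_low <- abs(t1 - t2) <= 5
  close_high <- abs(t2 - t3) <= 5
  if (close_low && close_high) {
    beta <- c(1, 2, 1)
  } else if (close_low && !close_high) {
    beta <- c(0, 1, 3)
  } else if (!close_low && close_high) {
    beta <- c(3, 1, 0)
  } else {
    beta <- c(1, 2, 1)
  }
  P1 <- cumsum(p)
  Pof <- function(t) P1[match(t, h$levels)]
  omega <- Pof(t3) - Pof(t1)
  comb <- t1 * (Pof(t1) + 0.25 * omega * beta[1L]) +
    0.25 * t2 * omega * beta[2L] +
    t3 * (1 - Pof(t3) + 0.25 * omega * beta[3L])
  structure(list(threshold = trunc(comb), per_alpha_thresholds = tstars),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result: combined %g (alpha 0.5/1/2: %g/%g/%g)>\n",
              x$threshold, x$per_alpha_thresholds[1L],
              x$per_alpha_thresholds[2L], x$per_alpha_thresholds[3L]))
  invisible(x)
}

#' Integrated density of above-threshold signal
#'
#' Sum of pixel intensities strictly above the threshold, divided by the
#' total image area in pixels — the positive punctate signal per unit area,
#' excluding all background below the entropy threshold.
#'
#' @param image numeric matrix of gray values.
#' @param threshold gray level; pixels must exceed it strictly to count.
#' @return intensity per pixel (0 when nothing exceeds the threshold).
#' @export
integrated_density <- function(image, threshold) {
  check_that(length(image) > 0, "empty image", "degenerate_input")
  v <- as.numeric(image)
  sum(v[v > threshold]) / length(v)
}

#' Percent fibrosis of a trichrome slide
#'
#' Transparent channel-dominance classifier for Masson's-trichrome images:
#' tissue pixels are those whose luminance `(R + G + B)/3` is at or above
#' `luminance_floor` (excluding empty glass); fibrosis-positive pixels are
#' tissue pixels whose blue channel exceeds the red channel by more than
#' `margin` (collagen stains blue, muscle red/pink).
#'
#' @param slide an RGB array (h x w x 3, 0-255) or a `synthetic_slide`.
#' @param margin blue-over-red dominance margin on the 8-bit scale (default 20).
#' @param luminance_floor minimum mean-channel luminance for tissue (default 10).
#' @param region optional region label: one of `"center"`, `"edge"`,
#'   `"remote"`, `"right_ventricle"`.
#' @return a `fibrosis_result` list: `percent_fibrosis`, `region`,
#'   `n_positive`, `n_tissue`, `n_excluded`, `n_total`.
#' @export
fibrosis_percent <- function(slide, margin = 20, luminance_floor = 10,
                             region = NA_character_) {
  px <- if (inherits(slide, "synthetic_slide")) slide$pixels else slide
  check_that(length(dim(px)) == 3L && dim(px)[3L] == 3L,
             "slide must be an RGB (h x w x 3) array", "format_error")
  if (!is.na(region))
    check_that(region %in% c("center", "edge", "remote", "right_ventricle"),
               "unknown region label")
  r <- px[, , 1L]; g <- px[, , 2L]; b <- px[, , 3L]
  lum <- (r + g + b) / 3
  tissue <- lum >= luminance_floor
  n_total <- length(lum)
  n_tissue <- sum(tissue)
  if (n_tissue == 0L)
    abort_cardiact("no tissue pixels above the luminance floor", "degenerate_input")
  pos <- tissue & (b - r > margin)
  structure(list(percent_fibrosis = 100 * sum(pos) / n_tissue,
                 region = region, n_positive = sum(pos), n_tissue = n_tissue,
                 n_excluded = n_total - n_tissue, n_total = n_total),
            class = "fibrosis_result")
}

#' Per-region descriptive statistics
#'
#' Groups scalar quantifications (percent fibrosis, integrated density, ...)
#' by tissue region and reports mean, SD, SEM (= SD/sqrt(n)) and n.  A
#' single-value region gets SD 0 with `sd_defined = FALSE`; a requested
#' region with no data is omitted with a warning.
#'
#' @param values numeric vector of per-image results.
#' @param regions character vector of region labels, same length.
#' @param regions_requested regions to report (default: those present).
#' @return data.frame with columns `region`, `n`, `mean`, `sd`, `sem`,
#'   `sd_defined`.
#' @export
region_summary <- function(values, regions, regions_requested = unique(regions)) {
  check_that(length(values) == length(regions),
             "values and regions must have equal length", "format_error")
  rows <- lapply(regions_requested, function(rg) {
    v <- values[regions == rg]
    if (length(v) == 0L) {
      warning(sprintf("region '%s' has no data; omitted", rg))
      return(NULL)
    }
    s <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(region = rg, n = length(v), mean = mean(v), sd = s,
               sem = s / sqrt(length(v)), sd_defined = length(v) > 1L)
  })
  out <- do.call(rbind, rows)
  check_that(!is.null(out) && nrow(out) >= 1L, "no region had data",
             "insufficient_data")
  rownames(out) <- NULL
  out
}
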