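#' Per-slice preprocessing parameters
#'
#' Defaults follow the pipeline's standard settings: a Gaussian blur of
#' sigma 1 px, a histogram expansion trimming 10% of the dynamic range from
#' each end, and a despeckle floor of 0.043 um^2 (one pixel at ~0.21 um/px).
#'
#' @param gaussian_sigma Blur width in pixels, `>= 0` (0 disables blurring).
#' @param trim_fraction Fraction of the dynamic range trimmed from each end
#'   before contrast stretching, in `[0, 0.5)`.
#' @param despeckle_area_um2 Connected components with area at or below this
#'   value (um^2) are removed after thresholding.
#' @return An object of class `nmj_preprocess_params`.
#' @export
preprocess_params <- function(gaussian_sigma = 1.0, trim_fraction = 0.10,
                              despeckle_area_um2 = 0.043) {
  stopifnot(gaussian_sigma >= 0,
            trim_fraction >= 0, trim_fraction < 0.5,
            despeckle_area_um2 >= 0)
  structure(list(gaussian_sigma = gaussian_sigma,
                 trim_fraction = trim_fraction,
                 despeckle_area_um2 = despeckle_area_um2),
            class = "nmj_preprocess_params")
}

# Reflect an out-of-range index back into [1, n] (mirror about the edge
# pixel, ImageJ-style), folding repeatedly for very small n.
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  repeat {
    under <- j < 1L
    over <- j > n
    if (!any(under) && !any(over)) return(j)
    j[under] <- 2L - j[under]
    j[over] <- 2L * n - j[over]
  }
}

#' Gaussian blur of a single slice
#'
#' Separable convolution with a normalized discrete Gaussian kernel
#' (radius `ceiling(4 * sigma)`), reflect padding at the frame edges.
#' `sigma = 0` returns the input unchanged. A constant image is preserved
#' exactly; total intensity is conserved up to boundary reflection.
#'
#' @param img Numeric intensity matrix.
#' @param sigma Blur width in pixels.
#' @return Numeric matrix of the same shape (not rounded).
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(( -r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, margin) {
    n <- dim(m)[margin]
    acc <- 0
    for (o in -r:r) {
      j <- reflect_index(seq_len(n) + o, n)
      shifted <- if (margin == 1L) m[j, , drop = FALSE] else m[, j, drop = FALSE]
      acc <- acc + k[o + r + 1L] * shifted
    }
    acc
  }
  conv1(conv1(img, 1L), 2L)
}

#' Histogram-expansion bounds of a slice
#'
#' Computes the trimmed contrast bounds from the observed grayscale extremes:
#' `range = max - min`, `nmin = min + trim_fraction * range`,
#' `nmax = max - trim_fraction * range`.
#'
#' @param img Numeric intensity matrix.
#' @param trim_fraction Fraction of the dynamic range trimmed from each end.
#' @param mask Optional logical matrix restricting which pixels define the
#'   extremes (e.g. an ROI).
#' @return List with `min`, `max`, `range`, `nmin`, `nmax`.
#' @examples
#' b <- expansion_bounds(matrix(c(0, 255), 1, 2), 0.10)
#' c(b$nmin, b$nmax)  # 25.5 229.5
#' @export
expansion_bounds <- function(img, trim_fraction = 0.10, mask = NULL) {
  v <- if (is.null(mask)) img else img[mask]
  mn <- min(v); mx <- max(v)
  rg <- mx - mn
  list(min = mn, max = mx, range = rg,
       nmin = mn + trim_fraction * rg,
       nmax = mx - trim_fraction * rg)
}

#' Saturating linear contrast stretch (histogram expansion / LUT compression)
#'
#' Linearly maps the trimmed intensity window `[nmin, nmax]` (see
#' [expansion_bounds()]) onto the full bit-depth range, clipping values below
#' `nmin` to 0 and above `nmax` to the range maximum, then rounds back to the
#' integer grid. The mapping is monotone non-decreasing in input intensity.
#' A constant slice is returned unchanged with a warning.
#'
#' @inheritParams expansion_bounds
#' @param bit_depth Output bit depth (8 or 16).
#' @return Integer-valued matrix in `[0, 2^bit_depth - 1]`.
#' @export
expand_histogram <- function(img, trim_fraction = 0.10, bit_depth = 8L,
                             mask = NULL) {
  stopifnot(is.matrix(img), trim_fraction >= 0, trim_fraction < 0.5)
  b <- expansion_bounds(img, trim_fraction, mask)
  if (b$range == 0) {
    warning("constant slice: histogram expansion skipped")
    return(img)
  }
  top <- 2^bit_depth - 1
  out <- round((img - b$nmin) / (b$nmax - b$nmin) * top)
  out <- pmin(pmax(out, 0), top)
  out
}

#' Otsu threshold of an integer-valued slice
#'
#' Selects the integer threshold `t` maximizing the between-class variance of
#' the intensity histogram, i.e. the separability of background (`<= t`) and
#' foreground (`> t`). Ties resolve to the lowest such `t`. The returned mask
#' is `TRUE` strictly above the threshold; with a `mask` argument the
#' histogram is computed over — and the output restricted to — those pixels.
#'
#' @param img Matrix of non-negative integer intensities.
#' @param mask Optional logical matrix (e.g. an ROI).
#' @return List with `threshold` (integer) and `mask` (logical matrix).
#' @export
otsu_threshold <- function(img, mask = NULL) {
  stopifnot(is.matrix(img))
  v <- as.vector(if (is.null(mask)) img else img[mask])
  if (length(v) == 0L) stop("no pixels to threshold")
  if (any(v < 0) || any(v != round(v))) {
    stop("otsu_threshold() expects non-negative integer intensities")
  }
  if (min(v) == max(v)) {
    stop("constant image: no separable intensity classes")
  }
  nbins <- as.integer(max(v)) + 1L
  counts <- tabulate(as.integer(v) + 1L, nbins = nbins)
  p <- counts / length(v)
  lev <- 0:(nbins - 1L)
  w <- cumsum(p)
  m <- cumsum(p * lev)
  mt <- m[nbins]
  # candidate thresholds t = 0 .. max-1 (class split: <= t vs > t)
  w0 <- w[seq_len(nbins - 1L)]
  m0 <- m[seq_len(nbins - 1L)]
  sb <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  t <- which.max(sb) - 1L
  out <- img > t
  if (!is.null(mask)) out <- out & mask
  list(threshold = t, mask = out)
}

#' Remove small foreground specks from a binary mask
#'
#' Deletes every 8-connected foreground component whose physical area is at
#' or below `min_area_um2`; all larger components pass through unchanged.
#' With the defaults (0.043 um^2 at 0.21 um/px) exactly the single-pixel
#' noise specks are removed. Idempotent; never adds foreground.
#'
#' @param mask Logical matrix.
#' @param cal An [nmj_calibration()].
#' @param min_area_um2 Area floor in um^2.
#' @return Logical matrix.
#' @export
despeckle <- function(mask, cal, min_area_um2 = 0.043) {
  stopifnot(is.matrix(mask), is.logical(mask), inherits(cal, "nmj_calibration"))
  lab <- label_components(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- pixels_to_area_um2(sizes, cal) > min_area_um2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  fg <- lab > 0L
  out[fg] <- keep[lab[fg]]
  out
}
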