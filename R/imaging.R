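#' Convert an image to the 8-bit range
#'
#' Min-max scales intensities to `[0, 255]`. A constant image maps to 0.
#'
#' @param image Numeric matrix.
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
to_8bit <- function(image) {
  rng <- range(image)
  if (rng[2] == rng[1]) return(matrix(0, nrow(image), ncol(image)))
  (image - rng[1]) / (rng[2] - rng[1]) * 255
}

# Grayscale dilation/erosion with a non-flat ball (sphere-cap) structuring
# element. Out-of-image support is ignored (equivalent to -Inf/+Inf padding).
ball_offsets <- function(radius) {
  d <- -floor(radius):floor(radius)
  g <- expand.grid(di = d, dj = d)
  g <- g[g$di^2 + g$dj^2 <= radius^2, ]
  g$h <- sqrt(radius^2 - g$di^2 - g$dj^2) - radius  # cap height, <= 0, 0 at center
  g
}

gray_morph <- function(image, offsets, op = c("dilate", "erode")) {
  op <- match.arg(op)
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(if (op == "dilate") -Inf else Inf, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    di <- offsets$di[k]; dj <- offsets$dj[k]; h <- offsets$h[k]
    dst_r <- max(1L, 1L + di):min(nr, nr + di)
    dst_c <- max(1L, 1L + dj):min(nc, nc + dj)
    src_r <- dst_r - di
    src_c <- dst_c - dj
    if (op == "dilate") {
      out[dst_r, dst_c] <- pmax(out[dst_r, dst_c], image[src_r, src_c] + h)
    } else {
      out[dst_r, dst_c] <- pmin(out[dst_r, dst_c], image[src_r, src_c] - h)
    }
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background by grayscale morphology with a ball
#' (sphere-cap) structuring element of the given radius, then subtracts it
#' so foreground deviations sit on a flat field. With a light background
#' (dark objects) the background is the morphological closing and the
#' output is `background - image`; with a dark background (bright objects)
#' the background is the opening and the output is `image - background`.
#' Either way the output is non-negative, a constant image maps to a flat
#' zero field, and objects narrower than the ball are preserved while
#' slow illumination trends are removed.
#'
#' @param image Numeric matrix.
#' @param radius Ball radius in pixels (>= 1).
#' @param light_background Logical; `TRUE` for brightfield-style images.
#' @return Numeric matrix of background-subtracted deviations.
#' @export
rolling_ball_subtract <- function(image, radius = 6, light_background = TRUE) {
  assert_number(radius, "radius")
  if (radius < 1) stop_chemotax("`radius` must be >= 1 px")
  if (radius >= min(dim(image))) {
    stop_chemotax("ball radius %g px must be smaller than the image (%d x %d)",
                  radius, nrow(image), ncol(image))
  }
  offs <- ball_offsets(radius)
  if (light_background) {
    background <- gray_morph(gray_morph(image, offs, "dilate"), offs, "erode")
    pmax(background - image, 0)
  } else {
    background <- gray_morph(gray_morph(image, offs, "erode"), offs, "dilate")
    pmax(image - background, 0)
  }
}

#' Percentile contrast enhancement
#'
#' Saturates a fixed fraction of the darkest and brightest pixels and
#' linearly rescales the rest to the full output range, the standard
#' "enhance contrast, normalize" step. With saturation `s` (percent), the
#' `k = ceiling(n * s / 200)` most extreme pixels at each end map to the
#' range limits; rank order of all other pixels is preserved.
#'
#' @param image Numeric matrix.
#' @param saturation Percent of pixels saturated in total (half at each
#'   end), in `[0, 100)`. Default 0.35.
#' @param normalize Rescale to `[0, max_value]` (default `TRUE`; `FALSE`
#'   clips without rescaling).
#' @param max_value Output full-scale value (default 255).
#' @return Numeric matrix.
#' @export
enhance_contrast <- function(image, saturation = 0.35, normalize = TRUE,
                             max_value = 255) {
  assert_number(saturation, "saturation", non_negative = TRUE)
  if (saturation >= 100) stop_chemotax("`saturation` must be < 100%%")
  v <- as.vector(image)
  if (min(v) == max(v)) {
    warn_chemotax("constant image: contrast stretch is undefined, returning input unchanged")
    return(image)
  }
  n <- length(v)
  k <- ceiling(n * saturation / 200)
  sv <- sort(v)
  lo <- if (k >= 1) sv[k] else sv[1]
  hi <- if (k >= 1) sv[n - k + 1L] else sv[n]
  if (hi <= lo) {  # degenerate: too many ties, fall back to full range
    lo <- sv[1]; hi <- sv[n]
  }
  out <- clamp(image, lo, hi)
  if (normalize) out <- (out - lo) / (hi - lo) * max_value
  out
}

#' Yen automatic threshold
#'
#' Returns the gray level maximizing Yen's maximum-correlation criterion
#' over the normalized 256-bin histogram. Writing `P(t)` for the cumulative
#' class probability and `P2(t)`, `P2'(t)` for the cumulative sums of
#' squared bin probabilities below and above `t`, the criterion is
#'
#'   C(t) = -log(P2(t) * P2'(t)) + 2 log(P(t) * (1 - P(t)))
#'
#' and the threshold is the lowest level attaining the maximum (ties broken
#' low, so the result is deterministic). Foreground is conventionally the
#' set of pixels strictly above the returned threshold.
#'
#' Images with values in `[0, 1]` (probability maps) are quantized to 256
#' levels and the threshold is returned on the input scale; other images
#' are treated as 8-bit gray levels.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @return The threshold, a single number on the input intensity scale.
#' @export
yen_threshold <- function(image) {
  v <- as.vector(image)
  if (length(unique(v)) < 2L) {
    stop_chemotax("constant image: no threshold exists")
  }
  prob_scale <- max(v) <= 1 && min(v) >= 0
  lev <- if (prob_scale) round(v * 255) else clamp(round(v), 0, 255)
  counts <- tabulate(lev + 1L, nbins = 256L)
  p <- counts / sum(counts)
  P <- cumsum(p)
  P2 <- cumsum(p^2)
  P2t <- sum(p^2) - P2
  crit <- rep(-Inf, 256L)
  valid <- P > 0 & P < 1 & P2 > 0 & P2t > 0
  crit[valid] <- -log(P2[valid] * P2t[valid]) +
    2 * log(P[valid] * (1 - P[valid]))
  t_level <- which.max(crit) - 1L  # which.max returns the first (lowest) max
  if (prob_scale) t_level / 255 else as.double(t_level)
}

#' Fixed-threshold binarization
#'
#' A pixel is foreground when its value is greater than or equal to the
#' threshold (the `>=` convention is fixed so masks reproduce bit-exactly).
#'
#' @param prob_map Numeric matrix (typically a probability map in
#'   `[0, 1]`).
#' @param threshold Threshold in `[0, 1]` for probability maps (default
#'   0.5, foreground = 1, background = 0).
#' @return Logical matrix.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  assert_number(threshold, "threshold")
  prob_map >= threshold
}
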