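#' Generate a synthetic confluency image with known coverage
#'
#' Builds a brightfield-like image of a cell monolayer with an exact
#' ground-truth coverage mask. Randomly oriented ellipses ("cells") are
#' accumulated until the union covers the target area fraction to within
#' 0.5 percentage points; the image then renders cells as darker, textured
#' regions on a smoothly shaded light background with mild sensor noise.
#' Cell interiors carry speckle texture (intracellular granularity), which
#' is the cue that survives rolling-ball background subtraction and drives
#' the pixel classifier.
#'
#' `target_fraction = 0` returns a blank background; `target_fraction = 1`
#' is the special confluent-sheet case (every pixel is cell texture).
#'
#' @param shape Integer `(rows, cols)`; default `c(1495, 1496)`, the assay
#'   camera format.
#' @param target_fraction Desired covered area fraction in `[0, 1]`.
#' @param cell_radius_range Ellipse semi-axis range in pixels. The default
#'   `c(15, 35)` follows the assay geometry: the camera frames one well of
#'   about 1.6 mm across 1496 px (about 1.1 um/px), so spread stromal
#'   cells of 40-100 um map to semi-axes of roughly 15-35 px.
#' @param seed Seed; identical seeds give identical outputs.
#' @param max_cells Safety cap on placed ellipses; if the target cannot be
#'   reached the generator errors and reports the achieved maximum.
#' @return A list: `image` (numeric matrix, 8-bit range) and `truth_mask`
#'   (logical matrix) with `attr(truth_mask, "fraction")` the exact covered
#'   fraction.
#' @export
generate_confluency_image <- function(shape = c(1495, 1496),
                                      target_fraction, cell_radius_range = c(15, 35),
                                      seed = 1, max_cells = 2e5) {
  assert_number(target_fraction, "target_fraction", non_negative = TRUE)
  if (target_fraction > 1) stop_chemotax("`target_fraction` must be in [0, 1]")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  n_px <- as.double(nr) * nc
  withr::with_seed(seed, {
    mask <- matrix(FALSE, nr, nc)
    if (target_fraction >= 1) {
      mask[] <- TRUE
    } else if (target_fraction > 0) {
      covered <- 0
      placed <- 0L
      tol <- 0.005
      while (covered / n_px < target_fraction - tol) {
        if (placed >= max_cells) {
          stop_chemotax("target fraction %g unreachable within %d cells; achieved %.3f",
                        target_fraction, max_cells, covered / n_px)
        }
        a <- stats::runif(1, cell_radius_range[1], cell_radius_range[2])
        b <- stats::runif(1, cell_radius_range[1], cell_radius_range[2])
        phi <- stats::runif(1, 0, pi)
        cx <- stats::runif(1, 1, nc); cy <- stats::runif(1, 1, nr)
        rmax <- max(a, b)
        i0 <- max(1L, floor(cy - rmax)); i1 <- min(nr, ceiling(cy + rmax))
        j0 <- max(1L, floor(cx - rmax)); j1 <- min(nc, ceiling(cx + rmax))
        if (i0 > i1 || j0 > j1) next
        ii <- i0:i1; jj <- j0:j1
        dy <- ii - 0.5 - cy
        dx <- jj - 0.5 - cx
        u <- outer(dy, dx, function(y, x) (x * cos(phi) + y * sin(phi))^2 / a^2 +
                     (-x * sin(phi) + y * cos(phi))^2 / b^2)
        inside <- u <= 1
        new_px <- sum(inside & !mask[ii, jj])
        mask[ii, jj] <- mask[ii, jj] | inside
        covered <- covered + new_px
        placed <- placed + 1L
      }
    }
    # rendering: shaded light background, darker textured cells. The cell
    # speckle (intracellular granularity) is spatially correlated, unlike
    # the white sensor noise; that scale difference is the cue a pixel
    # classifier retains even after per-image contrast normalization.
    xg <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
    yg <- matrix(seq(-1, 1, length.out = nr), nr, nc)
    shading <- 8 * xg + 5 * yg - 6 * (xg^2 + yg^2)  # slow illumination trend
    img <- 205 + shading + stats::rnorm(n_px, sd = 2)
    if (any(mask)) {
      texture <- blur_matrix(matrix(stats::rnorm(n_px), nr, nc), 1.2)
      texture <- texture / stats::sd(texture) * 12
      img[mask] <- 150 + shading[mask] + texture[mask]
    }
    img <- clamp(img, 0, 255)
    attr(mask, "fraction") <- sum(mask) / n_px
    list(image = img, truth_mask = mask)
  })
}
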