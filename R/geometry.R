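#' Build a four-well chemotaxis chamber layout
#'
#' Places one central well (for tumor cells) and three outer wells (for
#' stromal cells) at the vertices of an equilateral triangle centered on the
#' central well, so the three outer wells are equidistant from the center.
#' The spacing argument follows the edge-to-edge convention: the clear gel
#' gap between the rim of the central well and the rim of each outer well.
#' Center-to-center distance is therefore `spacing_um + well_diameter_um`.
#'
#' The image coordinate frame is row-major with the origin at the top-left
#' corner and y increasing downward. With `orientation_deg = 0` the first
#' outer well lies due north (up) of the center; the angle rotates all three
#' outer wells clockwise so real acquisitions can be registered.
#'
#' @param well_diameter_um Well diameter in micrometers. The fabricated
#'   chamber measures 1630 um; the design target was 1200 um. Both are valid
#'   presets.
#' @param spacing_um Edge-to-edge gel gap between the central and each outer
#'   well, in micrometers (default 1460).
#' @param chamber_extent_um Numeric length-2 vector, chamber width and height
#'   in micrometers.
#' @param pixel_size_um Physical size of one pixel in micrometers, used when
#'   converting the layout to raster masks.
#' @param orientation_deg Clockwise rotation of the outer-well triangle, in
#'   degrees.
#'
#' @return An object of class `chamber_layout`: a list with the central well
#'   position, the 3 x 2 matrix of outer-well positions (um, x then y), the
#'   well radius, spacing, chamber extent, pixel size and orientation.
#'
#' @examples
#' layout <- chamber_layout()
#' layout
#' @export
chamber_layout <- function(well_diameter_um = 1630,
                           spacing_um = 1460,
                           chamber_extent_um = c(10650, 9400),
                           pixel_size_um = 10,
                           orientation_deg = 0) {
  assert_number(well_diameter_um, "well_diameter_um", positive = TRUE)
  assert_number(spacing_um, "spacing_um")
  assert_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  assert_number(orientation_deg, "orientation_deg")
  if (!is.numeric(chamber_extent_um) || length(chamber_extent_um) != 2L ||
      any(chamber_extent_um <= 0)) {
    stop_chemotax("`chamber_extent_um` must be two positive lengths (width, height)")
  }
  if (spacing_um <= 0) {
    stop_chemotax(
      "geometry infeasible: edge-to-edge spacing %g um means wells touch or overlap",
      spacing_um
    )
  }
  r <- well_diameter_um / 2
  d_cc <- spacing_um + well_diameter_um  # center-to-center distance
  center <- chamber_extent_um / 2
  ang <- (orientation_deg + c(0, 120, 240)) * pi / 180
  # clockwise bearing from north in (x right, y down) coordinates
  outer <- cbind(
    x = center[1] + d_cc * sin(ang),
    y = center[2] - d_cc * cos(ang)
  )
  all_centers <- rbind(center, outer)
  rownames(all_centers) <- c("center", "outer1", "outer2", "outer3")
  for (k in seq_len(nrow(all_centers))) {
    p <- all_centers[k, ]
    if (any(p - r < 0) || p[1] + r > chamber_extent_um[1] ||
        p[2] + r > chamber_extent_um[2]) {
      stop_chemotax(
        "geometry infeasible: well `%s` (radius %g um) exceeds the chamber extent %g x %g um",
        rownames(all_centers)[k], r, chamber_extent_um[1], chamber_extent_um[2]
      )
    }
  }
  dd <- as.matrix(stats::dist(all_centers))
  if (any(dd[upper.tri(dd)] <= 2 * r + 1e-9)) {
    stop_chemotax("geometry infeasible: well disks touch or overlap (min center distance %g um <= diameter %g um)",
                  min(dd[upper.tri(dd)]), 2 * r)
  }
  structure(
    list(
      center_well_um = unname(center),
      outer_wells_um = unname(outer),
      well_radius_um = r,
      spacing_um = spacing_um,
      chamber_extent_um = unname(chamber_extent_um),
      pixel_size_um = pixel_size_um,
      orientation_deg = orientation_deg
    ),
    class = "chamber_layout"
  )
}

#' @export
print.chamber_layout <- function(x, ...) {
  cat("<chamber_layout>\n")
  cat(sprintf("  chamber extent: %g x %g um (pixel size %g um)\n",
              x$chamber_extent_um[1], x$chamber_extent_um[2], x$pixel_size_um))
  cat(sprintf("  well radius: %g um; edge-to-edge spacing: %g um\n",
              x$well_radius_um, x$spacing_um))
  cat(sprintf("  center well at (%g, %g) um; 3 outer wells at %g um center-to-center\n",
              x$center_well_um[1], x$center_well_um[2],
              x$spacing_um + 2 * x$well_radius_um))
  invisible(x)
}

#' Tidy a chamber layout into a tibble of wells
#'
#' @param x A `chamber_layout`.
#' @param ... Unused.
#' @return A tibble with one row per well: `well`, `x_um`, `y_um`,
#'   `radius_um`.
#' @export
tidy.chamber_layout <- function(x, ...) {
  tibble(
    well = c("center", "outer1", "outer2", "outer3"),
    x_um = c(x$center_well_um[1], x$outer_wells_um[, 1]),
    y_um = c(x$center_well_um[2], x$outer_wells_um[, 2]),
    radius_um = x$well_radius_um
  )
}

well_position_um <- function(layout, well) {
  wells <- tidy(layout)
  row <- wells[wells$well == well, ]
  if (nrow(row) != 1L) {
    stop_chemotax("unknown well id `%s` (use one of %s)", well,
                  paste(wells$well, collapse = ", "))
  }
  c(row$x_um, row$y_um)
}

#' Rasterize one well as a binary mask
#'
#' A pixel belongs to the mask when its center lies inside the well disk
#' (pixel-center membership, for determinism).
#'
#' @param layout A [chamber_layout()].
#' @param image_shape Integer length-2: raster rows and columns.
#' @param well Well id: `"center"`, `"outer1"`, `"outer2"` or `"outer3"`.
#' @return A logical matrix of dimension `image_shape`.
#' @export
well_mask <- function(layout, image_shape, well = "center") {
  stopifnot(inherits(layout, "chamber_layout"))
  pos <- well_position_um(layout, well)
  ps <- layout$pixel_size_um
  r <- layout$well_radius_um
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  if (pos[1] - r < 0 || pos[2] - r < 0 ||
      pos[1] + r > nc * ps || pos[2] + r > nr * ps) {
    stop_chemotax("well `%s` does not fit inside a %d x %d raster at %g um/px",
                  well, nr, nc, ps)
  }
  cx <- pixel_center(seq_len(nc), ps)
  cy <- pixel_center(seq_len(nr), ps)
  dx2 <- outer(rep(1, nr), (cx - pos[1])^2)
  dy2 <- outer((cy - pos[2])^2, rep(1, nc))
  dx2 + dy2 <= r^2
}

#' Intercardinal quadrant masks with a central exclusion disk
#'
#' Splits a square crop into NW, NE, SW and SE quadrants and removes a
#' central disk (the well body plus margin) so only migrating cells are
#' counted. The four quadrant masks plus the excluded disk partition the crop
#' exactly: every pixel belongs to exactly one of the five masks.
#'
#' Pixels are assigned to quadrants by half-open intervals on their center
#' coordinates (north/west take coordinates strictly below the midline), and
#' to the exclusion disk by pixel-center distance `<=` the exclusion radius.
#'
#' @param side Side of the square crop in pixels.
#' @param exclusion_radius_px Radius of the central excluded disk in pixels;
#'   must be smaller than `side / 2`.
#' @return A named list of logical `side x side` matrices: `NW`, `NE`, `SW`,
#'   `SE`, `excluded`.
#' @export
quadrant_masks <- function(side, exclusion_radius_px) {
  side <- as.integer(side)
  if (length(side) != 1L || side < 2L) stop_chemotax("`side` must be a single integer >= 2")
  assert_number(exclusion_radius_px, "exclusion_radius_px", non_negative = TRUE)
  if (exclusion_radius_px >= side / 2) {
    stop_chemotax("exclusion radius %g px must be < half the crop side (%g px)",
                  exclusion_radius_px, side / 2)
  }
  ctr <- side / 2
  cc <- seq_len(side) - 0.5           # pixel-center coordinates
  north <- matrix(cc < ctr, side, side)        # rows above midline
  west <- matrix(cc < ctr, side, side, byrow = TRUE)
  d2 <- outer((cc - ctr)^2, (cc - ctr)^2, "+")
  excluded <- d2 <= exclusion_radius_px^2
  list(
    NW = north & west & !excluded,
    NE = north & !west & !excluded,
    SW = !north & west & !excluded,
    SE = !north & !west & !excluded,
    excluded = excluded
  )
}

#' Export binary masks as an 8-bit TIFF
#'
#' @param mask Logical matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}
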