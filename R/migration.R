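#' Crop a frame to a square centered on a well
#'
#' Produces the 1:1 crop used for quadrant analysis. The crop center is the
#' pixel containing the well center; for odd sides the well center maps to
#' the central pixel of the crop, for even sides to the pixel just
#' down-right of the crop midpoint.
#'
#' @param frame Numeric (or logical) matrix.
#' @param layout A [chamber_layout()], used to locate the well (its
#'   `pixel_size_um` must match the frame).
#' @param well Well id.
#' @param side Crop side in pixels.
#' @param center_px Optional `(row, col)` override of the well-center pixel
#'   (used when cropping an already-cropped raster).
#' @return A `side x side` matrix with attribute `center_px`, the position
#'   of the well center within the crop.
#' @export
crop_to_well <- function(frame, layout = NULL, well = "center", side,
                         center_px = NULL) {
  side <- as.integer(side)
  if (is.null(center_px)) {
    stopifnot(inherits(layout, "chamber_layout"))
    pos <- well_position_um(layout, well)
    ps <- layout$pixel_size_um
    center_px <- c(pixel_index(pos[2], ps), pixel_index(pos[1], ps))
  }
  half_lo <- (side - 1L) %/% 2L
  r0 <- center_px[1] - half_lo
  c0 <- center_px[2] - half_lo
  if (r0 < 1L || c0 < 1L || r0 + side - 1L > nrow(frame) ||
      c0 + side - 1L > ncol(frame)) {
    stop_chemotax("a %d px crop centered at pixel (%d, %d) exceeds the %d x %d frame",
                  side, center_px[1], center_px[2], nrow(frame), ncol(frame))
  }
  out <- frame[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
  attr(out, "center_px") <- c(half_lo + 1L, half_lo + 1L)
  out
}

#' Per-quadrant migrating-cell area of a binary mask
#'
#' Applies [quadrant_masks()] to a square binary mask: the central disk
#' (the seeded well body plus margin) is excluded, the rest is split into
#' NW/NE/SW/SE, and each quadrant's area fraction is the number of
#' foreground pixels in that quadrant divided by the total analyzable
#' (non-excluded) pixel count. All four fractions share the same
#' denominator, so they sum exactly to the total fraction and the
#' exclusion-radius choice does not rescale comparisons between wells.
#'
#' @param mask Logical square matrix (segmented cells).
#' @param exclusion_radius_px Radius of the central excluded disk (px).
#' @param frame_index,time_s Bookkeeping columns carried into the result.
#' @return A one-row tibble of class `quadrant_areas`: `frame_index`,
#'   `time_s`, `nw`, `ne`, `sw`, `se`, `total_fraction`, `analyzable_px`;
#'   attribute `quadrant_analyzable_px` holds the per-quadrant analyzable
#'   pixel counts.
#' @export
quadrant_migration_areas <- function(mask, exclusion_radius_px,
                                     frame_index = NA_integer_,
                                     time_s = NA_real_) {
  if (nrow(mask) != ncol(mask)) {
    stop_chemotax("quadrant analysis requires a square (1:1) mask, got %d x %d",
                  nrow(mask), ncol(mask))
  }
  qm <- quadrant_masks(nrow(mask), exclusion_radius_px)
  analyzable_q <- vapply(qm[c("NW", "NE", "SW", "SE")], sum, numeric(1))
  analyzable <- sum(analyzable_q)
  fg <- vapply(qm[c("NW", "NE", "SW", "SE")],
               function(q) sum(mask & q), numeric(1))
  out <- tibble(
    frame_index = frame_index, time_s = time_s,
    nw = fg[["NW"]] / analyzable, ne = fg[["NE"]] / analyzable,
    sw = fg[["SW"]] / analyzable, se = fg[["SE"]] / analyzable,
    total_fraction = sum(fg) / analyzable,
    analyzable_px = analyzable
  )
  attr(out, "quadrant_analyzable_px") <- analyzable_q
  class(out) <- c("quadrant_areas", class(out))
  out
}

# Estimate the radius of the segmented well body at frame 0 by scanning the
# radial occupancy profile outward and keeping the largest radius whose
# 2 px annulus is at least half foreground.
estimate_body_radius_px <- function(mask, margin = 1.05) {
  side <- nrow(mask)
  ctr <- side / 2
  cc <- seq_len(side) - 0.5
  d <- sqrt(outer((cc - ctr)^2, (cc - ctr)^2, "+"))
  max_r <- floor(side / 2) - 1L
  occ <- vapply(seq_len(max_r), function(r) {
    ring <- d >= (r - 1) & d < (r + 1)
    mean(mask[ring])
  }, numeric(1))
  filled <- which(occ >= 0.5)
  if (length(filled) == 0L) return(0)
  margin * max(filled)
}

#' Quantify migration through time around one well
#'
#' Runs the per-frame quantification chain: square crop centered on the
#' well, pixel-classifier probability map, fixed-threshold binarization at
#' 0.5, central-region exclusion, per-quadrant area fractions.
#'
#' The default exclusion radius is the segmented well-body radius at the
#' first frame times 1.05 (so the seeded cell body never counts as
#' migration); pass `exclusion_radius_px` to fix it explicitly. If the
#' first frame contains no segmentable body, the layout's well radius is
#' used as fallback.
#'
#' @param stack An [image_stack()].
#' @param layout A [chamber_layout()].
#' @param well Well id the series belongs to.
#' @param classifier A trained [train_pixel_classifier()] model.
#' @param side Crop side (px).
#' @param exclusion_radius_px Optional fixed exclusion radius (px).
#' @param threshold Probability threshold (default 0.5).
#' @param condition Condition label (e.g. `"with-tumor"` or `"control"`).
#' @param facing Optional character subset of
#'   `c("nw", "ne", "sw", "se")`: the quadrants facing the attractant well.
#'   When given, a directional bias index is computed per frame.
#' @return An object of class `migration_result`: list with `series` (a
#'   tibble of per-frame [quadrant_migration_areas()] rows plus
#'   `bias_index` when `facing` is given), `condition`, `well`, `facing`,
#'   `exclusion_radius_px`, `side`.
#' @export
migration_time_series <- function(stack, layout, well, classifier, side,
                                  exclusion_radius_px = NULL, threshold = 0.5,
                                  condition = "condition", facing = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  masks <- lapply(stack$frames, function(fr) {
    crop <- crop_to_well(fr, layout, well, side)
    binarize(pixel_probability_map(crop, classifier), threshold)
  })
  if (is.null(exclusion_radius_px)) {
    est <- estimate_body_radius_px(masks[[1]])
    exclusion_radius_px <- if (est > 0) est else
      1.05 * layout$well_radius_um / stack$pixel_size_um
    exclusion_radius_px <- min(exclusion_radius_px, side / 2 - 1)
  }
  series <- bind_rows(lapply(seq_along(masks), function(i) {
    quadrant_migration_areas(masks[[i]], exclusion_radius_px,
                             frame_index = i, time_s = stack$timestamps_s[i])
  }))
  if (!is.null(facing)) {
    series$bias_index <- vapply(seq_len(nrow(series)), function(i) {
      directional_bias_index(series[i, ], facing)
    }, numeric(1))
  }
  structure(
    list(series = series, condition = condition, well = well,
         facing = facing, exclusion_radius_px = exclusion_radius_px,
         side = side),
    class = "migration_result"
  )
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf("<migration_result> well `%s` (%s): %d frame(s), exclusion radius %.1f px\n",
              x$well, x$condition, nrow(x$series), x$exclusion_radius_px))
  last <- x$series[nrow(x$series), ]
  cat(sprintf("  terminal fractions NW %.3f | NE %.3f | SW %.3f | SE %.3f (total %.3f)\n",
              last$nw, last$ne, last$sw, last$se, last$total_fraction))
  invisible(x)
}

#' Directional bias index of a quadrant-area row
#'
#' Measures how much of the migrated area lies in the quadrants facing the
#' attractant, relative to a direction-blind spread. With `p` the share of
#' migrated area in the facing quadrants and `e` the share of analyzable
#' area they cover (their expectation under uniform spread), the index is
#' `(p - e) / (1 - e)` when `p >= e` and `(p - e) / e` otherwise, so it is
#' 0 for uniform spread, +1 when all migrated area faces the attractant
#' and -1 when none does.
#'
#' @param areas A one-row [quadrant_migration_areas()] tibble.
#' @param facing Character subset of `c("nw", "ne", "sw", "se")`, proper
#'   and non-empty.
#' @return A number in `[-1, 1]`, or `NA` (with attribute
#'   `reason = "no migrated area"`) when the total fraction is 0.
#' @export
directional_bias_index <- function(areas, facing) {
  if (length(facing) == 0L || length(facing) >= 4L) {
    stop_chemotax("`facing` must be a non-empty proper subset of the four quadrants")
  }
  facing <- match.arg(tolower(facing), c("nw", "ne", "sw", "se"),
                      several.ok = TRUE)
  total <- areas$total_fraction
  if (is.na(total) || total <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "no migrated area"
    return(out)
  }
  aq <- attr(areas, "quadrant_analyzable_px")
  e <- if (!is.null(aq)) {
    sum(aq[toupper(facing)]) / sum(aq)
  } else {
    length(facing) / 4
  }
  p <- sum(unlist(areas[1, facing])) / total
  if (p >= e) (p - e) / (1 - e) else (p - e) / e
}

#' Quadrants facing the central well from an outer well
#'
#' Registers the quadrant template against the chamber geometry: given the
#' bearing from an outer well toward the attractant (central) well, returns
#' the two intercardinal quadrants whose bisectors are nearest that
#' bearing. The template must not hard-code one pair, because migration
#' shifts can appear in different quadrant pairs depending on the well.
#'
#' @param layout A [chamber_layout()].
#' @param well Outer well id.
#' @return Character vector of two quadrant names (lowercase).
#' @export
facing_quadrants <- function(layout, well) {
  pos <- well_position_um(layout, well)
  ctr <- layout$center_well_um
  v <- ctr - pos
  bearing <- atan2(v[2], v[1])  # y grows downward
  bisectors <- c(nw = atan2(-1, -1), ne = atan2(-1, 1),
                 sw = atan2(1, -1), se = atan2(1, 1))
  ang_dist <- abs(atan2(sin(bisectors - bearing), cos(bisectors - bearing)))
  names(sort(ang_dist))[1:2]
}

#' Permutation test for a difference in directional bias
#'
#' Two-sided label-permutation test for the difference in mean terminal
#' bias index between two arms (e.g. wells facing a tumor-seeded center
#' versus control wells). When the number of distinct group relabelings is
#' at most `max_exact` the null distribution is enumerated exactly;
#' otherwise it is sampled with `n_perm` seeded draws and the p-value uses
#' the add-one correction.
#'
#' @param bias_a,bias_b Numeric vectors of terminal bias indices (one per
#'   replicate well), or lists of `migration_result`s whose series carry a
#'   `bias_index` column (the terminal value is used).
#' @param n_perm Monte-Carlo permutations (default 1999); values below 100
#'   trigger a warning.
#' @param seed Seed for the Monte-Carlo branch.
#' @param max_exact Enumeration cutoff (default 1e4 arrangements).
#' @return A one-row tibble: `statistic` (mean difference), `p_value`,
#'   `n_a`, `n_b`, `method` (`"exact"` or `"monte-carlo"`),
#'   `n_arrangements`.
#' @export
permutation_test_bias <- function(bias_a, bias_b, n_perm = 1999, seed = 1,
                                  max_exact = 1e4) {
  terminal_bias <- function(x) {
    if (inherits(x, "migration_result")) x <- list(x)
    if (is.list(x)) {
      vapply(x, function(r) {
        stopifnot(inherits(r, "migration_result"))
        if (!"bias_index" %in% names(r$series)) {
          stop_chemotax("migration_result has no bias_index; rerun with `facing` set")
        }
        tail(r$series$bias_index, 1)
      }, numeric(1))
    } else {
      as.double(x)
    }
  }
  a <- terminal_bias(bias_a); b <- terminal_bias(bias_b)
  if (anyNA(a) || anyNA(b)) stop_chemotax("bias indices contain NA (wells without migrated area)")
  if (n_perm < 100) warn_chemotax("n_perm = %d is small; p-value resolution is coarse", n_perm)
  pooled <- c(a, b)
  na <- length(a); nb <- length(b); n <- na + nb
  obs <- mean(a) - mean(b)
  stat_for <- function(ia) mean(pooled[ia]) - mean(pooled[-ia])
  n_arr <- choose(n, na)
  eps <- 1e-12
  if (n_arr <= max_exact) {
    stats_all <- combn(n, na, stat_for)
    p <- mean(abs(stats_all) >= abs(obs) - eps)
    method <- "exact"
  } else {
    stats_all <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_for(sample.int(n, na)), numeric(1))
    })
    p <- (1 + sum(abs(stats_all) >= abs(obs) - eps)) / (n_perm + 1)
    method <- "monte-carlo"
  }
  tibble(statistic = obs, p_value = p, n_a = na, n_b = nb,
         method = method, n_arrangements = n_arr)
}

#' Confluency of a brightfield image
#'
#' The full confluency measurement chain: 8-bit conversion, rolling-ball
#' background subtraction (radius 6 px, light background), percentile
#' contrast enhancement (0.35% saturation, normalized), pixel-classifier
#' probability map, Yen automatic threshold on the probability map, and the
#' foreground area fraction relative to the whole image.
#'
#' A probability map with a single quantized level cannot be Yen
#' thresholded; it is treated as all-background (fraction 0) when below
#' 0.5 and all-foreground (fraction 1) otherwise.
#'
#' @param image Numeric matrix (brightfield frame).
#' @param classifier A trained [train_pixel_classifier()] model.
#' @param rolling_ball_radius Background ball radius (px), default 6.
#' @param saturation Contrast saturation (percent), default 0.35.
#' @return Fraction of the image covered by cells, in `[0, 1]`.
#' @export
confluency <- function(image, classifier, rolling_ball_radius = 6,
                       saturation = 0.35) {
  img <- to_8bit(image)
  img <- rolling_ball_subtract(img, rolling_ball_radius, light_background = TRUE)
  img <- enhance_contrast(img, saturation = saturation, normalize = TRUE)
  prob <- pixel_probability_map(img, classifier)
  lev <- round(prob * 255)
  if (length(unique(as.vector(lev))) < 2L) {
    return(if (lev[1] / 255 >= 0.5) 1 else 0)
  }
  thr <- yen_threshold(prob)
  # foreground is strictly above the threshold, compared on the same
  # 8-bit quantization the threshold was computed on
  mean(lev > round(thr * 255))
}

#' Terminal per-quadrant areas in spider-chart form
#'
#' Flattens one or more migration results to the long table behind a spider
#' (radar) chart: one row per condition, well and quadrant holding the
#' terminal-frame area fraction.
#'
#' @param results A `migration_result` or list of them.
#' @param path Optional CSV output path.
#' @return A tibble with columns `condition`, `well`, `quadrant`,
#'   `area_fraction`.
#' @export
spider_chart_export <- function(results, path = NULL) {
  if (inherits(results, "migration_result")) results <- list(results)
  out <- bind_rows(lapply(results, function(r) {
    last <- r$series[nrow(r$series), ]
    tibble(condition = r$condition, well = r$well,
           quadrant = c("NW", "NE", "SW", "SE"),
           area_fraction = c(last$nw, last$ne, last$sw, last$se))
  }))
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
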