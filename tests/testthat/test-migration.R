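test_that("well-centered crops are exact, maximal, and idempotent", {
  layout <- chamber_layout(well_diameter_um = 200, spacing_um = 150,
                           chamber_extent_um = c(1010, 1010), pixel_size_um = 10)
  frame <- matrix(seq_len(101 * 101), 101)
  crop <- crop_to_well(frame, layout, "center", side = 101)
  expect_identical(dim(crop), c(101L, 101L))
  expect_identical(attr(crop, "center_px"), c(51L, 51L))
  crop2 <- crop_to_well(crop, side = 101, center_px = attr(crop, "center_px"))
  expect_equal(unclass(crop2), unclass(crop), ignore_attr = TRUE)
  # odd side: the well center maps to the central crop pixel
  small <- crop_to_well(frame, layout, "center", side = 31)
  ctr_val <- frame[51, 51]
  expect_identical(small[16, 16], ctr_val)
  expect_error(crop_to_well(frame, layout, "center", side = 200), "exceeds")
})

test_that("quadrant areas partition foreground with a common denominator", {
  full <- matrix(TRUE, 64, 64)
  qa <- quadrant_migration_areas(full, 10)
  expect_equal(qa$nw, qa$ne); expect_equal(qa$sw, qa$se)
  expect_equal(qa$total_fraction, 1)
  expect_equal(qa$nw + qa$ne + qa$sw + qa$se, qa$total_fraction)

  empty <- matrix(FALSE, 64, 64)
  qa0 <- quadrant_migration_areas(empty, 10)
  expect_equal(qa0$total_fraction, 0)

  half <- matrix(FALSE, 64, 64); half[, 1:32] <- TRUE
  qh <- quadrant_migration_areas(half, 12)
  expect_equal(qh$nw + qh$sw, 0.5)
  expect_equal(qh$ne + qh$se, 0)

  expect_error(quadrant_migration_areas(matrix(TRUE, 10, 20), 2), "square")
})

test_that("every frame of a series conserves quadrant fractions", {
  set.seed(12)
  layout <- chamber_layout()
  clf <- get_migration_classifier()
  prof <- cell_type_profile("t", agent_params(n_agents = 25), "outer1",
                            rendered_radius_um = 40)
  traj <- simulate_migration(layout, prof, duration_s = 4 * 1800, seed = 5)
  pos <- c(tidy(layout)$x_um[2], tidy(layout)$y_um[2])
  rend <- render_migration_frames(traj, c(101, 101), 20,
                                  origin_um = pos - 101 / 2 * 20)
  for (i in seq_along(rend$truth_masks)) {
    qa <- quadrant_migration_areas(rend$truth_masks[[i]], 43)
    expect_equal(qa$nw + qa$ne + qa$sw + qa$se, qa$total_fraction,
                 tolerance = 1e-12)
  }
})

test_that("a time series localizes cells to the correct quadrant with <= 1% leakage", {
  layout <- chamber_layout(well_diameter_um = 400, spacing_um = 400,
                           chamber_extent_um = c(4040, 4040), pixel_size_um = 20)
  clf <- get_migration_classifier()
  # static cells placed only in the NE quadrant of the center crop,
  # outside the exclusion disk
  n <- 12
  pts <- withr::with_seed(8, tibble::tibble(
    cell_type = "ne", well = "center", agent = seq_len(n), step = 0L,
    t_s = 0, x_um = runif(n, 2020 + 500, 2020 + 1500),
    y_um = runif(n, 2020 - 1500, 2020 - 500)
  ))
  pts2 <- pts; pts2$t_s <- 1800; pts2$step <- 1L
  rend <- render_migration_frames(dplyr::bind_rows(pts, pts2), c(201, 201), 20,
                                  origin_um = c(2020, 2020) - 201 / 2 * 20,
                                  blob_radius_um = 40)
  stack <- rend$stack
  res <- migration_time_series(stack, layout, "center", clf, side = 201,
                               exclusion_radius_px = 21, facing = c("ne", "nw"))
  expect_equal(nrow(res$series), n_frames(stack))
  expect_true(all(res$series$ne > 0))
  leak <- with(res$series, nw + sw + se)
  expect_true(all(leak <= 0.01 * res$series$total_fraction))
  # empty stack gives an all-zero series
  blank <- image_stack(list(matrix(217, 201, 201)), 0, 20)
  res0 <- migration_time_series(blank, layout, "center", clf, side = 201,
                                exclusion_radius_px = 21)
  expect_equal(res0$series$total_fraction, 0)
})

test_that("the directional bias index spans [-1, 1] with the right anchors", {
  full <- quadrant_migration_areas(matrix(TRUE, 64, 64), 10)
  expect_equal(directional_bias_index(full, c("nw", "sw")), 0)

  west <- matrix(FALSE, 64, 64); west[, 1:32] <- TRUE
  qw <- quadrant_migration_areas(west, 10)
  expect_equal(directional_bias_index(qw, c("nw", "sw")), 1)
  expect_equal(directional_bias_index(qw, c("ne", "se")), -1)

  empty <- quadrant_migration_areas(matrix(FALSE, 64, 64), 10)
  b <- directional_bias_index(empty, c("nw", "sw"))
  expect_true(is.na(b))
  expect_identical(attr(b, "reason"), "no migrated area")

  expect_error(directional_bias_index(full, character(0)), "subset")
  expect_error(directional_bias_index(full, c("nw", "ne", "sw", "se")), "subset")
})

test_that("facing quadrants follow the bearing toward the central well", {
  layout <- chamber_layout()  # outer1 due north of center
  expect_setequal(facing_quadrants(layout, "outer1"), c("sw", "se"))
  rot <- chamber_layout(orientation_deg = 180)  # outer1 due south
  expect_setequal(facing_quadrants(rot, "outer1"), c("nw", "ne"))
})

test_that("the permutation test is exact, deterministic, and sane on identical arms", {
  same <- c(0.2, 0.3, 0.25, 0.28)
  res <- permutation_test_bias(same, same)
  expect_gte(res$p_value, 0.9)
  expect_identical(res$method, "exact")
  expect_equal(res$n_arrangements, choose(8, 4))

  a <- c(0.9, 0.85, 0.95, 0.8, 0.88); b <- c(0.1, 0.05, 0.2, 0.0, 0.12)
  r1 <- permutation_test_bias(a, b)
  expect_equal(r1$p_value, 2 / choose(10, 5))  # complete separation

  big_a <- runif(10); big_b <- runif(10)
  m1 <- permutation_test_bias(big_a, big_b, n_perm = 500, seed = 3)
  m2 <- permutation_test_bias(big_a, big_b, n_perm = 500, seed = 3)
  expect_identical(m1$p_value, m2$p_value)
  expect_identical(m1$method, "monte-carlo")
  expect_warning(permutation_test_bias(a, b, n_perm = 50), "small")
})

test_that("spider chart export is terminal-frame data and round-trips", {
  series <- dplyr::bind_rows(
    quadrant_migration_areas(matrix(FALSE, 32, 32), 5, frame_index = 1, time_s = 0),
    quadrant_migration_areas({m <- matrix(FALSE, 32, 32); m[1:10, 1:10] <- TRUE; m},
                             5, frame_index = 2, time_s = 1800)
  )
  res <- structure(list(series = series, condition = "with-tumor",
                        well = "outer1", facing = c("sw", "se"),
                        exclusion_radius_px = 5, side = 32),
                   class = "migration_result")
  sp <- spider_chart_export(res)
  expect_equal(nrow(sp), 4)
  expect_equal(sp$area_fraction[sp$quadrant == "NW"],
               series$nw[2])
  path <- withr::local_tempfile(fileext = ".csv")
  spider_chart_export(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$area_fraction, sp$area_fraction)
})
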