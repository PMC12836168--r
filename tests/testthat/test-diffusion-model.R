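test_that("point-source solution has the exact prefactor, symmetry, and domain", {
  expect_equal(point_source_intensity(0, t_s = 1 / (4 * pi), D = 1, A0 = 1), 1.0)
  set.seed(7)
  x <- runif(50, -800, 800); t <- runif(50, 10, 3000)
  expect_equal(point_source_intensity(x, t, D = 3.2),
               point_source_intensity(-x, t, D = 3.2))
  expect_error(point_source_intensity(10, 0, D = 1), "singular")
  expect_error(point_source_intensity(10, -5, D = 1), "singular")
})

test_that("the point-source profile conserves the released amount (quadrature oracle)", {
  for (ps in list(c(D = 6.393, t = 600, A0 = 3.7), c(D = 0.6009, t = 2400, A0 = 1))) {
    lim <- 10 * sqrt(4 * ps["D"] * ps["t"])
    q <- stats::integrate(function(x) {
      point_source_intensity(x, ps["t"], D = ps[["D"]], A0 = ps[["A0"]])
    }, -lim, lim, rel.tol = 1e-10)
    expect_equal(q$value, ps[["A0"]], tolerance = 1e-6)
  }
})

test_that("profile normalization is idempotent, scale invariant, and drops dead time points", {
  x <- seq(0, 500, by = 25)
  t <- c(600, 1200)
  I <- outer(x, t, function(x, t) point_source_intensity(x, t, D = 2))
  pr <- diffusion_profile(x, t, I)
  n1 <- normalize_profile(pr)
  expect_true(all(n1$intensity[n1$x_um == 0] == 1))
  n2 <- normalize_profile(n1)
  expect_equal(n1$intensity, n2$intensity)  # idempotent
  scaled <- normalize_profile(diffusion_profile(x, t, 7.3 * I))
  expect_equal(scaled$intensity, n1$intensity)  # scale invariance

  I0 <- I; I0[1, 2] <- 0  # kill the rim value of the second time point
  expect_warning(nz <- normalize_profile(diffusion_profile(x, t, I0)), "zero rim")
  expect_setequal(unique(nz$t_s), 600)
})

test_that("the fit recovers the coefficient exactly on noiseless profiles", {
  for (D in c(6.393, 0.6009)) {
    fit <- fit_diffusion_coefficient(analytic_profile(D))
    expect_equal(fit$D_hat, D, tolerance = 5e-5)
    expect_lt(fit$rss, 1e-10)
  }
})

test_that("fitted D is monotone in true D on noiseless data", {
  D_grid <- c(0.1, 0.5, 1, 3, 6, 12, 30)
  D_hat <- vapply(D_grid, function(D) {
    fit_diffusion_coefficient(analytic_profile(D))$D_hat
  }, numeric(1))
  expect_true(all(diff(D_hat) > 0))
})

test_that("the un-normalized fit recovers both D and the released amount", {
  x <- seq(0, 500, by = 10); t <- c(10, 20, 30, 40) * 60
  I <- outer(x, t, function(x, t) point_source_intensity(x, t, D = 4.1, A0 = 250))
  fit <- fit_diffusion_coefficient(diffusion_profile(x, t, I))
  expect_equal(fit$D_hat, 4.1, tolerance = 1e-4)
  expect_equal(fit$A0_hat, 250, tolerance = 1e-4)
  td <- tidy(fit)
  expect_setequal(td$term, c("D", "A0"))
  expect_equal(glance(fit)$n_points, length(x) * length(t))
})

test_that("fits stay within 10% median error under 5% multiplicative noise", {
  x <- seq(0, 500, by = 10); t <- c(10, 20, 30, 40) * 60
  clean <- outer(x, t, function(x, t) point_source_intensity(x, t, D = 5))
  errs <- withr::with_seed(99, {
    vapply(1:100, function(i) {
      noisy <- pmax(clean * (1 + 0.05 * rnorm(length(clean))), 0)
      pr <- normalize_profile(diffusion_profile(x, t, noisy))
      abs(fit_diffusion_coefficient(pr)$D_hat - 5) / 5
    }, numeric(1))
  })
  expect_lt(median(errs), 0.10)
})

test_that("a flat profile is flagged ill-posed", {
  x <- seq(0, 100, by = 10); t <- c(600, 1200)
  expect_warning(
    fit <- fit_diffusion_coefficient(
      diffusion_profile(x, t, matrix(1, length(x), length(t)))),
    "ill-posed")
  expect_true(fit$ill_posed)
  expect_true(is.na(fit$D_hat))
})

test_that("fit preconditions are enforced", {
  x <- seq(0, 100, by = 25)
  pr1 <- diffusion_profile(x, 600, matrix(exp(-x^2 / 100), ncol = 1))
  expect_error(fit_diffusion_coefficient(pr1), ">= 2 positive time points")
  pr2 <- diffusion_profile(c(0, 50), c(600, 1200), matrix(1:4, 2))
  expect_error(fit_diffusion_coefficient(pr2), ">= 5 distances")
})

test_that("line profiles sample floor(length/ps) + 1 points and flatten uniform frames", {
  layout <- chamber_layout(pixel_size_um = 10)
  shape <- rev(layout$chamber_extent_um) / 10
  frames <- list(matrix(37, shape[1], shape[2]), matrix(37, shape[1], shape[2]))
  stack <- image_stack(frames, c(600, 1200), 10)
  pr <- extract_line_profiles(stack, layout)
  expect_equal(length(unique(pr$x_um)), floor(500 / 10) + 1)
  expect_true(all(pr$intensity == 37))
})

test_that("profiles exiting the raster are truncated with a warning, or error in strict mode", {
  layout <- chamber_layout(well_diameter_um = 200, spacing_um = 100,
                           chamber_extent_um = c(900, 900), pixel_size_um = 10)
  stack <- image_stack(list(matrix(1, 90, 90)), 600, 10)
  expect_warning(pr <- extract_line_profiles(stack, layout), "truncat")
  expect_lt(length(unique(pr$x_um)), 51)
  expect_error(extract_line_profiles(stack, layout, strict = TRUE), "exit")
})

test_that("extracted profiles match the simulator's own radial transect", {
  layout <- chamber_layout(well_diameter_um = 400, spacing_um = 600,
                           chamber_extent_um = c(4000, 4000), pixel_size_um = 20)
  sim <- simulate_chamber_diffusion(layout, list(center = tracer_spec("t", 1e4, 6.393)),
                                    grid_spacing_um = 20, output_times_s = c(600))
  stack <- image_stack(sim$fields$center, 600, 20)
  pr <- extract_line_profiles(stack, layout, length_um = 400)
  tran <- sim_radial_transect(sim, "center", 1, 410 + layout$well_radius_um)
  r_px <- round(layout$well_radius_um / 20)
  matched <- tran$concentration[r_px + pr$x_um / 20]
  expect_equal(pr$intensity, matched, tolerance = 0.01)
})

test_that("averaging the four rim rays reduces fit RMSE versus a single ray", {
  layout <- chamber_layout(well_diameter_um = 400, spacing_um = 600,
                           chamber_extent_um = c(4000, 4000), pixel_size_um = 10)
  tracer <- tracer_spec("t", 1e4, 6.393)
  errs <- vapply(1:30, function(s) {
    st <- generate_tracer_stack(layout, tracer, noise_sigma = 0.10, seed = 400 + s)
    e4 <- fit_diffusion_coefficient(
      normalize_profile(extract_line_profiles(st, layout)))$D_hat - 6.393
    e1 <- fit_diffusion_coefficient(
      normalize_profile(extract_line_profiles(st, layout, directions = "north")))$D_hat - 6.393
    c(e4, e1)
  }, numeric(2))
  expect_lt(sqrt(mean(errs[1, ]^2)), sqrt(mean(errs[2, ]^2)))
})

test_that("profiles round-trip through CSV", {
  pr <- analytic_profile(2.5, x_um = seq(0, 200, by = 20), t_s = c(600, 1200))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(pr, path)
  back <- read_profile_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(pr))
  expect_true(attr(back, "normalized"))
})
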