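test_that("tracer stacks are reproducible and carry ground truth", {
  layout <- chamber_layout()
  tr <- tracer_spec("dextran", 1e4, 6.393)
  s1 <- generate_tracer_stack(layout, tr, noise_sigma = 0.05, seed = 21)
  s2 <- generate_tracer_stack(layout, tr, noise_sigma = 0.05, seed = 21)
  expect_identical(s1$frames, s2$frames)
  expect_equal(attr(s1, "true_D"), 6.393)
  s3 <- generate_tracer_stack(layout, tr, noise_sigma = 0.05, seed = 22)
  expect_false(identical(s1$frames, s3$frames))
})

test_that("the noiseless generate-extract-normalize-fit loop recovers the coefficient", {
  layout <- chamber_layout()
  for (D in c(6.393, 0.6009)) {
    st <- generate_tracer_stack(layout, tracer_spec("t", 1e4, D), seed = 1)
    fit <- fit_diffusion_coefficient(
      normalize_profile(extract_line_profiles(st, layout)))
    expect_equal(fit$D_hat, D, tolerance = 5e-3)
  }
})

test_that("the faster tracer leaves a flatter 40-minute profile than the slower one", {
  layout <- chamber_layout()
  drop_at_40min <- function(D) {
    st <- generate_tracer_stack(layout, tracer_spec("t", 1e4, D),
                                times_s = c(0, 40 * 60), seed = 1)
    pr <- normalize_profile(extract_line_profiles(st, layout))
    last <- pr[pr$t_s == 40 * 60, ]
    last$intensity[which.min(last$x_um)] - last$intensity[which.max(last$x_um)]
  }
  # dextran (10 kDa, fast) equilibrates; albumin (66 kDa, slow) stays steep
  expect_lt(drop_at_40min(6.393), drop_at_40min(0.6009))
})

test_that("immobile and unbiased agents behave as their motility parameters dictate", {
  layout <- chamber_layout()
  frozen <- cell_type_profile("still", agent_params(speed_um = 0), "outer1")
  traj <- simulate_migration(layout, frozen, duration_s = 10 * 1800, seed = 2)
  per_agent <- dplyr::summarise(dplyr::group_by(traj, agent),
                                sd_x = sd(x_um), sd_y = sd(y_um))
  expect_true(all(per_agent$sd_x == 0 & per_agent$sd_y == 0))

  nonmot <- cell_type_profile("fixed", agent_params(motile = FALSE), "outer1")
  traj2 <- simulate_migration(layout, nonmot, duration_s = 10 * 1800, seed = 2)
  expect_true(all(dplyr::summarise(dplyr::group_by(traj2, agent),
                                   s = sd(x_um) + sd(y_um))$s == 0))
})

test_that("unbiased walks have near-zero mean displacement; biased walks drift to the center", {
  layout <- chamber_layout()
  pos0 <- c(tidy(layout)$x_um[2], tidy(layout)$y_um[2])
  to_center <- layout$center_well_um - pos0
  to_center <- to_center / sqrt(sum(to_center^2))
  field <- chemotaxgel:::attractant_field(layout)
  terminal_drift <- function(kappa, seed) {
    prof <- cell_type_profile("t", agent_params(chemotactic_bias = kappa,
                                                n_agents = 40), "outer1")
    traj <- simulate_migration(layout, prof, duration_s = 24 * 3600,
                               seed = seed, field = field)
    last <- traj[traj$step == max(traj$step), ]
    first <- traj[traj$step == 0, ]
    dx <- mean(last$x_um - first$x_um); dy <- mean(last$y_um - first$y_um)
    c(proj = dx * to_center[1] + dy * to_center[2], dx = dx, dy = dy)
  }
  null_drift <- vapply(1:50, function(s) terminal_drift(0, 600 + s), numeric(3))
  # mean displacement magnitude is within 3 SE of zero per component
  for (row in c("dx", "dy")) {
    se <- sd(null_drift[row, ]) / sqrt(ncol(null_drift))
    expect_lt(abs(mean(null_drift[row, ])), 3 * se)
  }
  biased_proj <- vapply(1:50, function(s) terminal_drift(3, 700 + s)["proj"],
                        numeric(1))
  expect_gte(mean(biased_proj > 0), 0.95)
})

test_that("rendering is deterministic, clips gracefully, and matches blob-area truth", {
  # a sparse grid of agents with no overlaps
  centers <- expand.grid(x = seq(190, 1790, by = 400), y = seq(190, 1790, by = 400))
  pts <- tibble::tibble(cell_type = "g", well = "outer1",
                        agent = seq_len(nrow(centers)), step = 0L, t_s = 0,
                        x_um = centers$x, y_um = centers$y)
  rend <- render_migration_frames(pts, c(100, 100), 20, blob_radius_um = 120)
  rend2 <- render_migration_frames(pts, c(100, 100), 20, blob_radius_um = 120)
  expect_identical(rend$stack$frames, rend2$stack$frames)
  truth_frac <- mean(rend$truth_masks[[1]])
  analytic <- nrow(centers) * pi * 6^2 / 100^2  # 120 um = 6 px radius
  expect_equal(truth_frac, analytic, tolerance = 0.02)
  # zero agents: constant background
  none <- render_migration_frames(pts[0, ], c(50, 50), 20, times_s = 0)
  expect_equal(none$stack$frames[[1]], matrix(round(0.85 * 255), 50, 50))
  expect_false(any(none$truth_masks[[1]]))
})

test_that("confluency images honor their coverage set-point and seed contract", {
  blank <- generate_confluency_image(c(128, 128), 0, seed = 5)
  expect_false(any(blank$truth_mask))
  expect_equal(attr(blank$truth_mask, "fraction"), 0)

  g1 <- generate_confluency_image(c(256, 256), 0.5, seed = 5)
  g2 <- generate_confluency_image(c(256, 256), 0.5, seed = 5)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$truth_mask, g2$truth_mask)

  full <- generate_confluency_image(c(64, 64), 1, seed = 5)
  expect_true(all(full$truth_mask))

  expect_error(generate_confluency_image(c(256, 256), 0.9, seed = 5,
                                         max_cells = 3),
               "unreachable")
  expect_error(generate_confluency_image(c(64, 64), 1.2, seed = 5), "\\[0, 1\\]")
})

test_that("the 83% set-point fixture lands inside the half-point band", {
  gen <- generate_confluency_image(c(1495, 1496), 0.83, seed = 83)
  expect_gte(attr(gen$truth_mask, "fraction"), 0.825)
  expect_lte(attr(gen$truth_mask, "fraction"), 0.835)
})

test_that("agent and cell-type parameter validation rejects bad values", {
  expect_error(agent_params(persistence = 1), "< 1")
  expect_error(agent_params(speed_um = -2), ">= 0")
  expect_error(agent_params(chemotactic_bias = -1), ">= 0")
  p <- agent_params()
  expect_error(cell_type_profile("x", p, "outer1", density = 0), "> 0")
  expect_equal(p$step_interval_s, 1800)
})
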