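# Assay orchestration over YAML configs. Each run_* function composes the
# module operations end-to-end and returns a report list that serializes to
# JSON with provenance (config hash, package and R versions).

#' Read and validate an assay configuration
#'
#' The YAML schema groups physical quantities with explicit units in the
#' key names. Required keys: `layout` (with `well_diameter_um`,
#' `spacing_um`, `chamber_extent_um`, `pixel_size_um`; `spacing_um` is
#' edge-to-edge, and `orientation_deg` is optional), plus any of the
#' assay-specific blocks used by the run functions (`tracers`,
#' `migration`, `confluency`). A `seed` key fixes all randomness.
#'
#' @param path YAML file path.
#' @return A list of class `assay_config` with a `layout` turned into a
#'   [chamber_layout()] and attribute `hash` (of the raw file contents).
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) stop_chemotax("config file not found: `%s`", path)
  raw <- yaml::read_yaml(path)
  for (key in c("layout")) {
    if (is.null(raw[[key]])) stop_chemotax("config is missing required key `%s`", key)
  }
  for (key in c("well_diameter_um", "spacing_um", "chamber_extent_um", "pixel_size_um")) {
    if (is.null(raw$layout[[key]])) {
      stop_chemotax("config is missing required key `layout.%s`", key)
    }
  }
  raw$layout <- chamber_layout(
    well_diameter_um = raw$layout$well_diameter_um,
    spacing_um = raw$layout$spacing_um,
    chamber_extent_um = unlist(raw$layout$chamber_extent_um),
    pixel_size_um = raw$layout$pixel_size_um,
    orientation_deg = raw$layout$orientation_deg %||% 0
  )
  raw$seed <- raw$seed %||% 1L
  attr(raw, "hash") <- rlang::hash(readLines(path))
  class(raw) <- "assay_config"
  raw
}

report_provenance <- function(config) {
  list(
    config_hash = attr(config, "hash"),
    package_version = as.character(utils::packageVersion("chemotaxgel")),
    r_version = as.character(getRversion()),
    seed = config$seed
  )
}

#' Run the diffusion assay end-to-end
#'
#' For each tracer in the config: obtain a stack (from `stack_path` or,
#' when absent, by generating a synthetic stack with the configured true
#' coefficient and seed), extract and average the four rim line profiles,
#' normalize per time point, and fit the point-source model over the full
#' spatio-temporal dataset.
#'
#' Config block `tracers`: a list of entries with `name`,
#' `molecular_weight_da`, and either `stack_path` or `true_D` (plus
#' optional `well`, `times_min`, `noise_sigma`).
#'
#' @param config An [read_assay_config()] result (or a path to one).
#' @param out Optional JSON report path.
#' @return A list: `fits` (tibble with one row per tracer: `tracer`,
#'   `well`, `D_hat`, `rss`, `n_points`, `true_D` when known),
#'   `provenance`. Written to `out` as JSON when given.
#' @export
run_diffusion_assay <- function(config, out = NULL) {
  if (is.character(config)) config <- read_assay_config(config)
  if (is.null(config$tracers)) stop_chemotax("config is missing required key `tracers`")
  layout <- config$layout
  fits <- bind_rows(lapply(config$tracers, function(tr) {
    well <- tr$well %||% "center"
    if (!is.null(tr$stack_path)) {
      if (!file.exists(tr$stack_path)) {
        stop_chemotax("config key `tracers.stack_path` points to a missing file: `%s`",
                      tr$stack_path)
      }
      stack <- read_image_stack(tr$stack_path)
      true_D <- NA_real_
    } else {
      if (is.null(tr$true_D)) {
        stop_chemotax("tracer `%s` needs `stack_path` or `true_D`", tr$name)
      }
      spec <- tracer_spec(tr$name, tr$molecular_weight_da %||% 1e4, tr$true_D)
      stack <- generate_tracer_stack(
        layout, spec, well = well,
        times_s = (tr$times_min %||% c(0, 10, 20, 30, 40)) * 60,
        noise_sigma = tr$noise_sigma %||% 0, seed = config$seed
      )
      true_D <- tr$true_D
    }
    profile <- extract_line_profiles(stack, layout, well = well)
    fit <- fit_diffusion_coefficient(normalize_profile(profile))
    tibble(tracer = tr$name, well = well, D_hat = fit$D_hat,
           rss = fit$rss, n_points = fit$n_points, true_D = true_D)
  }))
  report <- list(fits = fits, provenance = report_provenance(config))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  report
}

#' Run the migration assay end-to-end
#'
#' Simulates (or loads) per-well migration movies for a chemotactically
#' biased arm and an unbiased control arm, quantifies per-quadrant
#' migrated area over time, computes the directional bias index of the
#' quadrants facing the central well, and compares the arms with the
#' permutation test.
#'
#' Config block `migration`: `n_wells_per_arm`, `bias_kappa`, `speed_um`,
#' `persistence`, `n_agents`, `duration_h`, `crop_side_px`,
#' `frame_pixel_size_um`, `blob_radius_um`.
#'
#' @param config An [read_assay_config()] result (or a path).
#' @param classifier Optional trained pixel classifier; by default one is
#'   trained on rendered synthetic frames with the config seed.
#' @param out Optional JSON report path; a spider CSV is written next to
#'   it.
#' @return A list: `series` (per-well terminal quadrant fractions),
#'   `bias` (per-well terminal bias index), `test` (permutation result),
#'   `spider` (spider-chart tibble), `provenance`.
#' @export
run_migration_assay <- function(config, classifier = NULL, out = NULL) {
  if (is.character(config)) config <- read_assay_config(config)
  mc <- config$migration
  if (is.null(mc)) stop_chemotax("config is missing required key `migration`")
  layout <- config$layout
  sim <- simulate_migration_experiment(
    layout,
    n_wells_per_arm = mc$n_wells_per_arm %||% 5,
    bias_kappa = mc$bias_kappa %||% 2,
    speed_um = mc$speed_um %||% 15,
    persistence = mc$persistence %||% 0.5,
    n_agents = mc$n_agents %||% 60,
    duration_s = (mc$duration_h %||% 72) * 3600,
    crop_side_px = mc$crop_side_px %||% 201,
    frame_pixel_size_um = mc$frame_pixel_size_um %||% 20,
    blob_radius_um = mc$blob_radius_um %||% 40,
    seed = config$seed,
    classifier = classifier
  )
  test <- permutation_test_bias(sim$bias_biased, sim$bias_control,
                                seed = config$seed)
  spider <- spider_chart_export(sim$results)
  report <- list(
    series = spider, bias = sim$bias_table, test = test,
    provenance = report_provenance(config)
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    readr::write_csv(spider, sub("\\.json$", "_spider.csv", out))
  }
  report
}

#' Run the confluency titration end-to-end
#'
#' Measures confluency for a set of seeding densities. Each density maps
#' to a synthetic confluency image at its configured target coverage
#' (config block `confluency`: list of `{density, target_fraction}`,
#' optional `cell_radius_range`), or to an image path.
#'
#' @param config An [read_assay_config()] result (or a path).
#' @param classifier Optional trained pixel classifier; by default one is
#'   trained on synthetic confluency tiles with the config seed.
#' @param shape Image shape for generated fixtures (default
#'   `c(748, 748)`, a half-format tile; the full camera format is
#'   `c(1495, 1496)`).
#' @param out Optional JSON report path.
#' @return A list: `table` (tibble with `density`, `target_fraction`,
#'   `measured_fraction`), `provenance`.
#' @export
run_confluency_titration <- function(config, classifier = NULL,
                                     shape = c(748, 748), out = NULL) {
  if (is.character(config)) config <- read_assay_config(config)
  cc <- config$confluency
  if (is.null(cc)) stop_chemotax("config is missing required key `confluency`")
  if (is.null(classifier)) {
    classifier <- train_confluency_classifier(seed = config$seed)
  }
  table <- bind_rows(lapply(cc, function(entry) {
    gen <- generate_confluency_image(
      shape = shape, target_fraction = entry$target_fraction,
      cell_radius_range = unlist(entry$cell_radius_range %||% c(15, 35)),
      seed = config$seed + round(1e4 * entry$target_fraction)
    )
    tibble(density = entry$density,
           target_fraction = attr(gen$truth_mask, "fraction"),
           measured_fraction = confluency(gen$image, classifier))
  }))
  report <- list(table = table, provenance = report_provenance(config))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  report
}

#' Train the default confluency classifier on synthetic tiles
#'
#' Generates small labeled confluency tiles spanning the coverage range
#' (including a blank and a confluent tile, so the classifier sees
#' contrast-normalized sensor noise and pure cell texture as single-class
#' examples), pushes them through the same preprocessing as the measurement
#' chain (8-bit, rolling ball, contrast enhancement) and trains the pixel
#' classifier on the processed images against the ground truth masks.
#'
#' @param seed Seed for generation and pixel sampling.
#' @param tile_shape Training tile shape (default `c(256, 256)`).
#' @param fractions Coverage set-points of the training tiles.
#' @return A `pixel_classifier`.
#' @export
train_confluency_classifier <- function(seed = 1, tile_shape = c(512, 512),
                                        fractions = c(0, 0.3, 0.6, 0.85, 1)) {
  tiles <- lapply(seq_along(fractions), function(i) {
    generate_confluency_image(tile_shape, fractions[i], seed = seed + i)
  })
  imgs <- lapply(tiles, function(tl) {
    enhance_contrast(rolling_ball_subtract(to_8bit(tl$image), 6, TRUE),
                     0.35, TRUE)
  })
  train_pixel_classifier(imgs, lapply(tiles, `[[`, "truth_mask"),
                         scales = c(1, 2, 4), n_samples = 3000, seed = seed)
}

# Shared machinery for the migration experiment: simulate both arms,
# render the terminal frame of each well, segment, and compute terminal
# bias indices. Used by run_migration_assay and the validation suite.
#' Simulate and quantify a two-arm migration experiment
#'
#' Builds `n_wells_per_arm` chemotactically biased wells (kappa =
#' `bias_kappa`) and as many unbiased control wells (kappa = 0), renders
#' the terminal frame of each around its seeded well, segments it with the
#' pixel classifier, and returns terminal quadrant areas and bias indices
#' for both arms.
#'
#' @param layout A [chamber_layout()].
#' @param n_wells_per_arm Replicate wells per arm.
#' @param bias_kappa Chemotactic bias of the treated arm.
#' @param speed_um,persistence,n_agents Agent motility parameters.
#' @param duration_s Simulated duration (s).
#' @param crop_side_px,frame_pixel_size_um,blob_radius_um Rendering
#'   parameters.
#' @param seed Seed; wells use consecutive derived seeds.
#' @param classifier Optional classifier; trained on a rendered calibration
#'   frame when `NULL`.
#' @param use_truth_masks Skip segmentation and use the renderer's ground
#'   truth masks (for tests that isolate the statistics from the
#'   classifier).
#' @return A list: `results` (all `migration_result`s), `bias_biased`,
#'   `bias_control` (terminal bias vectors), `bias_table`.
#' @export
simulate_migration_experiment <- function(layout, n_wells_per_arm = 5,
                                          bias_kappa = 2, speed_um = 15,
                                          persistence = 0.5, n_agents = 60,
                                          duration_s = 3 * 86400,
                                          crop_side_px = 201,
                                          frame_pixel_size_um = 20,
                                          blob_radius_um = 40,
                                          seed = 1, classifier = NULL,
                                          use_truth_masks = FALSE) {
  field <- attractant_field(layout)
  outer_wells <- c("outer1", "outer2", "outer3")
  ps <- frame_pixel_size_um
  side <- crop_side_px
  if (is.null(classifier) && !use_truth_masks) {
    classifier <- train_migration_classifier(layout, blob_radius_um, ps, seed)
  }
  run_well <- function(kappa, idx, arm) {
    well <- outer_wells[(idx - 1L) %% 3L + 1L]
    prof <- cell_type_profile(
      sprintf("%s-w%d", if (arm == 1L) "treated" else "control", idx),
      agent_params(speed_um = speed_um, persistence = persistence,
                   chemotactic_bias = kappa, n_agents = n_agents),
      seeded_well = well, rendered_radius_um = blob_radius_um
    )
    # spread well seeds so experiments with nearby seeds share no draws
    well_seed <- as.integer((as.double(seed) * 131 + 1000 * arm + idx) %%
                              2147483647)
    traj <- simulate_migration(layout, prof, duration_s = duration_s,
                               seed = well_seed, field = field)
    pos <- well_position_um(layout, well)
    origin <- pos - side / 2 * ps
    rend <- render_migration_frames(
      traj, c(side, side), ps, origin_um = origin,
      times_s = c(0, max(traj$t_s)), blob_radius_um = blob_radius_um
    )
    facing <- facing_quadrants(layout, well)
    excl_px <- 1.05 * layout$well_radius_um / ps
    masks <- if (use_truth_masks) {
      rend$truth_masks
    } else {
      lapply(rend$stack$frames, function(fr) {
        binarize(pixel_probability_map(fr, classifier), 0.5)
      })
    }
    series <- bind_rows(lapply(seq_along(masks), function(i) {
      quadrant_migration_areas(masks[[i]], excl_px, frame_index = i,
                               time_s = rend$stack$timestamps_s[i])
    }))
    series$bias_index <- vapply(seq_len(nrow(series)), function(i) {
      directional_bias_index(series[i, ], facing)
    }, numeric(1))
    structure(
      list(series = series,
           condition = if (arm == 1L) "with-tumor" else "control",
           well = sprintf("%s-%d", well, idx), facing = facing,
           exclusion_radius_px = excl_px, side = side),
      class = "migration_result"
    )
  }
  biased <- lapply(seq_len(n_wells_per_arm), function(i) run_well(bias_kappa, i, 1L))
  control <- lapply(seq_len(n_wells_per_arm), function(i) run_well(0, i, 2L))
  bias_of <- function(r) tail(r$series$bias_index, 1)
  bias_biased <- vapply(biased, bias_of, numeric(1))
  bias_control <- vapply(control, bias_of, numeric(1))
  list(
    results = c(biased, control),
    bias_biased = bias_biased,
    bias_control = bias_control,
    bias_table = tibble(
      condition = rep(c("with-tumor", "control"), each = n_wells_per_arm),
      well = vapply(c(biased, control), `[[`, character(1), "well"),
      terminal_bias = c(bias_biased, bias_control)
    )
  )
}

#' Train the default migration-frame classifier
#'
#' Renders one calibration frame of scattered synthetic cells (the same
#' appearance model as the migration movies) and trains the pixel
#' classifier on it against the renderer's ground truth.
#'
#' @param layout A [chamber_layout()].
#' @param blob_radius_um Rendered cell radius (um).
#' @param pixel_size_um Frame pixel size (um).
#' @param seed Seed.
#' @return A `pixel_classifier`.
#' @export
train_migration_classifier <- function(layout, blob_radius_um = 40,
                                       pixel_size_um = 20, seed = 1) {
  side <- 160L
  ps <- pixel_size_um
  n <- 80L
  pts <- withr::with_seed(seed, {
    tibble(cell_type = "calib", well = "outer1",
           agent = seq_len(n), step = 0L, t_s = 0,
           x_um = stats::runif(n, blob_radius_um, side * ps - blob_radius_um),
           y_um = stats::runif(n, blob_radius_um, side * ps - blob_radius_um))
  })
  rend <- render_migration_frames(pts, c(side, side), ps,
                                  blob_radius_um = blob_radius_um)
  train_pixel_classifier(rend$stack$frames, rend$truth_masks,
                         scales = c(1, 2), seed = seed)
}
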