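# Agent-based chemotactic migration generator. The paper-scale experiment
# observes migration; it does not model it. This simulator provides ground
# truth for the quantification pipeline: a biased persistent random walk
# whose heading mixes the previous heading, the local attractant gradient
# direction and von Mises noise.

#' Motility parameters of a synthetic cell type
#'
#' @param speed_um Displacement per step (um). Mesenchymal cells in
#'   collagen move on the order of 10-40 um/h; the default 15 um per 30 min
#'   step sits in that range.
#' @param persistence Heading autocorrelation weight in `[0, 1)`.
#' @param chemotactic_bias kappa >= 0, the weight of alignment to the
#'   attractant gradient (0 = unbiased walk).
#' @param step_interval_s Step duration (s); defaults to the 30 min imaging
#'   interval so trajectory steps align 1:1 with frames.
#' @param n_agents Number of simulated cells.
#' @param motile `FALSE` freezes the cells (non-migrating types).
#' @param heading_noise_kappa Concentration of the von Mises heading noise.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(speed_um = 15, persistence = 0.5,
                         chemotactic_bias = 2, step_interval_s = 1800,
                         n_agents = 60, motile = TRUE,
                         heading_noise_kappa = 3) {
  assert_number(speed_um, "speed_um", non_negative = TRUE)
  assert_number(persistence, "persistence", non_negative = TRUE)
  if (persistence >= 1) stop_chemotax("`persistence` must be < 1")
  assert_number(chemotactic_bias, "chemotactic_bias", non_negative = TRUE)
  assert_number(step_interval_s, "step_interval_s", positive = TRUE)
  assert_number(heading_noise_kappa, "heading_noise_kappa", non_negative = TRUE)
  structure(
    list(speed_um = speed_um, persistence = persistence,
         chemotactic_bias = chemotactic_bias,
         step_interval_s = step_interval_s,
         n_agents = as.integer(n_agents), motile = isTRUE(motile),
         heading_noise_kappa = heading_noise_kappa),
    class = "agent_params"
  )
}

#' Synthetic cell-type profile
#'
#' @param name Cell-type label (e.g. `"hDFb-like"`).
#' @param params An [agent_params()].
#' @param seeded_well Well id the cells start from.
#' @param rendered_radius_um Rendered blob radius (um).
#' @param density Nominal cells per well (bookkeeping; the rendered agent
#'   count is `params$n_agents`). Default 1e4, the assay seeding density.
#' @return A list of class `cell_type_profile`.
#' @export
cell_type_profile <- function(name, params, seeded_well,
                              rendered_radius_um = 15, density = 1e4) {
  stopifnot(inherits(params, "agent_params"))
  assert_number(density, "density", positive = TRUE)
  structure(
    list(name = name, params = params, seeded_well = seeded_well,
         rendered_radius_um = rendered_radius_um, density = density),
    class = "cell_type_profile"
  )
}

# Quasi-static attractant field: the diffusion field of the attractant
# source at a reference time, normalized to peak 1, with its gradient
# (central differences) and a saturation constant for the bias weight.
attractant_field <- function(layout, source_well = "center",
                             attractant_D = 0.6009, grid_spacing_um = 25,
                             reference_time_s = 86400) {
  sim <- simulate_chamber_diffusion(
    layout, stats::setNames(list(tracer_spec("attractant", 1e4, attractant_D)),
                            source_well),
    grid_spacing_um = grid_spacing_um,
    output_times_s = c(reference_time_s)
  )
  C <- sim$fields[[source_well]][[1]]
  C <- C / max(C)
  h <- grid_spacing_um
  gx <- (cbind(C[, -1], C[, ncol(C)]) - cbind(C[, 1], C[, -ncol(C)])) / (2 * h)
  gy <- (rbind(C[-1, ], C[nrow(C), ]) - rbind(C[1, ], C[-nrow(C), ])) / (2 * h)
  gmag <- sqrt(gx^2 + gy^2)
  g_half <- stats::median(gmag[gmag > 0])
  list(C = C, gx = gx, gy = gy, h = h, g_half = g_half,
       extent = layout$chamber_extent_um)
}

field_lookup <- function(field, x, y) {
  i <- clamp(pixel_index(y, field$h), 1L, nrow(field$C))
  j <- clamp(pixel_index(x, field$h), 1L, ncol(field$C))
  idx <- cbind(i, j)
  list(gx = field$gx[idx], gy = field$gy[idx])
}

#' Simulate chemotactic cell migration in the chamber
#'
#' Runs a biased persistent random walk for each cell type. Agents start
#' uniformly on the rim of their seeded well with outward initial
#' headings. At each step the new heading is the circular mean of the
#' previous heading (weight = persistence) and the local attractant
#' gradient direction (weight = kappa times a saturating function of the
#' gradient magnitude, `|g| / (|g| + g_half)` with `g_half` the median
#' non-zero gradient magnitude of the field), plus von Mises noise; the
#' displacement is `speed_um` per step. Non-motile types do not move.
#' Chamber boundaries reflect. All randomness flows from `seed`.
#'
#' The attractant field is quasi-static: the diffusion field of the source
#' well at a reference time (default 24 h), computed once. Self-generated
#' (sink-type) gradients are out of scope.
#'
#' @param layout A [chamber_layout()].
#' @param cell_types List of [cell_type_profile()]s.
#' @param attractant_source Well id emitting the attractant.
#' @param attractant_D Attractant diffusion coefficient (um^2/s); default
#'   0.6009, the albumin-like (66 kDa protein) coefficient.
#' @param duration_s Total simulated time (s).
#' @param seed Seed.
#' @param grid_spacing_um Attractant-field grid spacing (um).
#' @param reference_time_s Field reference time (s), default 86400 (24 h).
#' @param field Optional precomputed field (from repeated calls); overrides
#'   the attractant arguments.
#' @return A tibble of class `migration_trajectories`: one row per
#'   (cell type, agent, step) with `cell_type`, `well`, `agent`, `step`,
#'   `t_s`, `x_um`, `y_um`.
#' @export
simulate_migration <- function(layout, cell_types, attractant_source = "center",
                               attractant_D = 0.6009, duration_s = 3 * 86400,
                               seed = 1, grid_spacing_um = 25,
                               reference_time_s = 86400, field = NULL) {
  stopifnot(inherits(layout, "chamber_layout"))
  if (inherits(cell_types, "cell_type_profile")) cell_types <- list(cell_types)
  needs_field <- any(vapply(cell_types, function(ct)
    ct$params$motile && ct$params$chemotactic_bias > 0, logical(1)))
  if (is.null(field) && needs_field) {
    field <- attractant_field(layout, attractant_source, attractant_D,
                              grid_spacing_um, reference_time_s)
  }
  W <- layout$chamber_extent_um[1]; H <- layout$chamber_extent_um[2]
  r_well <- layout$well_radius_um
  withr::with_seed(seed, {
    bind_rows(lapply(cell_types, function(ct) {
      p <- ct$params
      if (p$step_interval_s > duration_s) {
        stop_chemotax("duration %g s is shorter than one step interval (%g s)",
                      duration_s, p$step_interval_s)
      }
      n_steps <- floor(duration_s / p$step_interval_s)
      n <- p$n_agents
      pos0 <- well_position_um(layout, ct$seeded_well)
      if (pos0[1] < 0 || pos0[2] < 0 || pos0[1] > W || pos0[2] > H) {
        stop_chemotax("seeded well `%s` lies outside the chamber", ct$seeded_well)
      }
      theta0 <- stats::runif(n, -pi, pi)
      x <- pos0[1] + r_well * cos(theta0)
      y <- pos0[2] + r_well * sin(theta0)
      heading <- theta0  # outward radial
      X <- matrix(0, n, n_steps + 1L); Y <- matrix(0, n, n_steps + 1L)
      X[, 1] <- x; Y[, 1] <- y
      for (s in seq_len(n_steps)) {
        if (p$motile && p$speed_um > 0) {
          vx <- p$persistence * cos(heading)
          vy <- p$persistence * sin(heading)
          if (p$chemotactic_bias > 0) {
            g <- field_lookup(field, x, y)
            gmag <- sqrt(g$gx^2 + g$gy^2)
            w <- p$chemotactic_bias * gmag / (gmag + field$g_half)
            ok <- gmag > 0
            vx[ok] <- vx[ok] + w[ok] * g$gx[ok] / gmag[ok]
            vy[ok] <- vy[ok] + w[ok] * g$gy[ok] / gmag[ok]
          }
          mean_dir <- ifelse(vx == 0 & vy == 0, heading, atan2(vy, vx))
          heading <- rvonmises(n, 0, p$heading_noise_kappa) + mean_dir
          x <- x + p$speed_um * cos(heading)
          y <- y + p$speed_um * sin(heading)
          # reflecting chamber boundaries
          x <- ifelse(x < 0, -x, ifelse(x > W, 2 * W - x, x))
          y <- ifelse(y < 0, -y, ifelse(y > H, 2 * H - y, y))
        }
        X[, s + 1L] <- x; Y[, s + 1L] <- y
      }
      tibble(
        cell_type = ct$name, well = ct$seeded_well,
        agent = rep(seq_len(n), times = n_steps + 1L),
        step = rep(0:n_steps, each = n),
        t_s = rep((0:n_steps) * p$step_interval_s, each = n),
        x_um = as.vector(X), y_um = as.vector(Y)
      )
    }))
  })
}

#' Render migration trajectories as brightfield-like frames
#'
#' Draws each agent as an anti-aliased dark disk on a light background
#' (the brightfield convention) at the requested times, together with the
#' exact boolean ground-truth mask per frame so segmentation can be scored
#' objectively. Rendering is deterministic given the trajectories: no
#' randomness is involved.
#'
#' @param traj A [simulate_migration()] tibble (one cell type or several;
#'   all rendered into the same frames).
#' @param frame_shape Integer `(rows, cols)` of the rendered frames.
#' @param pixel_size_um Rendered pixel size (um).
#' @param origin_um Physical coordinate of the top-left frame corner
#'   (default `c(0, 0)`), so frames can be centered on a well.
#' @param times_s Frame times; must be a subset of trajectory step times.
#' @param blob_radius_um Rendered cell radius (um).
#' @param intensity Disk gray level in `[0, 1]` (dark), default 0.35.
#' @param background Background gray level in `[0, 1]` (light), default
#'   0.85.
#' @return A list: `stack` (an 8-bit [image_stack()]) and `truth_masks`
#'   (list of logical matrices). Blobs falling outside the frame are
#'   clipped.
#' @export
render_migration_frames <- function(traj, frame_shape, pixel_size_um,
                                    origin_um = c(0, 0), times_s = NULL,
                                    blob_radius_um = 40, intensity = 0.35,
                                    background = 0.85) {
  times_s <- times_s %||% sort(unique(traj$t_s))
  if (nrow(traj) > 0 && !all(times_s %in% traj$t_s)) {
    stop_chemotax("`times_s` must be a subset of the trajectory step times")
  }
  nr <- as.integer(frame_shape[1]); nc <- as.integer(frame_shape[2])
  ps <- pixel_size_um
  r_px <- blob_radius_um / ps
  out <- lapply(times_s, function(t) {
    pts <- traj[traj$t_s == t, ]
    cov <- matrix(0, nr, nc)  # foreground coverage in [0, 1]
    mask <- matrix(FALSE, nr, nc)
    for (k in seq_len(nrow(pts))) {
      cx <- (pts$x_um[k] - origin_um[1]) / ps  # in pixels
      cy <- (pts$y_um[k] - origin_um[2]) / ps
      j0 <- max(1L, floor(cx - r_px - 1)); j1 <- min(nc, ceiling(cx + r_px + 1))
      i0 <- max(1L, floor(cy - r_px - 1)); i1 <- min(nr, ceiling(cy + r_px + 1))
      if (j0 > j1 || i0 > i1) next
      ii <- i0:i1; jj <- j0:j1
      d <- sqrt(outer((ii - 0.5 - cy)^2, (jj - 0.5 - cx)^2, "+"))
      cov[ii, jj] <- pmax(cov[ii, jj], clamp(r_px + 0.5 - d, 0, 1))
      mask[ii, jj] <- mask[ii, jj] | (d <= r_px)
    }
    gray <- background + (intensity - background) * cov
    list(frame = round(gray * 255), mask = mask)
  })
  list(
    stack = image_stack(lapply(out, `[[`, "frame"), times_s, ps, 8L),
    truth_masks = lapply(out, `[[`, "mask")
  )
}
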