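#' Tracer specification
#'
#' Describes a fluorescent tracer: its label, molecular weight, the true
#' diffusion coefficient used when generating synthetic data, and the total
#' released amount (the amplitude of the point-source model).
#'
#' @param name Tracer label.
#' @param molecular_weight_da Molecular weight (Da), > 0.
#' @param true_D Diffusion coefficient (um^2/s), > 0.
#' @param initial_amount Total amount released (arbitrary intensity units).
#' @return A list of class `tracer_spec`.
#' @examples
#' tracer_spec("rhodamine-dextran", 1e4, true_D = 6.393)
#' tracer_spec("albumin-FITC", 6.6e4, true_D = 0.6009)
#' @export
tracer_spec <- function(name, molecular_weight_da, true_D, initial_amount = 1) {
  assert_number(molecular_weight_da, "molecular_weight_da", positive = TRUE)
  assert_number(true_D, "true_D", positive = TRUE)
  assert_number(initial_amount, "initial_amount", positive = TRUE)
  structure(
    list(name = as.character(name),
         molecular_weight_da = molecular_weight_da,
         true_D = true_D,
         initial_amount = initial_amount),
    class = "tracer_spec"
  )
}

#' Simulate tracer diffusion across the chamber
#'
#' Explicit finite-difference solution of the 2D diffusion equation on the
#' chamber raster, with a 5-point stencil and zero-flux (reflecting)
#' boundaries. Each source starts as a uniform unit concentration inside its
#' well disk and zero outside; each tracer diffuses independently with its
#' own coefficient. The conservative flux form of the stencil keeps total
#' mass constant to floating-point rounding. The time step is set to 0.9
#' times the explicit stability limit `h^2 / (4 D)`; requesting a larger
#' step auto-refines it (with a message), or errors in strict mode.
#'
#' @param layout A [chamber_layout()].
#' @param sources Named list mapping well ids to [tracer_spec()]s, e.g.
#'   `list(center = tracer_spec(...))`.
#' @param grid_spacing_um Grid spacing (um); the simulation raster covers
#'   the full chamber extent.
#' @param output_times_s Times (s) at which to store concentration fields;
#'   non-negative, increasing. Time 0 returns the initial condition.
#' @param dt_s Optional explicit time step (s).
#' @param strict If `TRUE`, an unstable requested step is an error instead
#'   of being refined.
#' @param initial_field Optional matrix overriding the well-disk initial
#'   condition (applied to every source; used mainly for equilibrium and
#'   oracle checks).
#' @return An object of class `diffusion_sim`: list with `times_s`,
#'   `fields` (per source, a list of concentration matrices, one per output
#'   time), `grid_spacing_um`, `layout`, `sources`.
#' @export
simulate_chamber_diffusion <- function(layout, sources, grid_spacing_um = 25,
                                       output_times_s = c(0, 10, 20, 30, 40) * 60,
                                       dt_s = NULL, strict = FALSE,
                                       initial_field = NULL) {
  stopifnot(inherits(layout, "chamber_layout"))
  if (is.null(names(sources)) || any(names(sources) == "")) {
    stop_chemotax("`sources` must be a named list: well id -> tracer_spec")
  }
  if (any(diff(output_times_s) <= 0) || any(output_times_s < 0)) {
    stop_chemotax("`output_times_s` must be non-negative and increasing")
  }
  h <- grid_spacing_um
  nr <- as.integer(floor(layout$chamber_extent_um[2] / h))
  nc <- as.integer(floor(layout$chamber_extent_um[1] / h))
  grid_layout <- layout
  grid_layout$pixel_size_um <- h
  fields <- lapply(names(sources), function(well) {
    spec <- sources[[well]]
    stopifnot(inherits(spec, "tracer_spec"))
    D <- spec$true_D
    dt_max <- h^2 / (4 * D)
    dt <- dt_s %||% (0.9 * dt_max)
    if (dt > dt_max) {
      if (strict) {
        stop_chemotax("time step %g s violates the explicit stability limit %g s for D = %g um^2/s",
                      dt, dt_max, D)
      }
      message(sprintf("chemotaxgel: refining unstable time step %g s to %g s (stability limit %g s)",
                      dt, 0.9 * dt_max, dt_max))
      dt <- 0.9 * dt_max
    }
    if (is.null(initial_field)) {
      C <- matrix(0, nr, nc)
      C[well_mask(grid_layout, c(nr, nc), well)] <- 1
    } else {
      stopifnot(identical(dim(initial_field), c(nr, nc)))
      C <- initial_field
    }
    out <- vector("list", length(output_times_s))
    t_now <- 0
    alpha <- D / h^2
    for (k in seq_along(output_times_s)) {
      t_target <- output_times_s[k]
      while (t_now < t_target - 1e-9) {
        step <- min(dt, t_target - t_now)
        # conservative reflecting Laplacian: border neighbors mirror inward
        up <- rbind(C[1, , drop = FALSE], C[-nr, , drop = FALSE])
        down <- rbind(C[-1, , drop = FALSE], C[nr, , drop = FALSE])
        left <- cbind(C[, 1, drop = FALSE], C[, -nc, drop = FALSE])
        right <- cbind(C[, -1, drop = FALSE], C[, nc, drop = FALSE])
        C <- C + step * alpha * (up + down + left + right - 4 * C)
        t_now <- t_now + step
      }
      out[[k]] <- C
    }
    out
  })
  names(fields) <- names(sources)
  structure(
    list(times_s = output_times_s, fields = fields,
         grid_spacing_um = h, layout = grid_layout, sources = sources),
    class = "diffusion_sim"
  )
}

#' Total tracer mass per stored field
#'
#' @param sim A [simulate_chamber_diffusion()] result.
#' @return A tibble with columns `well`, `t_s`, `mass` (concentration sum
#'   times cell area).
#' @export
sim_total_mass <- function(sim) {
  stopifnot(inherits(sim, "diffusion_sim"))
  cell_area <- sim$grid_spacing_um^2
  bind_rows(imap(sim$fields, function(flds, well) {
    tibble(well = well, t_s = sim$times_s,
           mass = map_dbl(flds, sum) * cell_area)
  }))
}

#' Radial transect of a simulated field
#'
#' Samples a stored concentration field along the four principal axes from
#' the source-well center outward and averages them, mirroring the
#' line-profile extraction applied to image stacks.
#'
#' @param sim A [simulate_chamber_diffusion()] result.
#' @param well Source well id.
#' @param time_index Which stored time to sample.
#' @param max_radius_um Transect length from the well center (um).
#' @return A tibble with `r_um` (distance from the well center) and
#'   `concentration`.
#' @export
sim_radial_transect <- function(sim, well, time_index, max_radius_um) {
  stopifnot(inherits(sim, "diffusion_sim"))
  fld <- sim$fields[[well]][[time_index]]
  h <- sim$grid_spacing_um
  pos <- well_position_um(sim$layout, well)
  ic <- pixel_index(pos[2], h); jc <- pixel_index(pos[1], h)
  n <- floor(max_radius_um / h)
  offs <- seq_len(n)
  vals <- (fld[cbind(ic - offs, jc)] + fld[cbind(ic + offs, jc)] +
           fld[cbind(ic, jc - offs)] + fld[cbind(ic, jc + offs)]) / 4
  tibble(r_um = offs * h, concentration = vals)
}
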