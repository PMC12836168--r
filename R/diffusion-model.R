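#' Instantaneous point-source diffusion intensity
#'
#' The one-dimensional solution for an amount `A0` of substance released at
#' the origin at time zero and spreading with diffusion coefficient `D`:
#'
#'   I(x, t) = A0 / sqrt(4 pi D t) * exp(-x^2 / (4 D t))
#'
#' This is the unique closed form in which `A0` is the total amount of
#' diffusing substance, `x` the radial distance from the source and `t` the
#' time since release; it is even in `x`, vanishes as `|x| -> Inf`, and its
#' integral over all `x` equals `A0` at every time (mass conservation).
#' The solution is singular at `t = 0`, so zero or negative times are
#' rejected; injection-time frames are excluded from fits for the same
#' reason.
#'
#' @param x_um Distance from the source (um); vectorized.
#' @param t_s Time since release (s); strictly positive, vectorized.
#' @param D Diffusion coefficient (um^2/s), > 0.
#' @param A0 Total amount of diffusing substance (intensity units).
#' @return Intensity at `(x, t)`, same length as the broadcast of inputs.
#' @examples
#' point_source_intensity(0, t_s = 1 / (4 * pi), D = 1, A0 = 1)  # exactly 1
#' @export
point_source_intensity <- function(x_um, t_s, D, A0 = 1) {
  assert_number(D, "D", positive = TRUE)
  assert_number(A0, "A0")
  if (any(t_s <= 0)) {
    stop_chemotax("`t_s` must be > 0: the point-source solution is singular at t = 0")
  }
  A0 / sqrt(4 * pi * D * t_s) * exp(-x_um^2 / (4 * D * t_s))
}

#' Assemble a spatio-temporal diffusion profile
#'
#' A diffusion profile is the averaged fluorescence intensity as a function
#' of distance from the well rim, one column of values per imaging time
#' point, stored long (one row per `(x, t)` pair) so it pipes cleanly into
#' dplyr and ggplot2.
#'
#' @param x_um Distances from the rim (um). The grid must start at 0 and be
#'   strictly increasing.
#' @param t_s Times since injection (s), one per profile.
#' @param intensity Matrix of intensities (`length(x_um)` rows,
#'   `length(t_s)` columns) or a vector matching the long layout.
#' @param normalized Logical: has each time point been divided by its
#'   intensity at `x = 0`?
#' @return A tibble of class `diffusion_profile` with columns `x_um`, `t_s`,
#'   `intensity`, and attribute `normalized`.
#' @export
diffusion_profile <- function(x_um, t_s, intensity, normalized = FALSE) {
  if (x_um[1] != 0 || any(diff(x_um) <= 0)) {
    stop_chemotax("`x_um` must start at 0 and be strictly increasing")
  }
  nx <- length(x_um); nt <- length(t_s)
  if (is.matrix(intensity)) {
    stopifnot(nrow(intensity) == nx, ncol(intensity) == nt)
  } else {
    stopifnot(length(intensity) == nx * nt)
  }
  long <- tibble(
    x_um = rep(as.double(x_um), times = nt),
    t_s = rep(as.double(t_s), each = nx),
    intensity = as.vector(as.double(intensity))
  )
  if (any(long$intensity < 0)) stop_chemotax("intensities must be non-negative")
  new_diffusion_profile(long, normalized = normalized)
}

new_diffusion_profile <- function(df, normalized) {
  attr(df, "normalized") <- isTRUE(normalized)
  class(df) <- unique(c("diffusion_profile", class(df)))
  df
}

is_normalized <- function(profile) isTRUE(attr(profile, "normalized"))

#' Normalize a diffusion profile to its rim intensity
#'
#' Divides each time point's intensities by the intensity at `x = 0` for
#' that time point, the convention used when comparing gradient shapes
#' across tracers. Time points whose rim intensity is zero cannot be
#' normalized and are dropped with a warning. The operation is idempotent.
#'
#' @param profile A [diffusion_profile()].
#' @return A normalized `diffusion_profile` (`intensity` at `x = 0` is 1 for
#'   every retained time point).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "diffusion_profile"))
  out <- profile |>
    group_by(.data$t_s) |>
    mutate(.i0 = .data$intensity[.data$x_um == 0][1]) |>
    ungroup()
  bad <- unique(out$t_s[out$.i0 <= 0])
  if (length(bad) > 0) {
    warn_chemotax("dropping %d time point(s) with zero rim intensity: t = %s s",
                  length(bad), paste(bad, collapse = ", "))
    out <- out[!(out$t_s %in% bad), ]
  }
  out <- out |> mutate(intensity = .data$intensity / .data$.i0) |> select(-".i0")
  new_diffusion_profile(out, normalized = TRUE)
}

#' Fit the diffusion coefficient to a spatio-temporal profile
#'
#' Least-squares fit of the point-source model jointly over all `(x, t)`
#' pairs ("full spatial and temporal dataset"). On normalized profiles the
#' model reduces to `exp(-x^2 / (4 D t))` and only `D` is estimated. On
#' un-normalized profiles the amplitude `A0` enters linearly, so for any
#' candidate `D` its optimal value has a closed form and is profiled out;
#' the problem is one-dimensional in `D` either way. The sum of squares is
#' minimized by a deterministic log-spaced grid scan over the search bounds
#' followed by Brent refinement, so the fit has no random element and no
#' starting-value sensitivity.
#'
#' Frames at `t <= 0` are excluded (the model is singular at the injection
#' time). A profile with (numerically) no spatial variation leaves `D`
#' unidentifiable; the fit is then flagged ill-posed.
#'
#' @param profile A [diffusion_profile()].
#' @param times_used Optional subset of times (s) to fit on; default all
#'   positive times.
#' @param bounds Search interval for `D` (um^2/s), default `c(1e-4, 1e4)`.
#' @return An object of class `diffusion_fit`: list with `D_hat` (um^2/s),
#'   `A0_hat` (NA for normalized fits), `rss`, `n_points`, `normalized`,
#'   `ill_posed`, and the fitted data with a `fitted` column.
#' @examples
#' x <- seq(0, 500, by = 10)
#' t <- c(10, 20, 30, 40) * 60
#' I <- outer(x, t, function(x, t) point_source_intensity(x, t, D = 6.393))
#' pr <- normalize_profile(diffusion_profile(x, t, I))
#' fit_diffusion_coefficient(pr)$D_hat
#' @export
fit_diffusion_coefficient <- function(profile, times_used = NULL,
                                      bounds = c(1e-4, 1e4)) {
  stopifnot(inherits(profile, "diffusion_profile"))
  df <- as_tibble(profile)
  df <- df[df$t_s > 0, ]
  if (!is.null(times_used)) df <- df[df$t_s %in% times_used, ]
  tpts <- unique(df$t_s)
  if (length(tpts) < 2L) stop_chemotax("need >= 2 positive time points to fit")
  if (length(unique(df$x_um)) < 5L) stop_chemotax("need >= 5 distances to fit")
  normalized <- is_normalized(profile)
  x <- df$x_um; t <- df$t_s; y <- df$intensity
  if (stats::sd(y) < 1e-12 * max(mean(y), 1)) {
    warn_chemotax("flat profile: D is unidentifiable (ill-posed fit)")
    fit <- list(D_hat = NA_real_, A0_hat = NA_real_, rss = NA_real_,
                n_points = nrow(df), normalized = normalized,
                ill_posed = TRUE, data = df)
    class(fit) <- "diffusion_fit"
    return(fit)
  }
  sse_of <- function(D) {
    if (normalized) {
      m <- exp(-x^2 / (4 * D * t))
      sum((y - m)^2)
    } else {
      f <- exp(-x^2 / (4 * D * t)) / sqrt(4 * pi * D * t)
      a <- sum(f * y) / sum(f * f)   # profiled amplitude
      sum((y - a * f)^2)
    }
  }
  lg <- seq(log10(bounds[1]), log10(bounds[2]), length.out = 201L)
  sse_grid <- vapply(lg, function(l) sse_of(10^l), numeric(1))
  k <- which.min(sse_grid)
  lo <- lg[max(1L, k - 1L)]; hi <- lg[min(length(lg), k + 1L)]
  opt <- stats::optimize(function(l) sse_of(10^l), c(lo, hi), tol = 1e-12)
  D_hat <- 10^opt$minimum
  if (normalized) {
    A0_hat <- NA_real_
    fitted <- exp(-x^2 / (4 * D_hat * t))
  } else {
    f <- exp(-x^2 / (4 * D_hat * t)) / sqrt(4 * pi * D_hat * t)
    A0_hat <- sum(f * y) / sum(f * f)
    fitted <- A0_hat * f
  }
  fit <- list(
    D_hat = D_hat, A0_hat = A0_hat,
    rss = sum((y - fitted)^2), n_points = nrow(df),
    normalized = normalized, ill_posed = FALSE,
    data = mutate(df, fitted = fitted)
  )
  class(fit) <- "diffusion_fit"
  fit
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("<diffusion_fit>\n")
  if (x$ill_posed) {
    cat("  ill-posed (flat profile); D unidentifiable\n")
  } else {
    cat(sprintf("  D_hat = %.4g um^2/s  (%s profiles, %d points, RSS = %.3g)\n",
                x$D_hat, if (x$normalized) "normalized" else "absolute",
                x$n_points, x$rss))
    if (!is.na(x$A0_hat)) cat(sprintf("  A0_hat = %.4g intensity units\n", x$A0_hat))
  }
  invisible(x)
}

#' Tidy a diffusion fit
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`,
#'   `estimate`).
#' @export
tidy.diffusion_fit <- function(x, ...) {
  terms <- tibble(term = "D", estimate = x$D_hat, unit = "um^2/s")
  if (!x$normalized && !is.na(x$A0_hat)) {
    terms <- bind_rows(terms,
                       tibble(term = "A0", estimate = x$A0_hat, unit = "intensity"))
  }
  terms
}

#' One-row summary of a diffusion fit
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `D_hat`, `A0_hat`, `rss`, `n_points`,
#'   `normalized`, `ill_posed`.
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D_hat = x$D_hat, A0_hat = x$A0_hat, rss = x$rss,
         n_points = x$n_points, normalized = x$normalized,
         ill_posed = x$ill_posed)
}

#' Extract averaged line profiles around a well
#'
#' Draws four line profiles from the well rim outward into the gel along the
#' north, south, east and west axes, samples them at pixel resolution, and
#' averages the four directions pointwise into a single profile per frame.
#' `x = 0` is anchored at the rim pixel (the pixel whose center is nearest
#' the rim along each axis); the sample count along each ray is
#' `floor(length_um / pixel_size) + 1`.
#'
#' @param stack An [image_stack()].
#' @param layout A [chamber_layout()] giving the well position in physical
#'   coordinates (`pixel_size_um` is taken from the stack).
#' @param well Well id.
#' @param length_um Profile length beyond the rim (um), default 500.
#' @param strict If `TRUE`, rays leaving the raster are an error; otherwise
#'   they are truncated with a warning.
#' @param directions Which of the four rim rays to average (default all
#'   four); a subset quantifies how much directional averaging suppresses
#'   noise.
#' @return A [diffusion_profile()] with one time point per frame (frames at
#'   the stack's timestamps).
#' @export
extract_line_profiles <- function(stack, layout, well = "center",
                                  length_um = 500, strict = FALSE,
                                  directions = c("north", "south", "east", "west")) {
  stopifnot(inherits(stack, "image_stack"), inherits(layout, "chamber_layout"))
  ps <- stack$pixel_size_um
  pos <- well_position_um(layout, well)
  nr <- nrow(stack$frames[[1]]); nc <- ncol(stack$frames[[1]])
  ic <- pixel_index(pos[2], ps); jc <- pixel_index(pos[1], ps)
  r_px <- round(layout$well_radius_um / ps)
  n_samp <- floor(length_um / ps) + 1L
  offs <- r_px + seq_len(n_samp) - 1L
  max_off <- max(offs)
  room <- c(ic - 1L, nr - ic, jc - 1L, nc - jc)  # N, S, W, E
  if (any(room < max_off)) {
    if (strict) {
      stop_chemotax("line profiles of %g um exit the raster (need %d px beyond the center, have %s)",
                    length_um, max_off, paste(room, collapse = "/"))
    }
    keep <- offs <= min(room)
    warn_chemotax("truncating line profiles from %d to %d samples at the raster edge",
                  n_samp, sum(keep))
    offs <- offs[keep]
    n_samp <- length(offs)
  }
  directions <- match.arg(directions, several.ok = TRUE)
  x_um <- (offs - r_px) * ps
  ray_idx <- list(
    north = cbind(ic - offs, jc), south = cbind(ic + offs, jc),
    west = cbind(ic, jc - offs), east = cbind(ic, jc + offs)
  )[directions]
  prof <- vapply(stack$frames, function(fr) {
    rays <- vapply(ray_idx, function(ix) fr[ix], numeric(n_samp))
    rowMeans(matrix(rays, nrow = n_samp))
  }, numeric(n_samp))
  diffusion_profile(x_um, stack$timestamps_s, matrix(prof, nrow = n_samp))
}

#' Write a diffusion profile to CSV
#'
#' Columns: `x_um`, `t_s`, `intensity`, `normalized`.
#'
#' @param profile A [diffusion_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as_tibble(profile)
  df$normalized <- is_normalized(profile)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a diffusion profile from CSV
#' @param path CSV written by [write_profile_csv()].
#' @return A [diffusion_profile()].
#' @export
read_profile_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  x <- sort(unique(df$x_um))
  t <- sort(unique(df$t_s))
  df <- df[order(df$t_s, df$x_um), ]
  diffusion_profile(x, t, df$intensity,
                    normalized = isTRUE(all(df$normalized)))
}
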