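#' Construct a frequency-sweep table
#'
#' Validates and normalizes a rheometer frequency sweep (oscillatory shear,
#' constant strain within the linear viscoelastic region).
#'
#' @param frequency_hz Ascending oscillation frequencies (Hz).
#' @param g_prime_pa Storage modulus G' at each frequency (Pa).
#' @param g_double_prime_pa Loss modulus G'' at each frequency (Pa).
#' @param replicate Replicate label (recycled).
#' @return A tibble of class `frequency_sweep` with columns `frequency_hz`,
#'   `g_prime_pa`, `g_double_prime_pa`, `replicate`.
#' @export
frequency_sweep <- function(frequency_hz, g_prime_pa, g_double_prime_pa,
                            replicate = "r1") {
  rep_id <- rep_len(as.character(replicate), length(frequency_hz))
  increasing <- vapply(split(frequency_hz, rep_id),
                       function(f) all(diff(f) > 0), logical(1))
  if (!all(increasing)) {
    stop_chemotax("`frequency_hz` must be strictly increasing within each replicate")
  }
  if (any(g_prime_pa <= 0) || any(g_double_prime_pa < 0)) {
    stop_chemotax("G' must be positive and G'' non-negative")
  }
  out <- tibble(
    frequency_hz = as.double(frequency_hz),
    g_prime_pa = as.double(g_prime_pa),
    g_double_prime_pa = as.double(g_double_prime_pa),
    replicate = rep_id
  )
  class(out) <- c("frequency_sweep", class(out))
  out
}

#' Construct a strain-amplitude sweep table
#'
#' @param strain_pct Ascending strain amplitudes (percent).
#' @param g_prime_pa Storage modulus at each amplitude (Pa).
#' @param g_double_prime_pa Optional loss modulus (Pa).
#' @return A tibble of class `strain_sweep`.
#' @export
strain_sweep <- function(strain_pct, g_prime_pa, g_double_prime_pa = NA_real_) {
  if (any(diff(strain_pct) <= 0)) {
    stop_chemotax("`strain_pct` must be strictly increasing")
  }
  if (any(g_prime_pa <= 0)) stop_chemotax("moduli must be positive")
  out <- tibble(
    strain_pct = as.double(strain_pct),
    g_prime_pa = as.double(g_prime_pa),
    g_double_prime_pa = as.double(g_double_prime_pa)
  )
  class(out) <- c("strain_sweep", class(out))
  out
}

#' Locate the linear viscoelastic region (LVER) of a strain sweep
#'
#' The LVER is the leading strain range over which G' is amplitude
#' independent. The low-strain plateau is estimated as the median of the
#' first three points; the region extends over the longest run of leading
#' amplitudes whose G' stays within `tolerance` (relative) of that plateau.
#' A fixed working strain is recommended as the log-scale midpoint of the
#' region, matching how a sweep is used to pick the strain for a subsequent
#' frequency sweep.
#'
#' @param sweep A [strain_sweep()] (or data frame with `strain_pct`,
#'   `g_prime_pa`).
#' @param tolerance Allowed relative deviation of G' from the plateau
#'   (default 0.05).
#' @return A one-row tibble: `strain_min_pct`, `strain_max_pct`,
#'   `recommended_strain_pct`, `plateau_g_prime_pa`, `n_points`. When no
#'   leading point stays within tolerance the tibble has zero rows and a
#'   warning explains the diagnosis.
#' @export
find_lver <- function(sweep, tolerance = 0.05) {
  if (nrow(sweep) < 5L) stop_chemotax("a strain sweep needs >= 5 amplitudes")
  assert_number(tolerance, "tolerance", non_negative = TRUE)
  g <- sweep$g_prime_pa
  plateau <- stats::median(g[1:3])
  ok <- abs(g - plateau) <= tolerance * plateau
  if (!ok[1]) {
    warn_chemotax(
      "no linear viscoelastic plateau: G' already deviates > %g%% from the low-strain plateau (%g Pa) at the first amplitude",
      100 * tolerance, plateau)
    return(tibble(
      strain_min_pct = double(), strain_max_pct = double(),
      recommended_strain_pct = double(), plateau_g_prime_pa = double(),
      n_points = integer()
    ))
  }
  last <- if (all(ok)) length(ok) else which(!ok)[1] - 1L
  rng <- sweep$strain_pct[c(1L, last)]
  tibble(
    strain_min_pct = rng[1],
    strain_max_pct = rng[2],
    recommended_strain_pct = 10^mean(log10(rng)),
    plateau_g_prime_pa = plateau,
    n_points = last
  )
}

#' Interpolate moduli at a target frequency
#'
#' Returns G' and G'' at frequency `f` by log-log linear interpolation
#' between the bracketing measured frequencies (moduli-frequency relations
#' of collagen gels are near power-law, so interpolation is linear in
#' log-log space). Exact table values are returned when `f` is a grid point.
#' No extrapolation is performed.
#'
#' @param sweep A [frequency_sweep()] holding a single replicate.
#' @param f Target frequency (Hz), within the sweep range.
#' @param log_log Interpolate in log-log space (default) or linearly.
#' @return A one-row tibble: `frequency_hz`, `g_prime_pa`,
#'   `g_double_prime_pa`.
#' @export
moduli_at_frequency <- function(sweep, f, log_log = TRUE) {
  assert_number(f, "f", positive = TRUE)
  fr <- sweep$frequency_hz
  if (f < min(fr) || f > max(fr)) {
    stop_chemotax("frequency %g Hz is outside the sweep range [%g, %g] Hz; refusing to extrapolate",
                  f, min(fr), max(fr))
  }
  interp <- function(y) {
    if (any(fr == f)) return(y[which(fr == f)[1]])
    if (log_log) {
      exp(stats::approx(log(fr), log(y), xout = log(f))$y)
    } else {
      stats::approx(fr, y, xout = f)$y
    }
  }
  tibble(
    frequency_hz = f,
    g_prime_pa = interp(sweep$g_prime_pa),
    g_double_prime_pa = interp(sweep$g_double_prime_pa)
  )
}

#' Viscoelastic summary at a reporting frequency
#'
#' Reduces replicate frequency sweeps to the standard hydrogel summary:
#' mean and standard deviation of G' and G'' at the reporting frequency
#' (default 1 Hz), the loss tangent tan(delta) = G''/G' computed from the
#' mean moduli, and the dynamic Young's modulus under linear isotropy,
#' E' = 2 G' (1 + nu). With the near-incompressibility assumption nu = 0.5
#' this reduces to E' = 3 G'. Uncertainty in E' is propagated from the
#' replicate variability of G': sd(E') = 2 (1 + nu) sd(G').
#'
#' @param sweeps A [frequency_sweep()] tibble; replicates are distinguished
#'   by the `replicate` column.
#' @param frequency_hz Reporting frequency (Hz), default 1.
#' @param nu Poisson's ratio (default 0.5, near-incompressible hydrated
#'   collagen network).
#' @return A one-row tibble of class `rheology_summary`: `g_prime_pa`,
#'   `g_prime_sd_pa`, `g_double_prime_pa`, `g_double_prime_sd_pa`,
#'   `loss_tangent`, `poisson_ratio`, `e_prime_pa`, `e_prime_sd_pa`,
#'   `frequency_hz`, `n_replicates`. The per-replicate loss tangents are
#'   attached as attribute `replicate_loss_tangents`.
#' @examples
#' sw <- frequency_sweep(c(0.1, 1, 10), c(400, 460, 520), c(70, 75, 80))
#' summarize_rheology(sw)
#' @export
summarize_rheology <- function(sweeps, frequency_hz = 1, nu = 0.5) {
  assert_number(nu, "nu", non_negative = TRUE)
  reps <- split(sweeps, sweeps$replicate)
  if (length(reps) < 1L) stop_chemotax("at least one replicate sweep is required")
  at_f <- bind_rows(lapply(reps, moduli_at_frequency, f = frequency_hz))
  gp <- at_f$g_prime_pa
  gpp <- at_f$g_double_prime_pa
  out <- tibble(
    g_prime_pa = mean(gp),
    g_prime_sd_pa = stats::sd(gp),
    g_double_prime_pa = mean(gpp),
    g_double_prime_sd_pa = stats::sd(gpp),
    loss_tangent = mean(gpp) / mean(gp),
    poisson_ratio = nu,
    e_prime_pa = 2 * mean(gp) * (1 + nu),
    e_prime_sd_pa = 2 * (1 + nu) * stats::sd(gp),
    frequency_hz = frequency_hz,
    n_replicates = length(reps)
  )
  attr(out, "replicate_loss_tangents") <- unname(gpp / gp)
  class(out) <- c("rheology_summary", class(out))
  out
}

#' Read a rheometer sweep table from CSV
#'
#' Expected columns: `frequency_hz` (or `strain_pct`), `g_prime_pa`,
#' `g_double_prime_pa`, optionally `replicate`.
#'
#' @param path CSV file path.
#' @return A [frequency_sweep()] or [strain_sweep()] depending on columns.
#' @export
read_sweep_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("frequency_hz" %in% names(df)) {
    df <- df[order(df$replicate %||% "r1", df$frequency_hz), ]
    frequency_sweep(df$frequency_hz, df$g_prime_pa, df$g_double_prime_pa,
                    replicate = df$replicate %||% "r1")
  } else if ("strain_pct" %in% names(df)) {
    strain_sweep(df$strain_pct, df$g_prime_pa,
                 df$g_double_prime_pa %||% NA_real_)
  } else {
    stop_chemotax("sweep CSV must contain a `frequency_hz` or `strain_pct` column")
  }
}
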