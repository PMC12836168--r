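# Shared fixtures. Classifiers are trained once per session and memoized;
# everything is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

paper_layout <- function() chamber_layout()

get_confluency_classifier <- function() {
  memo("confluency_clf", train_confluency_classifier(seed = 11))
}

get_migration_classifier <- function() {
  memo("migration_clf", train_migration_classifier(paper_layout(), seed = 11))
}

# preprocessing chain shared by confluency-style fixtures
confluency_preprocess <- function(img) {
  enhance_contrast(rolling_ball_subtract(to_8bit(img), 6, TRUE), 0.35, TRUE)
}

# replicate frequency sweeps whose 1 Hz moduli have exactly the requested
# mean and sd (offsets -s, 0, +s have unit sd)
sweeps_with_moduli <- function(gp_mean, gp_sd, gpp_mean, gpp_sd) {
  gp <- gp_mean + c(-1, 0, 1) * gp_sd
  gpp <- gpp_mean + c(-1, 0, 1) * gpp_sd
  dplyr::bind_rows(lapply(1:3, function(i) {
    frequency_sweep(c(0.1, 1, 10), rep(gp[i], 3), rep(gpp[i], 3),
                    replicate = paste0("r", i))
  }))
}

# noiseless normalized spatio-temporal profile from the point-source model
analytic_profile <- function(D, x_um = seq(0, 500, by = 10),
                             t_s = c(10, 20, 30, 40) * 60) {
  I <- outer(x_um, t_s, function(x, t) point_source_intensity(x, t, D = D))
  normalize_profile(diffusion_profile(x_um, t_s, I))
}

# independent Yen criterion: explicit loop over all 256 candidate levels
yen_bruteforce <- function(levels_0_255) {
  counts <- tabulate(levels_0_255 + 1L, nbins = 256L)
  p <- counts / sum(counts)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:255) {
    P <- sum(p[seq_len(t + 1L)])
    if (P <= 0 || P >= 1) next
    P2 <- sum(p[seq_len(t + 1L)]^2)
    P2b <- sum(p[(t + 2L):256L]^2)
    if (P2 <= 0 || P2b <= 0) next
    crit <- -log(P2 * P2b) + 2 * log(P * (1 - P))
    if (crit > best + 1e-12) { best <- crit; best_t <- t }
  }
  best_t
}
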