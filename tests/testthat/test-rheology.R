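test_that("a flat strain sweep returns the full range as LVER", {
  sw <- strain_sweep(10^seq(-2, 1, length.out = 12), rep(500, 12))
  lver <- find_lver(sw)
  expect_equal(lver$strain_min_pct, 0.01)
  expect_equal(lver$strain_max_pct, 10)
  expect_equal(lver$n_points, 12L)
  # zero tolerance keeps only exactly-plateau points
  expect_equal(find_lver(sw, tolerance = 0)$n_points, 12L)
})

test_that("LVER ends at the last point within tolerance of the plateau", {
  strains <- 10^seq(-2, 1, length.out = 20)
  g <- ifelse(strains <= 1, 500, 500 * (strains / 1)^-0.4)  # flat then power-law decay
  sw <- strain_sweep(strains, g)
  lver <- find_lver(sw, tolerance = 0.05)
  # independent direct scan
  plateau <- stats::median(g[1:3])
  ok <- abs(g - plateau) <= 0.05 * plateau
  last_ok <- which(!ok)[1] - 1L
  expect_equal(lver$strain_max_pct, strains[last_ok])
  expect_equal(lver$n_points, last_ok)
  expect_true(lver$recommended_strain_pct >= lver$strain_min_pct &&
                lver$recommended_strain_pct <= lver$strain_max_pct)
})

test_that("a sweep with no plateau yields an empty LVER with a diagnostic", {
  strains <- 10^seq(-2, 1, length.out = 10)
  g <- 500 * strains^-0.5  # monotone decline from the start
  expect_warning(lver <- find_lver(strain_sweep(strains, g)), "plateau")
  expect_equal(nrow(lver), 0L)
})

test_that("moduli interpolation is exact on grid points and for power laws", {
  f <- c(0.1, 0.3, 1, 3, 10)
  sw <- frequency_sweep(f, 400 * f^0.17, 60 * f^0.12)
  at1 <- moduli_at_frequency(sw, 1)
  expect_identical(at1$g_prime_pa, 400)
  # power law is linear in log-log space, so interpolation is exact
  at <- moduli_at_frequency(sw, 0.7)
  expect_equal(at$g_prime_pa, 400 * 0.7^0.17, tolerance = 1e-10)
  expect_equal(at$g_double_prime_pa, 60 * 0.7^0.12, tolerance = 1e-10)
  expect_error(moduli_at_frequency(sw, 0.05), "outside")
  expect_error(moduli_at_frequency(sw, 20), "outside")
})

test_that("summary reproduces the identity E' = 3 G' for an incompressible gel", {
  set.seed(42)
  for (gp in runif(5, 50, 5000)) {
    s <- summarize_rheology(frequency_sweep(c(0.5, 1, 2), rep(gp, 3), rep(gp / 6, 3)),
                            nu = 0.5)
    expect_equal(s$e_prime_pa, 3 * gp, tolerance = 1e-12)
  }
})

test_that("loss tangent and moduli limits behave", {
  s0 <- summarize_rheology(frequency_sweep(c(0.5, 1, 2), rep(300, 3), rep(0, 3)))
  expect_equal(s0$loss_tangent, 0)
  s2 <- summarize_rheology(frequency_sweep(c(0.5, 1, 2), rep(300, 3), rep(30, 3)),
                           nu = 0)
  expect_equal(s2$e_prime_pa, 2 * 300)
  # predominantly elastic gels: tan delta < 1 iff G' > G''
  s <- summarize_rheology(sweeps_with_moduli(460.78, 141.09, 74.69, 32.96))
  expect_true(s$loss_tangent < 1)
  expect_true(s$g_prime_pa > s$g_double_prime_pa)
})

test_that("summary is invariant to replicate order and exposes per-replicate ratios", {
  sw <- sweeps_with_moduli(460.78, 141.09, 74.69, 32.96)
  rev_sw <- dplyr::arrange(sw, dplyr::desc(replicate), frequency_hz)
  s1 <- summarize_rheology(sw)
  s2 <- summarize_rheology(frequency_sweep(rev_sw$frequency_hz, rev_sw$g_prime_pa,
                                           rev_sw$g_double_prime_pa, rev_sw$replicate))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_length(attr(s1, "replicate_loss_tangents"), 3L)
})

test_that("sweep CSV round-trips through read_sweep_csv", {
  sw <- sweeps_with_moduli(460.78, 141.09, 74.69, 32.96)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sw, path)
  back <- read_sweep_csv(path)
  expect_s3_class(back, "frequency_sweep")
  expect_equal(sort(back$g_prime_pa), sort(sw$g_prime_pa))
})
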