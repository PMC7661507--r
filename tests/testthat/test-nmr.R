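## a small always-positive "exchange" generator standing in for K = 0:
## rates scaled to epsilon keep p_eq well defined without moving magnetization
eps_generator <- function(p1 = 0.5, eps = 1e-8) {
  K <- matrix(c(-eps * (1 - p1), eps * p1,
                 eps * (1 - p1), -eps * p1), 2, 2, byrow = TRUE)
  generator_matrix(K, c("P", "PH"))
}

lorentz <- function(om, x0, R2) R2 / (R2^2 + (om - x0)^2)   # area pi

test_that("single-state FID decays at R2 and gives a Lorentzian of FWHH 2*R2", {
  gen <- generator_matrix(matrix(0 * 1e-12, 1, 1), "P")
  spin <- spin_system(c(P = 40), c(P = 5))
  fid <- bm_fid(spin, gen, t_grid = seq(0, 2, length.out = 4000))
  amp <- sqrt(fid$re^2 + fid$im^2)
  expect_equal(amp, exp(-5 * fid$t), tolerance = 1e-9)
  ## phase evolves at -omega0 (our sign convention): re = exp(-R2 t) cos(w t)
  expect_equal(fid$re, exp(-5 * fid$t) * cos(40 * fid$t), tolerance = 1e-9)
  om <- seq(-60, 140, length.out = 600)
  sp <- fid_to_spectrum(fid, om)
  pk <- fit_lorentzian_projections(sp, detect_bimodal = FALSE)
  expect_equal(pk$omega0, 40, tolerance = 1e-3)
  expect_equal(pk$fwhh, 2 * 5, tolerance = 1e-2)
})

test_that("no-exchange limit is the population-weighted sum of Lorentzians", {
  gen <- eps_generator(p1 = 0.3)
  spin <- spin_system(c(P = -50, PH = 70), c(P = 6, PH = 9))
  om <- seq(-150, 170, length.out = 800)
  sp <- bm_spectrum_resolvent(spin, gen, om)
  want <- 0.3 * lorentz(om, -50, 6) + 0.7 * lorentz(om, 70, 9)
  expect_equal(sp$intensity, want, tolerance = 1e-5)
})

test_that("fast exchange collapses to one line at the weighted mean shift", {
  dw <- 120
  kex <- 100 * dw
  p1 <- 0.35
  K <- matrix(c(-kex * (1 - p1), kex * p1,
                 kex * (1 - p1), -kex * p1), 2, 2, byrow = TRUE)
  gen <- generator_matrix(K, c("P", "PH"))
  spin <- spin_system(c(P = 0, PH = dw), c(P = 6, PH = 6))
  om <- seq(-100, 220, length.out = 900)
  sp <- bm_spectrum_resolvent(spin, gen, om)
  pk <- fit_lorentzian_projections(sp)
  expect_false(pk$bimodal)
  w_mean <- (1 - p1) * dw   # population-weighted mean (p_eq[PH] = 1 - p1)
  expect_lt(abs(pk$omega0 - w_mean) / dw, 0.01)
})

test_that("quadrature spectra agree with the resolvent closed form", {
  rs <- default_rates()
  conc <- solve_species_concentrations(20e-6, 10e-6, rs)
  gen <- build_K4P(rs, conc)
  spin <- default_spin_system()
  om <- seq(-80, 220, length.out = 500)
  fid <- bm_fid(spin, gen,
                t_grid = seq(0, 12 / min(spin$R2), by = pi / (4 * 250)))
  sp_q <- fid_to_spectrum(fid, om)
  sp_r <- bm_spectrum_resolvent(spin, gen, om)
  expect_lt(max(abs(sp_q$intensity - sp_r$intensity)) /
              max(sp_r$intensity), 1e-3)
  ## zero signal transforms to zero
  fid0 <- fid; fid0$re <- 0; fid0$im <- 0
  expect_true(all(fid_to_spectrum(fid0, om)$intensity == 0))
  ## aliasing is detected
  coarse <- fid[seq(1, nrow(fid), by = 50), ]
  expect_error(fid_to_spectrum(coarse, seq(-4000, 4000, length.out = 10)),
               "aliasing")
})

test_that("spectral area is conserved under exchange-rate changes", {
  spin <- default_spin_system()
  om <- seq(-300, 500, length.out = 2000)
  area <- vapply(c(1, 100, 10000), function(f) {
    rs <- rate_set(1.45e9 * f, 1.7 * f, 0.53e9 * f, 1.9e3 * f,
                   0.53e9 * f, 6.36e3 * f)
    conc <- solve_species_concentrations(20e-6, 10e-6, rs)
    sp <- bm_spectrum_resolvent(spin, build_K4P(rs, conc), om)
    sum(sp$intensity) * mean(diff(om))
  }, numeric(1))
  expect_equal(area / area[1], rep(1, 3), tolerance = 1e-2)
})

test_that("Lorentzian projection fits round-trip a simulated titration", {
  rs <- default_rates()
  spin <- default_spin_system()
  tl <- titration_lineshapes(rs, spin, 20e-6, c(0, 5e-6, 10e-6, 20e-6, 40e-6),
                             model = "4state")
  pk <- fit_lorentzian_projections(tl$spectra)
  ## centers move monotonically from the free towards the bound resonance
  expect_equal(pk$omega0[1], 0, tolerance = 1)
  expect_true(all(diff(pk$omega0) > -1e-6))
  ## fitted centers agree with the population-weighted model prediction
  pred <- vapply(seq_len(nrow(tl$populations)), function(i)
    sum(spin$omega0[colnames(tl$populations)] * tl$populations[i, ]),
    numeric(1))
  expect_equal(pk$omega0, pred, tolerance = 0.05)
  ## constant background does not move the fitted parameters
  sp <- tl$spectra[[3]]
  sp_bg <- sp; sp_bg$intensity <- sp_bg$intensity + 0.002
  pk1 <- fit_lorentzian_projections(sp, detect_bimodal = FALSE)
  pk2 <- fit_lorentzian_projections(sp_bg, detect_bimodal = FALSE)
  expect_equal(pk1$omega0, pk2$omega0, tolerance = 1e-2)
})

test_that("state frequencies are recovered from peak-position titrations", {
  spin <- default_spin_system()
  rs <- default_rates()
  grid <- c(2e-6, 5e-6, 10e-6, 20e-6, 40e-6, 80e-6)
  p_eq_list <- lapply(grid, function(ch) {
    conc <- solve_species_concentrations(20e-6, ch, rs)
    build_K4P(rs, conc)$p_eq
  })
  truth <- spin$omega0
  meas <- vapply(p_eq_list, function(p) sum(truth[names(p)] * p), numeric(1))
  ## exact data: chi^2 = 0 and exact recovery
  est <- estimate_state_shifts(meas, p_eq_list, truth[["P"]])
  expect_true(est$identifiable)
  expect_equal(est$chisq, 0, tolerance = 1e-12)
  expect_equal(est$omega0[["PH"]], truth[["PH"]], tolerance = 1e-6)
  ## noisy recovery within 3 s.e.
  set.seed(24)
  meas_n <- meas + stats::rnorm(length(meas), 0, 0.5)
  est_n <- estimate_state_shifts(meas_n, p_eq_list, truth[["P"]])
  expect_lt(abs(est_n$omega0[["PH"]] - truth[["PH"]]),
            3 * est_n$se[["PH"]] + 1e-9)
  ## degenerate design: only P populated
  p_only <- lapply(1:4, function(i) c(P = 1, PH = 0, PPH = 0, PHH = 0))
  est_d <- estimate_state_shifts(rep(0, 4), p_only, 0)
  expect_false(est_d$identifiable)
})

test_that("relaxation rates derive from line widths with shared bound values", {
  r2 <- r2_from_fwhh(10, 16)
  expect_equal(r2[["P"]], 5)
  expect_equal(unname(r2[c("PH", "PPH", "PHH")]), rep(8, 3))
  ## round trip: a single-state line of width 2*R2 returns R2
  gen <- generator_matrix(matrix(0, 1, 1), "P")
  spin <- spin_system(c(P = 0), c(P = r2[["P"]]))
  fid <- bm_fid(spin, gen, t_grid = seq(0, 2, by = pi / (4 * 100)))
  pk <- fit_lorentzian_projections(
    fid_to_spectrum(fid, seq(-200, 200, length.out = 1200)),
    detect_bimodal = FALSE)
  expect_equal(r2_from_fwhh(pk$fwhh)[["P"]], r2[["P"]], tolerance = 2e-2)
})

test_that("two-state lineshapes are bimodal, four-state unimodal, at NMR concentrations", {
  rs <- default_rates()
  spin <- default_spin_system()
  grid <- c(5e-6, 10e-6)   # sub-stoichiometric: both populations present
  two <- titration_lineshapes(rs, spin, 20e-6, grid, model = "2state")
  four <- titration_lineshapes(rs, spin, 20e-6, grid, model = "4state")
  pk2 <- fit_lorentzian_projections(two$spectra)
  pk4 <- fit_lorentzian_projections(four$spectra)
  expect_true(all(pk2$bimodal))
  expect_false(any(pk4$bimodal))
  ## populations used are exactly the equilibrium module's
  conc <- solve_species_concentrations(20e-6, 10e-6, rs)
  expect_equal(four$populations[2, ], build_K4P(rs, conc)$p_eq,
               tolerance = 1e-12)
})

test_that("sensitivity metric is zero at the reference and grows with perturbation", {
  base <- list(rates = default_rates(), spin = default_spin_system(),
               c_P_tot = 20e-6, c_H_tot_grid = c(10e-6, 20e-6))
  sc <- sensitivity_scan(base, list(k_off_PPH = c(1, 1.5, 2.5, 4)))
  expect_equal(sc$l2[1], 0, tolerance = 1e-12)
  expect_true(all(diff(sc$l2) > 0))
})
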