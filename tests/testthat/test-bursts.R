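test_that("burst selection follows the two-pass rules exactly", {
  expect_equal(nrow(select_bursts(numeric(0), character(0))), 0)
  ## hand-built stream: 150 photons spaced 1.5 us (span 223.5 us), a 1 ms
  ## gap, then 60 photons spaced 1.5 us. Burst 1 has >100 photons; its
  ## slices [0,100us) and [100,200us) hold 67 photons each (> 50, kept)
  ## while [200,300us) holds 16 (dropped). Burst 2 (60 photons) fails the
  ## >100-photon cut entirely.
  t1 <- (0:149) * 1.5e-6
  t2 <- max(t1) + 1e-3 + (0:59) * 1.5e-6
  times <- c(t1, t2)
  ch <- rep(c("D", "A"), length.out = length(times))
  b <- select_bursts(times, ch)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_D + b$n_A, c(67, 67))
  expect_equal(b$start, c(0, 1e-4), tolerance = 1e-12)
  expect_true(all(b$parent_burst == b$parent_burst[1]))
  ## photons separated by exactly 30 us are NOT merged (strict less-than)
  t_exact <- c(0, 30e-6 * (1:200))
  b_exact <- select_bursts(t_exact, rep("D", length(t_exact)))
  expect_equal(nrow(b_exact), 0)   # 201 singleton bursts, none above 100
  ## just under the threshold they merge into one long burst
  t_under <- c(0, cumsum(rep(29.9e-6, 200)))
  id_under <- select_bursts(t_under, rep("D", 201),
                            slice_len = 2e-3, slice_min = 10)
  expect_gt(nrow(id_under), 0)
  expect_error(select_bursts(c(2, 1), c("D", "D")), "sorted")
})

test_that("transfer-efficiency corrections reproduce hand-worked values", {
  ## no corrections
  expect_equal(transfer_efficiency(50, 50)$E, 0.5)
  expect_equal(transfer_efficiency(80, 0)$E, 0)
  ## known correction vector, worked by hand:
  ## nD = 100 - 10*1 = 90; nA = 60 - 5*1 = 55; crosstalk: 55 - 0.05*90 = 50.5
  ## direct exc: 50.5 - 0.1*(50.5+90) = 36.45; gamma: nD -> 1.2*90 = 108
  ## E = 36.45/(36.45+108)
  res <- transfer_efficiency(100, 60, duration = 1, bg_D = 10, bg_A = 5,
                             crosstalk = 0.05, direct_exc = 0.1, gamma = 1.2)
  expect_equal(res$E, 36.45 / (36.45 + 108), tolerance = 1e-12)
  ## non-positive corrected totals are dropped with a reason, not an error
  res0 <- transfer_efficiency(5, 3, duration = 1, bg_D = 10, bg_A = 5)
  expect_true(res0$dropped)
})

test_that("global two-Gaussian histogram fit recovers populations and K_D", {
  set.seed(13)
  ## single population: recovered mean within the s.e. of the sample mean
  E1 <- stats::rnorm(3000, 0.62, 0.05)
  hf1 <- fit_histogram(list(E1))
  main <- which.max(hf1$amplitudes[1, ])
  expect_lt(abs(hf1$mu[main] - 0.62), 0.01)  # within half a bin width
  ## fractions sum to one by construction
  expect_equal(sum(hf1$fractions[1], 1 - hf1$fractions[1]), 1)
  ## two-population titration generated at K_D = 0.73 nM
  cH <- c(0.05, 0.1, 0.25, 0.5, 1, 2.5, 7.5, 20) * 1e-9
  d <- simulate_titration_bursts(cH, 0.73e-9, 50e-12, n_bursts = 1500,
                                 seed = 14)
  hf <- fit_histogram(split(d$E, d$c_H_tot))
  fit <- fit_isotherm(cH, hf$fractions, 50e-12)
  expect_lt(abs(fit$K_D - 0.73e-9), 3 * fit$K_D_sd)
})

test_that("recurrence histograms match a brute-force pair scan", {
  set.seed(15)
  n <- 800
  bursts <- data.frame(start = sort(stats::runif(n, 0, 60)),
                       E = stats::runif(n))
  rng <- c(0.6, 1)
  win <- c(5e-3, 25e-3)
  got <- sort(recurrence_histogram(bursts, rng, win))
  ## O(N^2) enumeration
  want <- c()
  for (i in seq_len(n)) {
    if (bursts$E[i] < rng[1] || bursts$E[i] > rng[2]) next
    dt <- bursts$start - bursts$start[i]
    want <- c(want, bursts$E[dt > win[1] & dt <= win[2]])
  }
  expect_equal(got, sort(want))
  ## a window beyond the data is empty and flagged
  eh <- recurrence_histogram(bursts, rng, c(100, 200))
  expect_length(eh, 0)
  expect_true(attr(eh, "empty"))
})

test_that("recurrence preserves the initial population for static molecules", {
  ## exchange far slower than the experiment: recurring molecules keep
  ## their state, so short-delay recurrence histograms stay in the range
  Kslow <- matrix(c(-1e-4, 1e-4, 1e-4, -1e-4), 2, 2)
  gs <- generator_matrix(Kslow, c("U", "B"))
  sim <- simulate_burst_experiment(gs, c(0.4, 0.75), t_total = 60,
                                   burst_rate = 10, p_recur = 0.6,
                                   seed = 16)
  Es <- recurrence_histogram(sim$bursts, c(0.6, 1), c(1e-4, 4e-3))
  expect_gt(mean(Es > 0.6), 0.85)
})

test_that("p_same estimation tracks the labeled ground truth", {
  Kslow <- matrix(c(-5, 5, 5, -5), 2, 2)
  gs <- generator_matrix(Kslow, c("U", "B"))
  sim <- simulate_burst_experiment(gs, c(0.4, 0.75), t_total = 400,
                                   burst_rate = 12, p_recur = 0.55,
                                   mean_gap = 4e-3, seed = 17)
  b <- sim$bursts
  t_grid <- seq(2e-3, 40e-3, by = 2e-3)
  est <- estimate_p_same(b, t_grid)
  ## empirical p_same from molecule labels, per delay bin
  bw <- 2e-3
  emp <- vapply(t_grid, function(tc) {
    same <- 0; tot <- 0
    hi <- findInterval(b$start + tc + bw / 2, b$start)
    lo <- findInterval(b$start + tc - bw / 2, b$start)
    for (i in seq_len(nrow(b))) {
      js <- if (hi[i] > lo[i]) seq(lo[i] + 1L, hi[i]) else integer(0)
      js <- js[js != i]
      tot <- tot + length(js)
      same <- same + sum(b$molecule[js] == b$molecule[i])
    }
    if (tot == 0) NA_real_ else same / tot
  }, numeric(1))
  ok <- is.finite(emp)
  expect_gt(mean(abs(est$p_same[ok] - emp[ok]) < 0.1), 0.9)
  ## long-delay limit: unrelated molecules dominate
  est_inf <- estimate_p_same(b, c(0.5, 1), bin_width = 0.2,
                             tail_window = c(2, 5))
  expect_lt(est_inf$p_same[1], 0.15)
})

test_that("recurrence-rate fit recovers exact and model-generated exchange rates", {
  ## p_same = 1 and a clean exponential: exact recovery
  t <- seq(1e-4, 1e-2, length.out = 30)
  kex_true <- 400
  E <- 0.55 + (0.75 - 0.55) * exp(-kex_true * t)
  fit <- fit_recurrence_kex(data.frame(t = t, E = E, p_same = 1))
  expect_equal(fit$k_ex, kex_true, tolerance = 1e-6)
  expect_equal(fit$E_eq, 0.55, tolerance = 1e-6)
  ## affine rescaling of all E leaves k_ex unchanged
  fit2 <- fit_recurrence_kex(data.frame(t = t, E = 0.3 + 0.5 * E,
                                        p_same = 1))
  expect_equal(fit2$k_ex, fit$k_ex, tolerance = 1e-6)
  ## four-state model at the recurrence conditions, bound- and unbound-start
  ## series with decaying p_same and noise: global fit consistent with the
  ## model's exchange rate
  rs <- default_rates()
  conc <- solve_species_concentrations(3e-6, 1e-6, rs)
  kex <- exchange_rate(rs, conc, "P", "4state")
  set.seed(18)
  tg <- exp(seq(log(2e-4), log(2e-2), length.out = 12))
  ps <- exp(-tg / 8e-3)
  Eeq <- 0.4 * (1 - conc$theta) + 0.75 * conc$theta
  mk <- function(E0) data.frame(
    t = tg, E = (1 - ps) * Eeq + ps * (Eeq + (E0 - Eeq) * exp(-kex * tg)) +
      stats::rnorm(length(tg), 0, 0.003),
    p_same = ps, sd = 0.003)
  gfit <- fit_recurrence_kex(list(mk(0.75), mk(0.4)))
  expect_lt(abs(gfit$k_ex - kex),
            3 * sqrt(gfit$k_ex_sd^2 + 77^2))
  expect_false(gfit$at_bound)
})
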