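test_that("two-state generator has the right structure and equilibrium", {
  rs <- default_rates()
  g <- build_K2(rs, 1e-9)
  expect_equal(g$K[2, 1], 1.45, tolerance = 1e-12)   # k_on_obs = k_on * c_H
  expect_equal(colSums(g$K), c(U = 0, B = 0))
  ## detailed balance: p_eq ratio equals k_on_obs / k_off
  expect_equal(g$p_eq[["B"]] / g$p_eq[["U"]], g$K[2, 1] / g$K[1, 2],
               tolerance = 1e-12)
  ## absorbing unbound state without ligand
  g0 <- build_K2(rs, 0)
  expect_equal(unname(g0$p_eq), c(1, 0))
  expect_error(build_K2(rs, -1e-9), "non-negative")
})

test_that("multi-state generators conserve probability for random rate sets", {
  set.seed(1)
  for (i in 1:20) {
    rs <- random_rate_set()
    conc3 <- solve_species_concentrations(10^stats::runif(1, -8, -5),
                                          10^stats::runif(1, -8, -5), rs,
                                          include_PHH = FALSE)
    conc4 <- solve_species_concentrations(conc3$c_P_tot, conc3$c_H_tot, rs)
    for (g in list(build_K3P(rs, conc3), build_K4P(rs, conc4),
                   build_K4H(rs, conc4))) {
      expect_lt(max(abs(colSums(g$K))), 1e-10 * max(abs(g$K)))
      expect_true(all(g$p_eq > 0))
      offd <- g$K; diag(offd) <- 0
      expect_true(all(offd >= 0))
    }
  }
})

test_that("three-state equilibrium matches the labeled-species mass-action ratios", {
  rs <- default_rates()
  conc <- solve_species_concentrations(200e-9, 10e-9, rs, include_PHH = FALSE)
  g <- build_K3P(rs, conc)
  p <- g$p_eq
  ## P* <-> P*H ratio
  expect_equal(p[["PH"]] / p[["P"]], rs$k_on * conc$c_H / rs$k_off,
               tolerance = 1e-9)
  ## P* <-> P*PH direct ratio: forward k_on_PPH c_PH, backward k_off_PPH / 2
  expect_equal(p[["PPH"]] / p[["P"]],
               rs$k_on_PPH * conc$c_PH / (rs$k_off_PPH / 2),
               tolerance = 1e-9)
})

test_that("the four-state model nests the three-state model", {
  rs <- default_rates()
  ## PHH channel switched off: keep k_off_PHH finite but no association
  rs_off <- rate_set(rs$k_on, rs$k_off, rs$k_on_PPH, rs$k_off_PPH,
                     1e-30, rs$k_off_PHH)
  conc3 <- solve_species_concentrations(100e-9, 10e-9, rs_off,
                                        include_PHH = FALSE)
  conc4 <- solve_species_concentrations(100e-9, 10e-9, rs_off)
  g3 <- build_K3P(rs_off, conc3)
  g4 <- build_K4P(rs_off, conc4)
  expect_equal(g4$K[1:3, 1:3], g3$K, tolerance = 1e-9)
  expect_lt(g4$p_eq[["PHH"]], 1e-12)
  ## spectral gap positive for generic positive rates
  ev <- sort(Re(eigen(g4$K, only.values = TRUE)$values), decreasing = TRUE)
  expect_lt(ev[2], -1e-12)
  expect_lt(abs(ev[1]), 1e-6)    # zero mode present
})

test_that("labeled-H generator mirrors the labeled-P one", {
  rs <- default_rates()
  conc <- solve_species_concentrations(1e-6, 3e-6, rs)
  g <- build_K4H(rs, conc)
  expect_lt(max(abs(colSums(g$K))), 1e-10 * max(abs(g$K)))
  ## vanishing ternary rates reduce to two-state with roles swapped
  rs0 <- rate_set(rs$k_on, rs$k_off, 1e-30, rs$k_off_PPH, 1e-30,
                  rs$k_off_PHH)
  conc0 <- solve_species_concentrations(1e-6, 3e-6, rs0)
  g0 <- build_K4H(rs0, conc0)
  expect_equal(g0$K[2, 1], rs$k_on * conc0$c_P, tolerance = 1e-9)
  expect_equal(g0$K[1, 2], rs$k_off, tolerance = 1e-12)
})

test_that("aggregate dwell times: closed forms, Eq-15 equivalence, simulation", {
  rs <- default_rates()
  ## two-state exact
  g2 <- build_K2(rs, 5e-9)
  dw <- mean_dwell_times(g2, "U")
  expect_equal(dw$tau_low, 1 / (rs$k_on * 5e-9), tolerance = 1e-12)
  expect_equal(dw$tau_high, 1 / rs$k_off, tolerance = 1e-12)
  ## three-state closed form over random parameter draws
  set.seed(3)
  for (i in 1:200) {
    rr <- random_rate_set()
    conc <- solve_species_concentrations(10^stats::runif(1, -8, -5),
                                         10^stats::runif(1, -8, -5), rr,
                                         include_PHH = FALSE)
    g3 <- build_K3P(rr, conc)
    dw3 <- mean_dwell_times(g3, "P")
    expect_equal(dw3$tau_high, tau_high_3state(rr, conc), tolerance = 1e-10)
    ## the single-state low aggregate has the exact exit-rate dwell
    expect_equal(dw3$tau_low,
                 1 / (rr$k_on * conc$c_H + rr$k_on_PPH * conc$c_PH),
                 tolerance = 1e-10)
  }
  ## agreement with dwell times measured on a long Gillespie trajectory
  conc <- solve_species_concentrations(100e-9, 10e-9, rs, include_PHH = FALSE)
  g3 <- build_K3P(rs, conc)
  dw3 <- mean_dwell_times(g3, "P")
  path <- simulate_ctmc(g3, 3000, seed = 99)
  low <- path$state == 1
  runs <- rle(low)
  seg <- data.frame(start = path$t, end = c(path$t[-1], path$duration),
                    low = low)
  seg$run <- cumsum(c(TRUE, diff(as.integer(seg$low)) != 0))
  dur <- tapply(seg$end - seg$start, seg$run, sum)
  is_low <- tapply(seg$low, seg$run, `[`, 1)
  ## drop the (possibly truncated) first and last dwell
  keep <- seq_along(dur)[-c(1, length(dur))]
  emp_low <- mean(dur[keep][is_low[keep]])
  emp_high <- mean(dur[keep][!is_low[keep]])
  n_low <- sum(is_low[keep]); n_high <- sum(!is_low[keep])
  expect_lt(abs(emp_low - dw3$tau_low), 4 * dw3$tau_low / sqrt(n_low))
  expect_lt(abs(emp_high - dw3$tau_high), 4 * dw3$tau_high / sqrt(n_high))
})

test_that("bound dwell shortens about 30-fold at 100 nM competitor", {
  rs <- default_rates()
  conc0 <- solve_species_concentrations(0, 10e-9, rs, include_PHH = FALSE)
  expect_equal(tau_high_3state(rs, conc0), 1 / rs$k_off, tolerance = 1e-9)
  conc <- solve_species_concentrations(100e-9, 10e-9, rs, include_PHH = FALSE)
  fold <- (1 / tau_high_3state(rs, conc)) / rs$k_off
  expect_gt(fold, 25); expect_lt(fold, 35)
})

test_that("exchange rates: closed form, monotonicity, and 2-state lower bound", {
  rs <- default_rates()
  conc <- solve_species_concentrations(50e-9, 10e-9, rs, include_PHH = FALSE)
  expect_equal(exchange_rate(rs, conc, "P", "2state"),
               rs$k_on * conc$c_H + rs$k_off, tolerance = 1e-12)
  ## the ternary pathway accelerates exchange wherever it is open
  grid <- seq(10e-9, 2e-6, length.out = 15)
  kex2 <- kex3 <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cc <- solve_species_concentrations(grid[i], 10e-9, rs,
                                       include_PHH = FALSE)
    kex2[i] <- exchange_rate(rs, cc, "P", "2state")
    kex3[i] <- exchange_rate(rs, cc, "P", "3state")
  }
  expect_true(all(kex3 > kex2))
  expect_true(all(diff(kex3) > 0))    # monotone in competitor concentration
})

test_that("four-state exchange at recurrence conditions is ~864/s", {
  rs <- default_rates()
  conc <- solve_species_concentrations(3e-6, 1e-6, rs)
  kex <- exchange_rate(rs, conc, "P", "4state")
  expect_gt(kex, 864 - 77); expect_lt(kex, 864 + 77)
})

test_that("global ternary fit recovers, is idempotent, and flags null signal", {
  rs <- default_rates()
  grid <- seq(0, 2e-6, length.out = 12)
  obs <- t(vapply(grid, function(cp) observed_rates_3state(rs, cp, 10e-9),
                  numeric(2)))
  clean <- data.frame(
    c_P_tot = rep(grid, 2), c_H_tot = 10e-9,
    observable = rep(c("k_on_obs", "k_off_obs"), each = length(grid)),
    value = c(obs[, 1], obs[, 2]),
    sd = 0.05 * c(obs[, 1], obs[, 2]))
  ## idempotence on noise-free data from a displaced start
  start <- rate_set(rs$k_on, rs$k_off, rs$k_on_PPH * 3, rs$k_off_PPH / 3,
                    rs$k_on_PPH * 3, rs$k_on_PPH * 3 * rs$K_D_PHH)
  fit0 <- global_fit_ternary(clean, start)
  expect_equal(fit0$k_on_PPH, rs$k_on_PPH, tolerance = 1e-6)
  expect_equal(fit0$k_off_PPH, rs$k_off_PPH, tolerance = 1e-6)
  ## noisy recovery within 3 s.e.
  set.seed(5)
  noisy <- clean
  noisy$value <- clean$value * (1 + stats::rnorm(nrow(clean), 0, 0.05))
  fit <- global_fit_ternary(noisy, start)
  expect_lt(abs(fit$k_on_PPH - rs$k_on_PPH), 3 * fit$k_on_PPH_se)
  expect_lt(abs(fit$k_off_PPH - rs$k_off_PPH), 3 * fit$k_off_PPH_se)
  ## data generated without any ternary channel: fitted association rate
  ## collapses with large relative uncertainty
  rs_null <- rate_set(rs$k_on, rs$k_off, 1e-30, rs$k_off_PPH, 1e-30,
                      rs$k_off_PHH)
  obs0 <- t(vapply(grid, function(cp)
    observed_rates_3state(rs_null, cp, 10e-9), numeric(2)))
  null_dat <- data.frame(
    c_P_tot = rep(grid, 2), c_H_tot = 10e-9,
    observable = rep(c("k_on_obs", "k_off_obs"), each = length(grid)),
    value = c(obs0[, 1], obs0[, 2]), sd = 0.05 * c(obs0[, 1], obs0[, 2]))
  fit_null <- global_fit_ternary(null_dat, start)
  expect_lt(fit_null$k_on_PPH, 0.05 * rs$k_on_PPH)
})
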