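fast_rates <- function() rate_set(2e9, 1.7, 1e9, 1e3, 1e9, 1e3)

test_that("single-photon likelihood equals 1' n_D p_eq", {
  rs <- fast_rates()
  g <- build_K2(rs, 1e-9)
  em <- emission_rates(100, 10, 20, 200)
  tr <- photon_trace(0.5, "D")
  expect_equal(trace_likelihood(tr, g, em),
               log(sum(c(100, 10) * g$p_eq)), tolerance = 1e-12)
  ## photon in a channel with zero rate everywhere: -Inf, not an error
  em0 <- emission_rates(0, 0, 20, 200)
  expect_identical(trace_likelihood(tr, g, em0), -Inf)
})

test_that("likelihood matches a Taylor-series matrix-exponential oracle", {
  rs <- fast_rates()
  g <- build_K2(rs, 2e-9)
  em <- emission_rates(120, 15, 30, 180)
  ## short hand-built traces, including the two-photon case
  traces <- list(photon_trace(c(0, 0.013), c("D", "A")),
                 photon_trace(c(0, 0.01, 0.25, 0.26, 1.2),
                              c("D", "D", "A", "A", "D")))
  for (tr in traces) {
    expect_equal(trace_likelihood(tr, g, em),
                 oracle_trace_loglik(tr, g$K, nD = c(120, 15),
                                     nA = c(30, 180), p_eq = g$p_eq),
                 tolerance = 1e-10)
  }
})

test_that("closed-form 2x2 propagator equals the generic eigen route", {
  rs <- fast_rates()
  g <- build_K2(rs, 2e-9)
  em <- emission_rates(120, 15, 30, 180)
  set.seed(2)
  tr <- photon_trace(cumsum(stats::rexp(400, 150)),
                     sample(c("D", "A"), 400, replace = TRUE))
  ll_fast <- trace_likelihood(tr, g, em)
  ll_generic <- trace_likelihood(tr, g,
                                 list(n_D = c(120, 15), n_A = c(30, 180)))
  expect_equal(ll_fast, ll_generic, tolerance = 1e-12)
})

test_that("likelihood is invariant under uniform time translation", {
  rs <- fast_rates()
  g <- build_K2(rs, 2e-9)
  em <- emission_rates(120, 15, 30, 180)
  set.seed(3)
  t0 <- cumsum(stats::rexp(200, 100))
  cc <- sample(c("D", "A"), 200, replace = TRUE)
  expect_equal(trace_likelihood(photon_trace(t0, cc), g, em),
               trace_likelihood(photon_trace(t0 + 17.3, cc), g, em),
               tolerance = 1e-12)
})

test_that("the generating parameters out-score perturbed ones", {
  rs <- rate_set(2e9, 1.7, 1e9, 1e3, 1e9, 1e3)
  c_H <- 1e-9   # k_on_obs = 2 /s
  em <- emission_rates(20e3, 5e3, 5e3, 20e3)
  sim <- simulate_trace_ensemble(12, 5, rs, c_H, em,
                                 brightness_jitter = 0, seed = 21)
  g_true <- build_K2(rs, c_H)
  g_pert <- build_K2(rate_set(2 * rs$k_on, 2 * rs$k_off, rs$k_on_PPH,
                              rs$k_off_PPH, rs$k_on_PHH, rs$k_off_PHH), c_H)
  ll_true <- sum(vapply(sim$traces, trace_likelihood, numeric(1),
                        gen = g_true, rates = em))
  ll_pert <- sum(vapply(sim$traces, trace_likelihood, numeric(1),
                        gen = g_pert, rates = em))
  expect_gt(ll_true, ll_pert)
})

test_that("Viterbi recovers the true path for well-separated emission rates", {
  rs <- rate_set(2e9, 2, 1e9, 1e3, 1e9, 1e3)
  g <- build_K2(rs, 1e-9)
  em <- emission_rates(10e3, 100, 100, 10e3)   # 100:1 separation
  set.seed(31)
  path <- simulate_ctmc(g, 20)
  tr <- simulate_photon_trace(path, em)
  vit <- viterbi_path(tr, g, em)
  truth <- true_photon_states(tr, path)
  expect_gt(mean(vit == truth), 0.99)
})

test_that("Viterbi follows the preferred state when emissions are uninformative", {
  rs <- rate_set(2e9, 0.5, 1e9, 1e3, 1e9, 1e3)   # p_eq favors bound
  g <- build_K2(rs, 1e-9)
  em <- emission_rates(5e3, 5e3, 5e3, 5e3)
  set.seed(5)
  tr <- photon_trace(cumsum(stats::rexp(500, 1e4)),
                     sample(c("D", "A"), 500, replace = TRUE))
  vit <- viterbi_path(tr, g, em)
  pref <- which.max(g$p_eq)
  expect_true(all(vit == pref))
})

test_that("reversing a trace reverses the Viterbi path", {
  rs <- rate_set(2e9, 2, 1e9, 1e3, 1e9, 1e3)
  g <- build_K2(rs, 1.5e-9)
  em <- emission_rates(8e3, 1e3, 1e3, 8e3)
  set.seed(8)
  path <- simulate_ctmc(g, 10)
  tr <- simulate_photon_trace(path, em)
  vit <- viterbi_path(tr, g, em)
  t_rev <- max(tr$t) - rev(tr$t)
  tr_rev <- photon_trace(t_rev, rev(tr$color) + 1L)
  vit_rev <- viterbi_path(tr_rev, g, em)
  expect_gt(mean(rev(vit_rev) == vit), 0.999)
})

test_that("joint ML fit recovers the generating rates on a small ensemble", {
  rs <- default_rates()
  em <- emission_rates(15e3, 5e3, 5e3, 15e3)
  c_H <- 5e-9
  sim <- simulate_trace_ensemble(8, 15, rs, c_H, em, seed = 41)
  fit <- fit_two_state(sim$traces, c_H = c_H)
  bs <- bootstrap_rates(fit, n_rounds = 10, seed = 42)
  expect_lt(abs(fit$k_on_obs - rs$k_on * c_H), 3 * bs$k_on_obs_sd)
  expect_lt(abs(fit$k_off_obs - rs$k_off), 3 * bs$k_off_obs_sd)
  ## emission rates recovered within a few percent
  expect_lt(abs(mean(fit$emissions[, "n_D_U"]) - 15e3) / 15e3, 0.05)
})

test_that("estimates tighten as the photon rate increases", {
  rs <- default_rates()
  c_H <- 5e-9
  err <- vapply(c(2e3, 8e3, 32e3), function(rate) {
    em <- emission_rates(0.75 * rate, 0.25 * rate, 0.25 * rate, 0.75 * rate)
    sim <- simulate_trace_ensemble(6, 12, rs, c_H, em,
                                   brightness_jitter = 0, seed = 55)
    fit <- fit_two_state(sim$traces, c_H = c_H)
    abs(fit$k_off_obs - rs$k_off) / rs$k_off
  }, numeric(1))
  ## consistency trend: the highest photon rate beats the lowest
  expect_lt(err[3], err[1] + 0.02)
  expect_lt(err[3], 0.1)
})

test_that("bootstrap is deterministic under a fixed seed and degenerate on identical data", {
  rs <- default_rates()
  em <- emission_rates(10e3, 3e3, 3e3, 10e3)
  sim <- simulate_trace_ensemble(6, 8, rs, 5e-9, em, seed = 61)
  fit <- fit_two_state(sim$traces, c_H = 5e-9, n_cycles = 2)
  b1 <- bootstrap_rates(fit, n_rounds = 6, seed = 7)
  b2 <- bootstrap_rates(fit, n_rounds = 6, seed = 7)
  expect_identical(b1$samples, b2$samples)
  ## identical traces: every resample is the same dataset, s.d. collapses
  tr <- sim$traces[[1]]
  clones <- replicate(6, tr, simplify = FALSE)
  fitc <- fit_two_state(clones, c_H = 5e-9, n_cycles = 2)
  bc <- bootstrap_rates(fitc, n_rounds = 6, seed = 8)
  expect_lt(bc$k_on_obs_sd / fitc$k_on_obs, 1e-6)
})

test_that("trace selection by transition count works at the edges", {
  empty <- select_traces(list())
  expect_length(empty$traces, 0)
  tr <- photon_trace(seq(0, 1, length.out = 11), rep(c("D", "A"), c(5, 6)))
  paths <- list(c(rep(1L, 3), rep(2L, 3), rep(1L, 3), 2L, 1L),  # 4 transitions
                c(rep(1L, 5), rep(2L, 6)))                       # 1 transition
  res <- select_traces(list(tr, tr), paths = paths)
  expect_length(res$traces, 0)          # 4 transitions is not > 4
  expect_match(res$report$reason[1], "transitions")
  res0 <- select_traces(list(tr, tr), paths = paths, min_transitions = 0)
  expect_length(res0$traces, 2)
  res3 <- select_traces(list(tr, tr), paths = paths, min_transitions = 3)
  expect_length(res3$traces, 1)
})

test_that("photon traces round-trip through delimited text", {
  tr <- photon_trace(c(0.1, 0.2, 0.35), c("D", "A", "D"), trace_id = "x")
  f <- tempfile(fileext = ".tsv")
  write_photon_trace(tr, f)
  tr2 <- read_photon_trace(f)
  expect_equal(tr2$t, tr$t)
  expect_identical(tr2$color, tr$color)
  unlink(f)
})

test_that("brightness screening flags drifting traces and passes stable ones", {
  rs <- default_rates()
  em <- emission_rates(10e3, 3e3, 3e3, 10e3)
  sim <- simulate_trace_ensemble(1, 20, rs, 5e-9, em, seed = 71)
  tr <- sim$traces[[1]]
  expect_true(screen_brightness(tr)$stable)
  ## impose a 3x brightness step halfway through
  half <- tr$t > tr$t[1] + 10
  keep <- !half | (stats::runif(length(tr$t)) < 1 / 3)
  tr_drift <- photon_trace(tr$t[keep], tr$color[keep] + 1L)
  expect_false(screen_brightness(tr_drift)$stable)
})
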