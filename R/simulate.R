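#' Exact stochastic trajectory of a continuous-time Markov chain
#'
#' Gillespie simulation of a kinetic generator. Reproducible through R's RNG
#' (`set.seed`).
#'
#' @param gen a [generator_matrix].
#' @param duration trajectory length (seconds).
#' @param state0 initial state (index or label); default: drawn from `p_eq`.
#' @param seed optional seed applied via [set.seed].
#' @return list of class `ctmc_path`: switch times `t`, states `state`
#'   (integer, entered at the corresponding time), `duration`, `labels`.
#' @export
simulate_ctmc <- function(gen, duration, state0 = NULL, seed = NULL) {
  stopifnot(inherits(gen, "generator_matrix"))
  check_pos(duration, "duration")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state0)) {
    state0 <- sample.int(length(gen$p_eq), 1, prob = gen$p_eq)
  } else if (is.character(state0)) {
    state0 <- match(state0, gen$state_labels)
  }
  out <- cpp_simulate_ctmc(gen$K, duration, as.integer(state0))
  structure(list(t = out$t, state = out$state, duration = duration,
                 labels = gen$state_labels), class = "ctmc_path")
}

## segment table (start, end, state) of a ctmc_path
ctmc_segments <- function(path) {
  data.frame(start = path$t,
             end = c(path$t[-1], path$duration),
             state = path$state)
}

#' Simulate a colored photon trace from a state path
#'
#' Per-state Poisson photon emission in the donor and acceptor channels along
#' a simulated state trajectory; photons from all segments are merged and
#' time-ordered.
#'
#' @param path a `ctmc_path` (2 states for the surface model).
#' @param rates an [emission_rates] giving per-state donor/acceptor rates
#'   (state 1 = unbound, state 2 = bound).
#' @param seed optional RNG seed.
#' @param trace_id identifier for the resulting trace.
#' @return a [photon_trace] (or `NULL` if no photons were emitted).
#' @export
simulate_photon_trace <- function(path, rates, seed = NULL,
                                  trace_id = NA_character_) {
  stopifnot(inherits(path, "ctmc_path"), inherits(rates, "emission_rates"))
  if (!is.null(seed)) set.seed(seed)
  seg <- ctmc_segments(path)
  nD <- c(rates[["n_D_U"]], rates[["n_D_B"]])[seg$state]
  nA <- c(rates[["n_A_U"]], rates[["n_A_B"]])[seg$state]
  len <- seg$end - seg$start
  kD <- stats::rpois(nrow(seg), nD * len)
  kA <- stats::rpois(nrow(seg), nA * len)
  tD <- rep(seg$start, kD) + stats::runif(sum(kD)) * rep(len, kD)
  tA <- rep(seg$start, kA) + stats::runif(sum(kA)) * rep(len, kA)
  tt <- c(tD, tA); cc <- c(rep(0L, length(tD)), rep(1L, length(tA)))
  if (length(tt) == 0L) return(NULL)
  o <- order(tt)
  tt <- tt[o]; cc <- cc[o]
  ## enforce strictly increasing times (coincident draws have measure zero,
  ## but guard against ties from limited float resolution)
  dup <- duplicated(tt)
  if (any(dup)) { tt <- tt[!dup]; cc <- cc[!dup] }
  photon_trace(tt, cc + 1L, trace_id = trace_id)
}

#' Simulate an ensemble of immobilized-molecule photon traces
#'
#' Forward model of the surface experiment: two-state switching at
#' `k_on_obs = k_on * c_H` and `k_off`, with per-state donor/acceptor
#' emission. Emission rates are jittered per trace (lognormal, sd
#' `brightness_jitter`) to emulate molecules sitting at different positions
#' in the focus.
#'
#' @param n_traces number of traces.
#' @param duration seconds per trace.
#' @param rates a [rate_set].
#' @param c_H free ligand concentration (molar).
#' @param emissions an [emission_rates] with the nominal per-state rates.
#' @param brightness_jitter lognormal sd of the per-trace brightness factor
#'   (default 0.05).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with `traces` (list of [photon_trace]) and `truth` (the
#'   generating parameters).
#' @export
simulate_trace_ensemble <- function(n_traces, duration, rates, c_H, emissions,
                                    brightness_jitter = 0.05, seed) {
  set.seed(seed)
  gen <- build_K2(rates, c_H)
  traces <- vector("list", n_traces)
  for (j in seq_len(n_traces)) {
    f <- exp(stats::rnorm(1, 0, brightness_jitter))
    em_j <- emission_rates(emissions[["n_D_U"]] * f, emissions[["n_D_B"]] * f,
                           emissions[["n_A_U"]] * f, emissions[["n_A_B"]] * f)
    path <- simulate_ctmc(gen, duration)
    traces[[j]] <- simulate_photon_trace(path, em_j,
                                         trace_id = sprintf("trace%03d", j))
  }
  traces <- Filter(Negate(is.null), traces)
  list(traces = traces,
       truth = list(k_on_obs = rates$k_on * c_H, k_off_obs = rates$k_off,
                    c_H = c_H, emissions = emissions, seed = seed))
}

#' Simulate a free-diffusion burst experiment with recurrence structure
#'
#' Poisson arrivals of molecules into the confocal volume; each molecule
#' carries a hidden kinetic state that evolves as a continuous-time Markov
#' chain while the molecule recurs near the focus, producing a geometric
#' number of bursts separated by exponential recurrence gaps. Within a burst
#' (fixed duration by default) photons are emitted at a constant total rate
#' with an acceptor fraction set by the state's transfer efficiency.
#' Ground-truth molecule identities and states are returned for validating
#' recurrence estimators.
#'
#' @param gen a [generator_matrix] for the hidden state.
#' @param E_states per-state transfer efficiencies.
#' @param t_total experiment duration (s).
#' @param burst_rate arrival rate of new molecules (1/s).
#' @param photon_rate total photon rate within a burst (1/s).
#' @param burst_duration burst length (s), default 1 ms.
#' @param p_recur probability that a molecule returns for another burst.
#' @param mean_gap mean recurrence gap between bursts of one molecule (s).
#' @param seed RNG seed.
#' @return list with `bursts` (data.frame: start, end, n_D, n_A, E,
#'   molecule, state) and `photons` (data.frame: t, channel, molecule).
#' @export
simulate_burst_experiment <- function(gen, E_states, t_total = 60,
                                      burst_rate = 20, photon_rate = 1e5,
                                      burst_duration = 1e-3, p_recur = 0.3,
                                      mean_gap = 5e-3, seed) {
  set.seed(seed)
  n_mol <- stats::rpois(1, burst_rate * t_total)
  arrivals <- sort(stats::runif(n_mol, 0, t_total))
  rows <- list(); ph_t <- list(); ph_c <- list(); k <- 1L
  for (m in seq_len(n_mol)) {
    n_bursts <- 1L + stats::rgeom(1, 1 - p_recur)
    gaps <- c(0, stats::rexp(n_bursts - 1L, 1 / mean_gap))
    starts <- arrivals[m] + cumsum(gaps)
    ## hidden state evolves across the whole recurrence episode
    episode <- simulate_ctmc(gen, max(starts) - arrivals[m] + burst_duration)
    seg <- ctmc_segments(episode)
    for (b in seq_len(n_bursts)) {
      s0 <- starts[b]
      rel <- s0 - arrivals[m] + burst_duration / 2
      st <- seg$state[findInterval(rel, seg$start)]
      nph <- stats::rpois(1, photon_rate * burst_duration)
      if (nph == 0L) next
      nA <- stats::rbinom(1, nph, E_states[st])
      rows[[k]] <- data.frame(start = s0, end = s0 + burst_duration,
                              n_D = nph - nA, n_A = nA,
                              E = nA / nph, molecule = m, state = st)
      tt <- sort(stats::runif(nph, s0, s0 + burst_duration))
      ph_t[[k]] <- tt
      ph_c[[k]] <- c(rep("A", nA), rep("D", nph - nA))[sample.int(nph)]
      k <- k + 1L
    }
  }
  bursts <- do.call(rbind, rows)
  bursts <- bursts[order(bursts$start), ]
  rownames(bursts) <- NULL
  photons <- data.frame(t = unlist(ph_t), channel = unlist(ph_c))
  photons <- photons[order(photons$t), ]
  list(bursts = bursts, photons = photons,
       truth = list(E_states = E_states, seed = seed))
}

#' Simulate burst-level transfer-efficiency titration histograms
#'
#' Burst-level forward model of a slow-exchange titration: at each ligand
#' concentration a fraction `theta` of bursts (from the depletion isotherm)
#' originates from the bound population. Per burst, the photon count is
#' Poisson and the acceptor count binomial at the state's transfer
#' efficiency, so the per-population E distributions carry shot noise.
#'
#' @param c_H_tot_grid ligand concentrations (molar).
#' @param K_D_star generating affinity (molar).
#' @param c_Pstar_tot labeled total concentration (molar).
#' @param n_bursts bursts per titration point.
#' @param E_U,E_B transfer efficiencies of unbound/bound molecules.
#' @param mean_photons mean photons per burst.
#' @param seed RNG seed.
#' @return data.frame with columns `c_H_tot`, `E`, `state` (ground truth).
#' @export
simulate_titration_bursts <- function(c_H_tot_grid, K_D_star, c_Pstar_tot,
                                      n_bursts = 3000, E_U = 0.4, E_B = 0.75,
                                      mean_photons = 150, seed) {
  set.seed(seed)
  out <- lapply(c_H_tot_grid, function(ch) {
    th <- two_state_bound_fraction(ch, c_Pstar_tot, K_D_star)
    bound <- stats::runif(n_bursts) < th
    nph <- pmax(stats::rpois(n_bursts, mean_photons), 20L)
    nA <- stats::rbinom(n_bursts, nph, ifelse(bound, E_B, E_U))
    data.frame(c_H_tot = ch, E = nA / nph,
               state = ifelse(bound, "B", "U"))
  })
  do.call(rbind, out)
}

#' Simulate a stopped-flow relaxation trace
#'
#' Population dynamics of the labeled species after mixing are propagated
#' with the post-mixing kinetic generator from the pre-mixing equilibrium
#' distribution; the signal is the bound-state population (acceptor
#' fluorescence proxy) plus Gaussian noise.
#'
#' @param rates a [rate_set].
#' @param conc_before,conc_after `concentration_state` before and after
#'   mixing (the generator is built at the post-mixing concentrations).
#' @param t_grid time grid (s).
#' @param noise_sd Gaussian noise sd on the normalized signal.
#' @param model `"3state"` or `"4state"`.
#' @param seed RNG seed.
#' @return data.frame of class `relaxation_trace`: `t`, `signal`, plus
#'   attribute `truth` (list with the generator and the dominant relaxation
#'   rate).
#' @export
simulate_stopped_flow <- function(rates, conc_before, conc_after,
                                  t_grid = seq(0, 0.2, length.out = 400),
                                  noise_sd = 0.01,
                                  model = c("3state", "4state"), seed) {
  model <- match.arg(model)
  set.seed(seed)
  gen_b <- if (model == "3state") build_K3P(rates, conc_before)
           else build_K4P(rates, conc_before)
  gen_a <- if (model == "3state") build_K3P(rates, conc_after)
           else build_K4P(rates, conc_after)
  p0 <- gen_b$p_eq
  ed <- eigen(gen_a$K)
  Vi <- solve(ed$vectors)
  bound_idx <- -1L  # all states but the first are high-FRET (bound-like)
  sig <- vapply(t_grid, function(t) {
    p <- Re(ed$vectors %*% (exp(ed$values * t) * (Vi %*% p0)))
    sum(p[bound_idx])
  }, numeric(1))
  ev <- Re(ed$values)
  slow <- -max(ev[ev < -1e-9])
  data <- data.frame(t = t_grid, signal = sig + stats::rnorm(length(sig), 0,
                                                             noise_sd))
  attr(data, "truth") <- list(relaxation_rate = slow, clean = sig,
                              generator = gen_a)
  data
}

#' Simulate a lineshape titration with noise
#'
#' Forward model for projection fitting: spectra from the Bloch-McConnell
#' propagator at each titration point plus additive Gaussian noise, volume
#' normalized.
#'
#' @param spin a [spin_system].
#' @param rates a [rate_set].
#' @param c_P_tot labeled-protein total concentration (molar).
#' @param c_H_tot_grid titrant concentrations (molar).
#' @param omega_grid frequency grid (rad/s); default automatic.
#' @param noise_sd additive noise, relative to the maximum intensity.
#' @param seed RNG seed.
#' @return list of spectra (data.frames `omega`, `intensity`), one per
#'   titration point, with the noise-free spectra in `attr(, "truth")`.
#' @export
simulate_nmr_titration <- function(spin, rates, c_P_tot, c_H_tot_grid,
                                   omega_grid = NULL, noise_sd = 0.01, seed) {
  set.seed(seed)
  clean <- titration_lineshapes(rates, spin, c_P_tot, c_H_tot_grid,
                                model = "4state", omega_grid = omega_grid)
  noisy <- lapply(clean$spectra, function(sp) {
    mx <- max(sp$intensity)
    sp$intensity <- sp$intensity + stats::rnorm(nrow(sp), 0, noise_sd * mx)
    ## volume normalization
    area <- sum(sp$intensity) * mean(diff(sp$omega))
    sp$intensity <- sp$intensity / area
    sp
  })
  attr(noisy, "truth") <- clean
  noisy
}

#' Draw umbrella-sampling windows from a known potential
#'
#' Boltzmann samples of the reaction coordinate under the biased potential
#' `W(r) + k/2 (r - r0)^2` by inverse-CDF sampling on a fine grid, one
#' window per bias center. Used to validate the WHAM reconstruction with
#' exact ground truth.
#'
#' @param W_fun function of r (nm) returning the unbiased potential W(r)
#'   (kJ/mol).
#' @param centers window centers (nm).
#' @param k_umb force constant (kJ/mol/nm^2), default 10.
#' @param n_per_window samples per window.
#' @param temperature kelvin, default 300.
#' @param r_max upper edge of the sampled range (nm).
#' @param seed RNG seed.
#' @return list of `umbrella_window` objects (see [umbrella_window]).
#' @export
simulate_umbrella <- function(W_fun, centers, k_umb = 10, n_per_window = 4000,
                              temperature = 300, r_max = max(centers) + 2,
                              seed) {
  set.seed(seed)
  beta <- 1 / (polyion_constants$kB_kJ * temperature)
  r_fine <- seq(1e-3, r_max, length.out = 4096)
  W <- W_fun(r_fine)
  lapply(centers, function(r0) {
    u <- W + 0.5 * k_umb * (r_fine - r0)^2
    p <- exp(-beta * (u - min(u)))
    cdf <- cumsum(p); cdf <- cdf / cdf[length(cdf)]
    ## inverse CDF with jitter within grid cells
    keep <- c(TRUE, diff(cdf) > 0)
    smp <- stats::approx(cdf[keep], r_fine[keep],
                         xout = stats::runif(n_per_window), rule = 2)$y
    umbrella_window(center = r0, k_umb = k_umb, samples = smp)
  })
}
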