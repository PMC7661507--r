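#' Photon trace container
#'
#' A colored photon arrival-time trace from a single immobilized molecule.
#'
#' @param arrival_times strictly increasing photon arrival times (seconds).
#' @param colors per-photon detection channel, `"D"` or `"A"` (or a factor /
#'   integer vector with 1 = donor, 2 = acceptor).
#' @param trace_id optional identifier.
#' @return object of class `photon_trace` with elements `t` (times), `color`
#'   (integer, 0 = donor, 1 = acceptor), `tau` (inter-photon times, first
#'   entry 0 by convention), `trace_id`, `duration`.
#' @export
photon_trace <- function(arrival_times, colors, trace_id = NA_character_) {
  stopifnot(length(arrival_times) == length(colors),
            length(arrival_times) >= 1L)
  if (is.unsorted(arrival_times, strictly = TRUE))
    stop("arrival_times must be strictly increasing")
  col <- if (is.character(colors) || is.factor(colors)) {
    match(as.character(colors), c("D", "A")) - 1L
  } else as.integer(colors) - 1L
  if (any(is.na(col)) || any(!col %in% c(0L, 1L)))
    stop("colors must be 'D'/'A' (or 1/2)")
  structure(list(t = as.numeric(arrival_times), color = col,
                 tau = c(0, diff(arrival_times)),
                 trace_id = trace_id,
                 duration = arrival_times[length(arrival_times)] -
                   arrival_times[1]),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("Photon trace %s: %d photons over %.3g s (%d donor, %d acceptor)\n",
              x$trace_id, length(x$t), x$duration,
              sum(x$color == 0L), sum(x$color == 1L)))
  invisible(x)
}

#' Emission rates of the two-state model
#'
#' @param n_D_U,n_D_B donor photon detection rates in the unbound/bound
#'   state (1/s).
#' @param n_A_U,n_A_B acceptor rates (1/s).
#' @return object of class `emission_rates` (named numeric of length 4).
#' @export
emission_rates <- function(n_D_U, n_D_B, n_A_U, n_A_B) {
  v <- c(n_D_U = unname(n_D_U), n_D_B = unname(n_D_B),
         n_A_U = unname(n_A_U), n_A_B = unname(n_A_B))
  check_nonneg(v, "emission rates")
  structure(v, class = "emission_rates")
}

#' Log-likelihood of a photon trace under a kinetic + emission model
#'
#' Evaluates the photon-by-photon likelihood
#' \deqn{L = \mathbf{1}^T \prod_i \mathbf{n}_{c_i}
#'   \exp[(\mathbf{K} - \mathbf{n}_D - \mathbf{n}_A)\tau_i]\, \mathbf{p}_{eq}}
#' with left-to-right propagation and per-photon renormalization; the
#' returned value is the exact log-likelihood (sum of log norms). A photon
#' detected in a channel with zero rate in all states yields `-Inf`.
#'
#' For two states a closed-form propagator is used (compiled); for three or
#' more states the propagator is evaluated by eigendecomposition.
#'
#' @param trace a [photon_trace].
#' @param gen a [generator_matrix] (2 or more states).
#' @param rates an [emission_rates] (two-state) or a list with numeric
#'   vectors `n_D`, `n_A` of per-state rates (multi-state).
#' @return log-likelihood (scalar).
#' @export
trace_likelihood <- function(trace, gen, rates) {
  stopifnot(inherits(trace, "photon_trace"), inherits(gen, "generator_matrix"))
  n <- nrow(gen$K)
  if (n == 2L && inherits(rates, "emission_rates")) {
    kon <- gen$K[2, 1]; koff <- gen$K[1, 2]
    return(cpp_loglik2(trace$tau, trace$color, kon, koff,
                       rates[["n_D_U"]], rates[["n_D_B"]],
                       rates[["n_A_U"]], rates[["n_A_B"]]))
  }
  nD <- rates$n_D; nA <- rates$n_A
  stopifnot(length(nD) == n, length(nA) == n)
  M <- gen$K - diag(nD + nA)
  ed <- eigen(M)
  Vi <- solve(ed$vectors)
  propagate <- function(v, tau)
    Re(ed$vectors %*% (exp(ed$values * tau) * (Vi %*% v)))
  v <- gen$p_eq
  logl <- 0
  for (i in seq_along(trace$tau)) {
    if (i > 1L) v <- propagate(v, trace$tau[i])
    v <- v * (if (trace$color[i] == 0L) nD else nA)
    s <- sum(v)
    if (!is.finite(s) || s <= 0) return(-Inf)
    logl <- logl + log(s)
    v <- v / s
  }
  logl
}

## crude initialization: bin the trace, classify bins by acceptor fraction,
## return emission-rate guesses and transition-rate guesses
init_two_state <- function(trace, bin = 0.01) {
  brks <- seq(trace$t[1], trace$t[length(trace$t)] + bin, by = bin)
  idx <- findInterval(trace$t, brks)
  nA <- tabulate(idx[trace$color == 1L], nbins = length(brks))
  nT <- tabulate(idx, nbins = length(brks))
  keep <- nT > 0
  frac <- nA[keep] / nT[keep]
  thr <- mean(range(frac))
  bound <- frac > thr
  assign_bin <- bound[cumsum(keep)[idx]]     # per-photon bound flag
  t_bound <- sum(nT[keep][bound]) / sum(nT[keep]) * trace$duration
  t_unb <- trace$duration - t_bound
  em <- c(
    n_D_U = sum(trace$color == 0L & !assign_bin) / max(t_unb, bin),
    n_D_B = sum(trace$color == 0L & assign_bin) / max(t_bound, bin),
    n_A_U = sum(trace$color == 1L & !assign_bin) / max(t_unb, bin),
    n_A_B = sum(trace$color == 1L & assign_bin) / max(t_bound, bin))
  trans <- sum(diff(bound) != 0)
  list(em = pmax(em, 1), n_trans = trans, t_unb = t_unb, t_bound = t_bound)
}

## closed-form emission update given a Viterbi path (hard-assignment M step)
update_emissions <- function(trace, path) {
  t_state <- c(0, 0)
  ## attribute each inter-photon interval to the state of the later photon
  for (s in 1:2) t_state[s] <- sum(trace$tau[path == s])
  cnt <- function(col, s) sum(trace$color == col & path == s)
  pmax(c(n_D_U = cnt(0L, 1L) / t_state[1], n_D_B = cnt(0L, 2L) / t_state[2],
         n_A_U = cnt(1L, 1L) / t_state[1], n_A_B = cnt(1L, 2L) / t_state[2]),
       1e-3)
}

#' Maximum-likelihood two-state kinetics from an ensemble of photon traces
#'
#' Jointly maximizes the total photon-by-photon log-likelihood of all traces
#' with respect to the shared kinetic parameters (`k_on_obs`, `k_off_obs`)
#' and trace-specific emission rates (photon rates vary from trace to trace
#' with the position of the molecule in the focus). The maximization is
#' performed by block-coordinate ascent in log-parameter space: emission
#' rates are updated from the Viterbi state path of each trace
#' (closed-form conditional maximizer under hard assignment), and the shared
#' kinetic parameters by Nelder-Mead on the exact likelihood; the blocks are
#' iterated to joint convergence.
#'
#' @param traces list of [photon_trace] objects.
#' @param c_H free ligand concentration (molar); if given, `k_on` =
#'   `k_on_obs / c_H` is reported.
#' @param n_cycles number of block-update cycles (default 3).
#' @param start optional named list with `k_on_obs`, `k_off_obs` starting
#'   values; default from binned-trace initialization.
#' @param reltol relative convergence tolerance of the kinetic-parameter
#'   optimization.
#' @return object of class `ml_fit`: `k_on_obs`, `k_off_obs`, `k_on` (if
#'   `c_H` given), per-trace `emissions` matrix, `logL`, `n_photons`, and the
#'   per-trace log-likelihood vector.
#' @export
fit_two_state <- function(traces, c_H = NULL, n_cycles = 3, start = NULL,
                          reltol = 1e-10) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "photon_trace")))
  taus <- lapply(traces, `[[`, "tau")
  cols <- lapply(traces, `[[`, "color")
  J <- length(traces)

  inits <- lapply(traces, init_two_state)
  em <- do.call(rbind, lapply(inits, `[[`, "em"))
  if (is.null(start)) {
    t_unb <- sum(vapply(inits, `[[`, numeric(1), "t_unb"))
    t_bnd <- sum(vapply(inits, `[[`, numeric(1), "t_bound"))
    n_tr <- sum(vapply(inits, `[[`, numeric(1), "n_trans"))
    k_on_obs <- max(n_tr / 2 / max(t_unb, 1e-6), 1e-3)
    k_off_obs <- max(n_tr / 2 / max(t_bnd, 1e-6), 1e-3)
  } else {
    k_on_obs <- start$k_on_obs; k_off_obs <- start$k_off_obs
  }

  total_nll <- function(lpar, emis)
    -sum(cpp_loglik2_traces(taus, cols, exp(lpar[1]), exp(lpar[2]), emis))

  for (cycle in seq_len(n_cycles)) {
    opt <- stats::optim(c(log(k_on_obs), log(k_off_obs)), total_nll,
                        emis = em, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 400))
    k_on_obs <- exp(opt$par[1]); k_off_obs <- exp(opt$par[2])
    if (cycle < n_cycles) {
      for (j in seq_len(J)) {
        path <- cpp_viterbi2(taus[[j]], cols[[j]], k_on_obs, k_off_obs,
                             em[j, 1], em[j, 2], em[j, 3], em[j, 4])
        em[j, ] <- update_emissions(traces[[j]], path)
      }
    }
  }
  per_trace <- cpp_loglik2_traces(taus, cols, k_on_obs, k_off_obs, em)
  colnames(em) <- c("n_D_U", "n_D_B", "n_A_U", "n_A_B")
  structure(list(k_on_obs = k_on_obs, k_off_obs = k_off_obs,
                 k_on = if (!is.null(c_H)) k_on_obs / c_H else NA_real_,
                 c_H = c_H, emissions = em,
                 logL = sum(per_trace), per_trace_logL = per_trace,
                 n_photons = sum(lengths(taus)),
                 taus = taus, cols = cols),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("Photon-ML two-state fit: %d traces, %d photons\n",
              nrow(x$emissions), x$n_photons))
  cat(sprintf("  k_on_obs  = %.4g /s\n  k_off_obs = %.4g /s\n",
              x$k_on_obs, x$k_off_obs))
  if (is.finite(x$k_on)) cat(sprintf("  k_on = %.4g /M/s (c_H = %.3g M)\n",
                                     x$k_on, x$c_H))
  cat(sprintf("  logL = %.6g\n", x$logL))
  invisible(x)
}

#' Most likely state path of a photon trace
#'
#' Viterbi (max-product) decoding over the per-photon interval propagators of
#' the two-state model; each photon is assigned its most likely state.
#'
#' @param trace a [photon_trace].
#' @param gen a two-state [generator_matrix].
#' @param rates an [emission_rates].
#' @return integer vector (1 = unbound, 2 = bound), one entry per photon.
#' @export
viterbi_path <- function(trace, gen, rates) {
  stopifnot(nrow(gen$K) == 2L, inherits(rates, "emission_rates"))
  cpp_viterbi2(trace$tau, trace$color, gen$K[2, 1], gen$K[1, 2],
               rates[["n_D_U"]], rates[["n_D_B"]],
               rates[["n_A_U"]], rates[["n_A_B"]])
}

#' Bootstrap standard deviations of the fitted kinetic parameters
#'
#' Resamples whole traces with replacement, refits the shared kinetic
#' parameters for each resample (emission rates kept at their per-trace
#' maximizers, which travel with the resampled traces), and reports the
#' standard deviation over rounds.
#'
#' @param fit an `ml_fit` from [fit_two_state].
#' @param n_rounds number of bootstrap rounds (default 20).
#' @param seed RNG seed (set via [set.seed]).
#' @param maxit Nelder-Mead iteration cap per refit; refits start at the
#'   full-data optimum.
#' @return list with `k_on_obs_sd`, `k_off_obs_sd`, the resampled estimate
#'   matrix `samples`, and `n_degenerate` (resamples consisting of a single
#'   repeated trace).
#' @export
bootstrap_rates <- function(fit, n_rounds = 20, seed = NULL, maxit = 100) {
  stopifnot(inherits(fit, "ml_fit"))
  J <- length(fit$taus)
  if (J < 5L) warning("fewer than 5 traces: bootstrap s.d. unreliable")
  if (!is.null(seed)) set.seed(seed)
  est <- matrix(NA_real_, n_rounds, 2,
                dimnames = list(NULL, c("k_on_obs", "k_off_obs")))
  start <- c(log(fit$k_on_obs), log(fit$k_off_obs))
  n_degenerate <- 0L
  for (r in seq_len(n_rounds)) {
    idx <- sample.int(J, J, replace = TRUE)
    if (length(unique(idx)) == 1L) n_degenerate <- n_degenerate + 1L
    taus <- fit$taus[idx]; cols <- fit$cols[idx]
    emis <- fit$emissions[idx, , drop = FALSE]
    nll <- function(lpar)
      -sum(cpp_loglik2_traces(taus, cols, exp(lpar[1]), exp(lpar[2]), emis))
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = maxit))
    est[r, ] <- exp(opt$par)
  }
  list(k_on_obs_sd = stats::sd(est[, 1]), k_off_obs_sd = stats::sd(est[, 2]),
       samples = est, n_degenerate = n_degenerate)
}

#' Filter traces by number of observed transitions
#'
#' Keeps traces whose Viterbi state path shows more than `min_transitions`
#' transitions between the bound and unbound state, mirroring the selection
#' of stable immobilized-molecule traces.
#'
#' @param traces list of [photon_trace].
#' @param paths list of per-photon state paths (from [viterbi_path]); if
#'   `NULL`, paths are computed from `fit`.
#' @param fit optional `ml_fit` used to compute provisional paths.
#' @param min_transitions minimum transition count (strictly more required),
#'   default 4.
#' @return list with `traces` (kept), `report` (data.frame with trace_id,
#'   n_transitions, kept).
#' @export
select_traces <- function(traces, paths = NULL, fit = NULL,
                          min_transitions = 4) {
  if (length(traces) == 0L)
    return(list(traces = list(),
                report = data.frame(trace_id = character(0),
                                    n_transitions = integer(0),
                                    kept = logical(0))))
  if (is.null(paths)) {
    stopifnot(!is.null(fit))
    paths <- lapply(seq_along(traces), function(j)
      cpp_viterbi2(traces[[j]]$tau, traces[[j]]$color,
                   fit$k_on_obs, fit$k_off_obs,
                   fit$emissions[j, 1], fit$emissions[j, 2],
                   fit$emissions[j, 3], fit$emissions[j, 4]))
  }
  n_tr <- vapply(paths, function(p) sum(diff(p) != 0L), integer(1))
  kept <- n_tr > min_transitions
  report <- data.frame(
    trace_id = vapply(traces, function(x) as.character(x$trace_id),
                      character(1)),
    n_transitions = n_tr, kept = kept,
    reason = ifelse(kept, "", sprintf("<= %d transitions", min_transitions)))
  list(traces = traces[kept], report = report)
}

#' Read / write photon traces as two-column delimited text
#'
#' Format: two columns, `time_s` and `channel` (D or A), tab-separated with a
#' header line.
#'
#' @param path file path.
#' @param trace a [photon_trace] (for writing).
#' @return [photon_trace] (for reading); invisible path (for writing).
#' @export
read_photon_trace <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  photon_trace(d$time_s, d$channel, trace_id = basename(path))
}

#' @rdname read_photon_trace
#' @export
write_photon_trace <- function(trace, path) {
  d <- data.frame(time_s = trace$t,
                  channel = c("D", "A")[trace$color + 1L])
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Screen a trace for brightness drift
#'
#' Sliding-window test for substantial brightness variations (focus drift,
#' long-lived dark states, background changes): the total photon rate in
#' each window is compared to the trace mean; windows deviating by more
#' than `threshold` standard deviations of the expected Poisson counting
#' noise *and* more than the state-dependent rate contrast flag the trace.
#'
#' @param trace a [photon_trace].
#' @param window window length (seconds), default 1.
#' @param threshold flag threshold in Poisson standard deviations beyond
#'   the state contrast, default 3.
#' @return list with `stable` (logical), `window_rates`, `mean_rate`,
#'   `max_z` (largest excess deviation).
#' @export
screen_brightness <- function(trace, window = 1, threshold = 3) {
  stopifnot(inherits(trace, "photon_trace"))
  brks <- seq(trace$t[1], trace$t[length(trace$t)] + window, by = window)
  if (length(brks) < 3L)
    return(list(stable = TRUE, window_rates = length(trace$t) / trace$duration,
                mean_rate = length(trace$t) / trace$duration, max_z = 0))
  cnt <- tabulate(findInterval(trace$t, brks), nbins = length(brks) - 1L)
  cnt <- cnt[-length(cnt)]                     # drop the partial last window
  mu <- mean(cnt)
  ## jump test between consecutive windows: a brightness step or drift gives
  ## a jump far beyond Poisson counting noise; genuine state switching with
  ## similar total brightness does not. The 20% relative floor keeps modest
  ## state-brightness contrast from flagging; raise threshold for traces
  ## whose states differ strongly in total rate.
  d <- abs(diff(cnt))
  z <- d / sqrt(pmax(cnt[-1] + cnt[-length(cnt)], 1))
  rel <- d / pmax(pmax(cnt[-1], cnt[-length(cnt)]), 1)
  flag <- z > threshold & rel > 0.2
  list(stable = !any(flag), window_rates = cnt / window,
       mean_rate = mu / window, max_z = max(z))
}
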