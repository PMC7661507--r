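#' Burst selection from a photon stream
#'
#' Two-pass burst search used for free-diffusion data: (i) consecutive
#' photons separated by strictly less than `interphoton_max` are combined
#' into one burst and bursts with more than `min_photons` photons are kept;
#' (ii) each kept burst is split into slices of length `slice_len` (half-open
#' intervals from the burst start) and only slices containing more than
#' `slice_min` photons are retained. Slices inherit the identity of their
#' parent burst.
#'
#' @param times photon arrival times (seconds), sorted.
#' @param channels per-photon channel, "D"/"A".
#' @param interphoton_max maximum inter-photon gap within a burst (s),
#'   default 30e-6. The comparison is strict: photons separated by exactly
#'   this value start a new burst.
#' @param min_photons bursts must contain strictly more photons than this
#'   (default 100).
#' @param slice_len slice length (s), default 100e-6.
#' @param slice_min slices must contain strictly more photons than this
#'   (default 50).
#' @return data.frame of class `burst_table`: `start`, `end`, `n_D`, `n_A`,
#'   `E`, `parent_burst`.
#' @export
select_bursts <- function(times, channels, interphoton_max = 30e-6,
                          min_photons = 100, slice_len = 100e-6,
                          slice_min = 50) {
  if (length(times) == 0L)
    return(structure(data.frame(start = numeric(0), end = numeric(0),
                                n_D = integer(0), n_A = integer(0),
                                E = numeric(0), parent_burst = integer(0)),
                     class = c("burst_table", "data.frame")))
  if (is.unsorted(times)) stop("photon times must be sorted")
  isA <- channels == "A"
  ## pass 1: split at gaps >= interphoton_max (strictly-less-than merges)
  burst_id <- cumsum(c(1, as.integer(diff(times) >= interphoton_max)))
  counts <- tabulate(burst_id)
  keep_burst <- which(counts > min_photons)
  rows <- vector("list", length(keep_burst))
  for (i in seq_along(keep_burst)) {
    b <- keep_burst[i]
    sel <- burst_id == b
    tb <- times[sel]; ab <- isA[sel]
    ## pass 2: half-open 100-us slices from the burst start
    slice <- floor((tb - tb[1]) / slice_len)
    ns <- tabulate(slice + 1L)
    good <- which(ns > slice_min) - 1L
    if (length(good) == 0L) next
    nA <- vapply(good, function(s) sum(ab[slice == s]), integer(1))
    nT <- ns[good + 1L]
    rows[[i]] <- data.frame(
      start = tb[1] + good * slice_len,
      end = tb[1] + (good + 1) * slice_len,
      n_D = nT - nA, n_A = nA, E = nA / nT, parent_burst = b)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(start = numeric(0), end = numeric(0),
                                      n_D = integer(0), n_A = integer(0),
                                      E = numeric(0), parent_burst = integer(0))
  rownames(out) <- NULL
  structure(out, class = c("burst_table", "data.frame"))
}

#' Corrected transfer efficiency of a burst
#'
#' Applies background, channel-crosstalk, direct-excitation and detection /
#' quantum-yield corrections to raw counts and returns
#' `E = n_A / (n_A + n_D)`. With all corrections at their identity defaults
#' the raw ratio is returned, so uncorrected synthetic data round-trip
#' exactly.
#'
#' @param n_D,n_A raw donor/acceptor counts.
#' @param duration burst duration (s) for background subtraction.
#' @param bg_D,bg_A background rates (1/s), default 0.
#' @param crosstalk donor-to-acceptor leakage fraction, default 0.
#' @param direct_exc direct acceptor excitation fraction (of total corrected
#'   counts), default 0.
#' @param gamma detection/quantum-yield factor multiplying the donor counts,
#'   default 1.
#' @return list with `E`, `n_D`, `n_A` (corrected), `dropped` (TRUE when the
#'   corrected total is not positive).
#' @export
transfer_efficiency <- function(n_D, n_A, duration = 0, bg_D = 0, bg_A = 0,
                                crosstalk = 0, direct_exc = 0, gamma = 1) {
  nD <- n_D - bg_D * duration
  nA <- n_A - bg_A * duration
  nA <- nA - crosstalk * nD
  nA <- nA - direct_exc * (nA + nD)
  nD <- gamma * nD
  tot <- nD + nA
  dropped <- !is.finite(tot) | tot <= 0
  E <- ifelse(dropped, NA_real_, nA / tot)
  list(E = E, n_D = nD, n_A = nA, dropped = dropped)
}

#' Global multi-histogram peak fit of transfer-efficiency distributions
#'
#' Fits a series of burst E histograms (one per titration condition) with a
#' pair of peak functions whose positions and widths are shared across the
#' series while the amplitudes are free per condition. Peak models: a
#' Gaussian pair, or a log-normal (asymmetric donor-only peak) plus a
#' Gaussian. Amplitudes are profiled out by linear least squares at each
#' shape evaluation, so the nonlinear optimization runs over the four shape
#' parameters only.
#'
#' @param E_list list of numeric vectors of burst transfer efficiencies, one
#'   per condition.
#' @param model `"gaussian_pair"` or `"lognormal_plus_gaussian"`.
#' @param bins number of histogram bins on \[0, 1\] (default 50).
#' @param start optional list `mu1`, `mu2`, `sd1`, `sd2`.
#' @return list of class `histogram_fit`: `mu`, `sd` (length-2, shared),
#'   `amplitudes` (matrix conditions x 2), `fractions` (bound-fraction per
#'   condition = area share of peak 2), `sse`, `converged`.
#' @export
fit_histogram <- function(E_list, model = c("gaussian_pair",
                                            "lognormal_plus_gaussian"),
                          bins = 50, start = NULL) {
  model <- match.arg(model)
  if (!is.list(E_list)) E_list <- list(E_list)
  brks <- seq(0, 1, length.out = bins + 1)
  mids <- (brks[-1] + brks[-length(brks)]) / 2
  counts <- lapply(E_list, function(E)
    graphics::hist(pmin(pmax(E, 0), 1), breaks = brks, plot = FALSE)$counts)
  if (is.null(start)) {
    allE <- unlist(E_list)
    km <- stats::kmeans(allE, centers = 2, nstart = 5)
    mu0 <- sort(km$centers)
    start <- list(mu1 = mu0[1], mu2 = mu0[2], sd1 = 0.05, sd2 = 0.05)
  }
  shape1 <- function(x, mu, sd) {
    if (model == "gaussian_pair") stats::dnorm(x, mu, sd)
    else stats::dlnorm(x, log(max(mu, 1e-3)), sd)
  }
  sse_fn <- function(par) {
    mu <- c(par[1], par[2]); sd <- exp(par[3:4])
    B1 <- shape1(mids, mu[1], sd[1])
    B2 <- stats::dnorm(mids, mu[2], sd[2])
    X <- cbind(B1, B2)
    tot <- 0
    for (cts in counts) {
      a <- tryCatch(stats::coef(stats::lm.fit(X, cts)), error = function(e)
        c(0, 0))
      a[!is.finite(a)] <- 0
      tot <- tot + sum((cts - X %*% a)^2)
    }
    tot
  }
  par0 <- c(start$mu1, start$mu2, log(start$sd1), log(start$sd2))
  opt <- stats::optim(par0, sse_fn, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu <- c(opt$par[1], opt$par[2]); sd <- exp(opt$par[3:4])
  B1 <- shape1(mids, mu[1], sd[1]); B2 <- stats::dnorm(mids, mu[2], sd[2])
  X <- cbind(B1, B2)
  amps <- t(vapply(counts, function(cts) {
    a <- stats::coef(stats::lm.fit(X, cts)); a[!is.finite(a) | a < 0] <- 0; a
  }, numeric(2)))
  ## areas: amplitude x integral of the unit-density shape = amplitude
  fractions <- amps[, 2] / pmax(rowSums(amps), .Machine$double.eps)
  structure(list(mu = mu, sd = sd, amplitudes = amps, fractions = fractions,
                 sse = opt$value, converged = opt$convergence == 0,
                 model = model, mids = mids, counts = counts),
            class = "histogram_fit")
}

#' Recurrence histogram of second bursts
#'
#' Scans a time-ordered burst table for all pairs in which the first burst's
#' transfer efficiency falls in `initial_E_range` and the second burst
#' starts within the given delay window after the first; returns the E values
#' of the second bursts. All pairs within the window contribute, not only
#' adjacent bursts.
#'
#' @param bursts a `burst_table` (or data.frame with `start`, `E`).
#' @param initial_E_range length-2 numeric, inclusive E range of the first
#'   burst.
#' @param window length-2 numeric `c(t_min, t_max)` (s): delay window for the
#'   second burst (start-to-start).
#' @return numeric vector of second-burst E values, with attribute
#'   `n_first` (number of qualifying first bursts). Empty selections return
#'   a zero-length vector flagged with attribute `empty = TRUE`.
#' @export
recurrence_histogram <- function(bursts, initial_E_range, window) {
  stopifnot(window[1] <= window[2])
  ts <- bursts$start
  if (is.unsorted(ts)) stop("bursts must be time-ordered")
  first <- which(bursts$E >= initial_E_range[1] &
                   bursts$E <= initial_E_range[2])
  lo <- findInterval(ts[first] + window[1], ts, left.open = TRUE)
  hi <- findInterval(ts[first] + window[2], ts)
  out <- numeric(0)
  idx <- which(hi > lo)
  if (length(idx)) {
    sec <- unlist(lapply(idx, function(i) {
      js <- seq(lo[i] + 1L, hi[i])
      js[js != first[i]]          # a burst never pairs with itself
    }))
    out <- bursts$E[sec]
  }
  attr(out, "n_first") <- length(first)
  attr(out, "empty") <- length(out) == 0L
  out
}

#' Same-molecule probability from burst-interval statistics
#'
#' Estimates `p_same(t)`, the probability that a burst observed a delay `t`
#' after a given burst stems from the same molecule. Bursts from unrelated
#' molecules arrive as a Poisson process whose rate is estimated from the
#' long-delay tail of the start-to-start pair rate; the excess pair rate at
#' short delays is attributed to recurring molecules:
#' `p_same(t) = max(0, 1 - rate_bg / rate(t))`.
#'
#' @param bursts a `burst_table`.
#' @param t_grid delay-bin centers (s).
#' @param bin_width width of each delay bin (s); default: grid spacing.
#' @param tail_window length-2 numeric (s): delay range, well beyond the
#'   recurrence timescale, from which the Poisson background rate of
#'   unrelated bursts is estimated. Default `c(5, 10) * max(t_grid)`.
#' @return data.frame `t`, `p_same`, `pair_rate`, `bg_rate`; a warning is
#'   attached when fewer than 1000 bursts are available.
#' @export
estimate_p_same <- function(bursts, t_grid, bin_width = NULL,
                            tail_window = c(5, 10) * max(t_grid)) {
  ts <- bursts$start
  n <- length(ts)
  wide <- n < 1000
  if (is.null(bin_width))
    bin_width <- if (length(t_grid) > 1) min(diff(t_grid)) else t_grid / 2
  t_max <- max(max(t_grid) + bin_width, tail_window[2])
  ## pair delays up to t_max (sorted starts: contiguous forward scan)
  hi <- findInterval(ts + t_max, ts)
  delays <- unlist(lapply(seq_len(n), function(i)
    if (hi[i] > i) ts[seq(i + 1L, hi[i])] - ts[i] else numeric(0)))
  counts_per_bin <- vapply(t_grid, function(tc)
    sum(delays >= tc - bin_width / 2 & delays < tc + bin_width / 2),
    numeric(1))
  pair_rate <- counts_per_bin / (n * bin_width)
  in_tail <- delays >= tail_window[1] & delays < tail_window[2]
  bg_rate <- sum(in_tail) / (n * diff(tail_window))
  p_same <- pmax(0, 1 - bg_rate / pmax(pair_rate, .Machine$double.eps))
  out <- data.frame(t = t_grid, p_same = p_same, pair_rate = pair_rate,
                    bg_rate = bg_rate)
  attr(out, "wide_uncertainty") <- wide
  out
}

#' Fit the exchange rate to recurrence peak positions
#'
#' Weighted global fit of the recurrence relaxation model
#' \deqn{\langle E\rangle(t) = (1 - p_{same}(t))\langle E\rangle_{eq} +
#'   p_{same}(t)\left[\langle E\rangle_{eq} + (\langle E\rangle(0) -
#'   \langle E\rangle_{eq})e^{-k_{ex} t}\right]}
#' to one or two series of peak positions (bound-start and unbound-start)
#' sharing a single relaxation rate `k_ex` and a common plateau `E_eq`,
#' with one initial value `E0` per series.
#'
#' @param series list of data.frames with columns `t`, `E`, `p_same`, and
#'   optionally `sd`.
#' @param E_eq_init,k_ex_init optional starting values.
#' @return list of class `recurrence_fit`: `k_ex`, `k_ex_sd`, `E_eq`, `E0`
#'   (per series), `fit` (the `nls.lm` object), `at_bound` flag.
#' @export
fit_recurrence_kex <- function(series, E_eq_init = NULL, k_ex_init = NULL) {
  if (is.data.frame(series)) series <- list(series)
  S <- length(series)
  allE <- unlist(lapply(series, `[[`, "E"))
  if (is.null(E_eq_init)) E_eq_init <- mean(allE)
  if (is.null(k_ex_init)) {
    tmax <- max(unlist(lapply(series, `[[`, "t")))
    k_ex_init <- 2 / tmax
  }
  E0_init <- vapply(series, function(d) d$E[which.min(d$t)], numeric(1))
  par0 <- c(log(k_ex_init), E_eq_init, E0_init)
  resid_fn <- function(par) {
    kex <- exp(par[1]); Eeq <- par[2]; E0 <- par[3:(2 + S)]
    unlist(lapply(seq_len(S), function(s) {
      d <- series[[s]]
      w <- if ("sd" %in% names(d) && all(is.finite(d$sd)) && all(d$sd > 0))
        1 / d$sd else rep(1, nrow(d))
      pred <- (1 - d$p_same) * Eeq +
        d$p_same * (Eeq + (E0[s] - Eeq) * exp(-kex * d$t))
      w * (d$E - pred)
    }))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  kex <- exp(fit$par[1])
  J <- numeric_jacobian(resid_fn, fit$par)
  dof <- max(length(fit$fvec) - length(fit$par), 1L)
  s2 <- sum(fit$fvec^2) / dof
  cov <- tryCatch(solve(crossprod(J)) * s2,
                  error = function(e) matrix(NA, length(fit$par),
                                             length(fit$par)))
  kex_sd <- kex * sqrt(cov[1, 1])
  at_bound <- kex < 1e-6 || kex > 1e7
  structure(list(k_ex = kex, k_ex_sd = kex_sd, E_eq = fit$par[2],
                 E0 = fit$par[3:(2 + S)], fit = fit, at_bound = at_bound),
            class = "recurrence_fit")
}

#' Recurrence transfer-efficiency series from a burst table
#'
#' Convenience driver: for each recurrence time, builds the recurrence
#' histogram of second bursts given an initial E range, fits the FRET peak
#' (Gaussian, with a log-normal donor-only peak when `donor_only = TRUE`),
#' and returns the peak position series ready for [fit_recurrence_kex].
#'
#' @param bursts a `burst_table`.
#' @param initial_E_range E range selecting the first burst.
#' @param t_centers recurrence-time window centers (s).
#' @param window_width width of each delay window (s).
#' @param p_same optional data.frame from [estimate_p_same] evaluated at
#'   `t_centers`; if `NULL` it is estimated from `bursts`.
#' @return data.frame `t`, `E`, `p_same`, `n` suitable for
#'   [fit_recurrence_kex].
#' @export
recurrence_series <- function(bursts, initial_E_range, t_centers,
                              window_width, p_same = NULL) {
  if (is.null(p_same))
    p_same <- estimate_p_same(bursts, t_centers, bin_width = window_width)
  E <- vapply(t_centers, function(tc) {
    Es <- recurrence_histogram(bursts, initial_E_range,
                               c(tc - window_width / 2, tc + window_width / 2))
    if (length(Es) < 10) return(NA_real_)
    mean(Es)
  }, numeric(1))
  n <- vapply(t_centers, function(tc) {
    length(recurrence_histogram(bursts, initial_E_range,
                                c(tc - window_width / 2,
                                  tc + window_width / 2)))
  }, integer(1))
  data.frame(t = t_centers, E = E, p_same = p_same$p_same, n = n)
}
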