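#' FCS correlation model with translational diffusion and triplet blinking
#'
#' \deqn{G(\tau) = 1 + \frac{1}{N}\left(1+\tau/\tau_D\right)^{-1}
#'   \left(1+s^2\tau/\tau_D\right)^{-1/2}
#'   \left(1 + c_T e^{-\tau/\tau_T}\right)}
#'
#' @param tau lag times (s).
#' @param N mean number of labeled molecules in the focus.
#' @param tau_D diffusion time (s).
#' @param c_T triplet amplitude.
#' @param tau_T triplet correlation time (s).
#' @param s lateral-to-axial focus aspect ratio.
#' @return correlation amplitudes G(tau).
#' @export
fcs_model <- function(tau, N, tau_D, c_T = 0, tau_T = 1e-6, s = 0.2) {
  1 + (1 / N) * (1 + tau / tau_D)^-1 * (1 + s^2 * tau / tau_D)^-0.5 *
    (1 + c_T * exp(-tau / tau_T))
}

#' Fit the FCS correlation model
#'
#' Least-squares fit of [fcs_model] to a measured correlation curve. The
#' focus aspect ratio `s` can be fixed (typical when calibrated
#' independently) or fitted.
#'
#' @param tau,G correlation curve (lags in s, amplitudes).
#' @param fit_triplet include the triplet term (default TRUE).
#' @param s aspect ratio; used as fixed value unless `fit_s`.
#' @param fit_s fit `s` as a free parameter (default FALSE).
#' @return list with `N`, `tau_D`, `c_T`, `tau_T`, `s`, standard errors
#'   where fitted, and the `nls` object.
#' @export
fcs_fit <- function(tau, G, fit_triplet = TRUE, s = 0.2, fit_s = FALSE) {
  stopifnot(all(tau > 0), all(is.finite(G)))
  N0 <- 1 / max(G[1] - 1, 1e-3)
  tD0 <- tau[which.min(abs((G - 1) / (G[1] - 1) - 0.5))]
  dat <- data.frame(tau = tau, G = G)
  if (fit_triplet && fit_s) {
    fit <- minpack.lm::nlsLM(G ~ fcs_model(tau, exp(lN), exp(ltD), exp(lcT),
                                           exp(ltT), exp(ls)),
                             data = dat,
                             start = list(lN = log(N0), ltD = log(tD0),
                                          lcT = log(0.1), ltT = log(2e-6),
                                          ls = log(s)))
  } else if (fit_triplet) {
    fit <- minpack.lm::nlsLM(G ~ fcs_model(tau, exp(lN), exp(ltD), exp(lcT),
                                           exp(ltT), s),
                             data = dat,
                             start = list(lN = log(N0), ltD = log(tD0),
                                          lcT = log(0.1), ltT = log(2e-6)))
  } else {
    fit <- minpack.lm::nlsLM(G ~ fcs_model(tau, exp(lN), exp(ltD), 0, 1e-6, s),
                             data = dat,
                             start = list(lN = log(N0), ltD = log(tD0)))
  }
  cf <- stats::coef(fit)
  out <- list(N = exp(cf[["lN"]]), tau_D = exp(cf[["ltD"]]),
              c_T = if ("lcT" %in% names(cf)) exp(cf[["lcT"]]) else 0,
              tau_T = if ("ltT" %in% names(cf)) exp(cf[["ltT"]]) else NA_real_,
              s = if ("ls" %in% names(cf)) exp(cf[["ls"]]) else s,
              fit = fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  out$tau_D_se <- out$tau_D * se[["ltD"]]
  out
}

#' Hydrodynamic radius from a relative diffusion time
#'
#' `R_H = tau_D * R_H_ref / tau_D_ref`, referencing the diffusion time of a
#' species of known hydrodynamic radius measured in the same focus.
#'
#' @param tau_D measured diffusion time (s).
#' @param tau_D_ref reference diffusion time (s).
#' @param R_H_ref reference hydrodynamic radius (any length unit; the result
#'   carries the same unit).
#' @return hydrodynamic radius.
#' @export
rh_from_fcs <- function(tau_D, tau_D_ref, R_H_ref) {
  check_pos(tau_D_ref, "tau_D_ref")
  check_pos(R_H_ref, "R_H_ref")
  tau_D * R_H_ref / tau_D_ref
}

#' Single-exponential fit of a stopped-flow relaxation trace
#'
#' Fits `signal = offset + amplitude * exp(-k_ex t)` after excluding an
#' initial dead-time window; the signal is max-min normalized before
#' fitting (amplitude and offset remain free). Degenerate traces whose
#' amplitude is indistinguishable from zero are flagged as unidentifiable.
#'
#' @param t,signal the relaxation trace (s, a.u.).
#' @param dead_time initial exclusion window (s), default 0.
#' @return list with `k_ex`, `k_ex_se`, `amplitude`, `offset`,
#'   `identifiable`, and the `nls` object (NULL when unidentifiable).
#' @export
stopped_flow_fit <- function(t, signal, dead_time = 0) {
  keep <- t >= dead_time
  t <- t[keep]; signal <- signal[keep]
  rng <- diff(range(signal))
  if (rng <= 0 || stats::sd(signal) < 1e-12)
    return(list(k_ex = NA_real_, k_ex_se = NA_real_, amplitude = 0,
                offset = mean(signal), identifiable = FALSE, fit = NULL))
  y <- (signal - min(signal)) / rng
  a0 <- y[1] - y[length(y)]
  k0 <- 1 / (max(t) / 3)
  ## crude rate guess from the 1/e crossing of the normalized decay
  if (abs(a0) > 0.2) {
    target <- y[length(y)] + a0 * exp(-1)
    ix <- which(((y - target) * sign(a0)) < 0)[1]
    if (!is.na(ix) && t[ix] > min(t)) k0 <- 1 / (t[ix] - t[1])
  }
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ off + a * exp(-exp(lk) * t), data = dat,
    start = list(off = y[length(y)], a = a0, lk = log(k0)),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(k_ex = NA_real_, k_ex_se = NA_real_, amplitude = NA_real_,
                offset = NA_real_, identifiable = FALSE, fit = NULL))
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients
  amp_sig <- abs(cf[["a"]]) > 3 * se["a", "Std. Error"]
  list(k_ex = exp(cf[["lk"]]),
       k_ex_se = exp(cf[["lk"]]) * se["lk", "Std. Error"],
       amplitude = cf[["a"]] * rng, offset = cf[["off"]] * rng + min(signal),
       identifiable = amp_sig, fit = fit)
}

#' Gradient-echo diffusion fit (Stejskal-Tanner)
#'
#' Fits \eqn{I = I_0 \exp[-D G_x^2 \gamma^2 \delta^2 (\Delta - \delta/3)]}
#' to a pulsed-field-gradient decay and returns the translational diffusion
#' coefficient.
#'
#' @param G_x gradient strengths (gauss/cm).
#' @param I signal intensities.
#' @param delta gradient pulse width (s), default 3e-3.
#' @param Delta pulse separation / diffusion time (s), default 250e-3.
#' @param gamma gyromagnetic ratio (rad/gauss/s), default the 1H value used
#'   for amide-detected diffusion (26752).
#' @return list with `D` (cm^2/s), `D_se`, `I_0`, and the `nls` object.
#' @export
stejskal_tanner_fit <- function(G_x, I, delta = 3e-3, Delta = 250e-3,
                                gamma = polyion_constants$gamma_15N) {
  b <- G_x^2 * gamma^2 * delta^2 * (Delta - delta / 3)
  dat <- data.frame(b = b, I = I)
  D0 <- if (any(b > 0) && all(I > 0)) {
    sl <- stats::coef(stats::lm(log(I) ~ b))[2]
    max(-sl, 1e-9)
  } else 1e-6
  fit <- minpack.lm::nlsLM(I ~ I0 * exp(-exp(lD) * b), data = dat,
                           start = list(I0 = max(I), lD = log(D0)))
  cf <- stats::coef(fit)
  D <- exp(cf[["lD"]])
  if (D <= 0) stop("fitted diffusion coefficient must be positive")
  se <- summary(fit)$coefficients
  list(D = D, D_se = D * se["lD", "Std. Error"], I_0 = cf[["I0"]], fit = fit)
}

#' Hydrodynamic radius from relative diffusion coefficients
#'
#' `R_H = D_ref * R_H_ref / D_protein`, referencing an internal viscosity
#' standard (default: 1,4-dioxane, R_H = 2.12 Angstrom).
#'
#' @param D_protein diffusion coefficient of the protein (any unit shared
#'   with `D_ref`).
#' @param D_ref diffusion coefficient of the reference.
#' @param R_H_ref reference hydrodynamic radius, default 2.12 (Angstrom).
#' @return hydrodynamic radius in the unit of `R_H_ref`.
#' @export
rh_from_diffusion <- function(D_protein, D_ref, R_H_ref = 2.12) {
  check_pos(D_protein, "D_protein")
  check_pos(D_ref, "D_ref")
  D_ref * R_H_ref / D_protein
}
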