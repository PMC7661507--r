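#' Global fit of concentration-dependent kinetics to the ternary-complex model
#'
#' Weighted least-squares fit of observed pseudo-first-order rates
#' (`k_on_obs`, `k_off_obs`, or their sum `k_ex`) measured at different total
#' concentrations, to the three-state model including the PPH ternary
#' complex. The dimer coefficients `k_on` and `k_off` are fixed (they are
#' determined independently from measurements at very low concentrations);
#' the two adjustable parameters are `k_on_PPH` and `k_off_PPH`, shared
#' across all datasets, with the PHH association rate tied to
#' `k_on_PPH` (the trimer association rate coefficients are taken as equal)
#' and the PHH affinity fixed.
#'
#' @param data data.frame with columns `c_P_tot`, `c_H_tot` (molar),
#'   `observable` (one of "k_on_obs", "k_off_obs", "k_ex"), `value` (1/s),
#'   and optionally `sd` (1/s). Rows lacking `sd` are weighted at a relative
#'   10 percent of their value.
#' @param rates a [rate_set] providing the fixed `k_on`, `k_off`, the
#'   starting ternary rates, and the fixed PHH affinity.
#' @param K_D_PHH_fixed PHH affinity held fixed (molar); default from `rates`.
#' @param model kinetic model for the predictions; the default `"3state"`
#'   neglects PHH (appropriate for a large excess of P), `"4state"` includes
#'   it.
#' @return list of class `ternary_fit`: fitted [rate_set], `k_on_PPH_se`,
#'   `k_off_PPH_se`, `chisq`, `dof`, the weight vector, the Jacobian
#'   condition number `kappa` (large values flag unidentifiable parameter
#'   combinations), and the underlying `nls.lm` object.
#' @export
global_fit_ternary <- function(data, rates, K_D_PHH_fixed = rates$K_D_PHH,
                               model = c("3state", "4state")) {
  model <- match.arg(model)
  stopifnot(inherits(rates, "rate_set"),
            all(c("c_P_tot", "c_H_tot", "observable", "value") %in%
                  names(data)))
  if (!all(data$observable %in% c("k_on_obs", "k_off_obs", "k_ex")))
    stop("unknown observable name(s) in data")
  sd <- if ("sd" %in% names(data)) data$sd else rep(NA_real_, nrow(data))
  sd[!is.finite(sd) | sd <= 0] <- 0.1 * abs(data$value[!is.finite(sd) | sd <= 0])
  w <- 1 / sd

  predict_one <- function(rs, cp, ch, obs) {
    if (model == "3state") {
      r <- observed_rates_3state(rs, cp, ch)
      switch(obs, k_on_obs = r[["k_on_obs"]], k_off_obs = r[["k_off_obs"]],
             k_ex = r[["k_on_obs"]] + r[["k_off_obs"]])
    } else {
      conc <- solve_species_concentrations(cp, ch, rs, include_PHH = TRUE)
      dw <- mean_dwell_times(build_K4P(rs, conc), low_states = "P")
      switch(obs, k_on_obs = dw$k_on_obs, k_off_obs = dw$k_off_obs,
             k_ex = dw$k_ex)
    }
  }
  make_rates <- function(par) {
    k_on_T <- exp(par[1]); k_off_T <- exp(par[2])
    rate_set(rates$k_on, rates$k_off, k_on_T, k_off_T,
             k_on_T, k_on_T * K_D_PHH_fixed)
  }
  resid_fn <- function(par) {
    rs <- make_rates(par)
    pred <- mapply(predict_one, cp = data$c_P_tot, ch = data$c_H_tot,
                   obs = data$observable, MoreArgs = list(rs = rs))
    w * (data$value - pred)
  }
  start <- c(log(rates$k_on_PPH), log(rates$k_off_PPH))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  par <- fit$par
  ## covariance of log-parameters from J'J (weighted residuals)
  J <- numeric_jacobian(resid_fn, par)
  JtJ <- crossprod(J)
  kappa <- tryCatch(kappa(JtJ, exact = TRUE), error = function(e) Inf)
  dof <- max(nrow(data) - length(par), 1L)
  s2 <- sum(fit$fvec^2) / dof
  cov_log <- tryCatch(solve(JtJ) * s2, error = function(e) {
    warning("singular Jacobian: parameters not identifiable"); matrix(NA, 2, 2)
  })
  se_log <- sqrt(pmax(diag(cov_log), 0))
  rs_fit <- make_rates(par)
  structure(list(
    rates = rs_fit,
    k_on_PPH = rs_fit$k_on_PPH, k_off_PPH = rs_fit$k_off_PPH,
    k_on_PPH_se = rs_fit$k_on_PPH * se_log[1],
    k_off_PPH_se = rs_fit$k_off_PPH * se_log[2],
    cov_log = cov_log, kappa = kappa,
    chisq = sum(fit$fvec^2), dof = dof, weights = w, nls_lm = fit,
    model = model),
    class = "ternary_fit")
}

#' @export
print.ternary_fit <- function(x, ...) {
  cat("Global ternary-complex kinetic fit (", x$model, " model)\n", sep = "")
  cat(sprintf("  k_on_PPH  = %.4g +/- %.2g /M/s\n", x$k_on_PPH, x$k_on_PPH_se))
  cat(sprintf("  k_off_PPH = %.4g +/- %.2g /s\n", x$k_off_PPH, x$k_off_PPH_se))
  cat(sprintf("  chi^2/dof = %.3g, Jacobian condition number = %.3g\n",
              x$chisq / x$dof, x$kappa))
  if (is.finite(x$kappa) && x$kappa > 1e8)
    cat("  WARNING: parameter combination poorly identified\n")
  invisible(x)
}

## central-difference Jacobian
numeric_jacobian <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    hp <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hp
    xm <- x; xm[i] <- x[i] - hp
    J[, i] <- (f(xp) - f(xm)) / (2 * hp)
  }
  J
}
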