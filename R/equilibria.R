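#' Two-state binding isotherm with ligand depletion
#'
#' Exact bound fraction of a labeled species P* titrated with ligand H for
#' the single reaction P* + H = P*H, from the quadratic root of the mass
#' balance (valid at any labeled concentration, i.e. including depletion of
#' the ligand pool by the labeled species).
#'
#' @param c_H_tot total ligand concentration (molar, scalar or vector).
#' @param c_Pstar_tot total labeled-species concentration (molar).
#' @param K_D_star dissociation constant of the labeled complex (molar).
#' @return bound fraction theta in \[0, 1\], same length as `c_H_tot`.
#' @examples
#' two_state_bound_fraction(0.73e-9, 1e-15, 0.73e-9)  # ~ 0.5 in dilute limit
#' @export
two_state_bound_fraction <- function(c_H_tot, c_Pstar_tot, K_D_star) {
  check_nonneg(c_H_tot, "c_H_tot")
  check_nonneg(c_Pstar_tot, "c_Pstar_tot")
  check_pos(K_D_star, "K_D_star")
  if (c_Pstar_tot == 0) {
    ## dilute-labeled limit: Langmuir isotherm in free = total ligand
    return(c_H_tot / (c_H_tot + K_D_star))
  }
  s <- c_H_tot + K_D_star + c_Pstar_tot
  ## rationalized root: stable when c_Pstar_tot << s
  th <- 2 * c_H_tot / (s + sqrt(s^2 - 4 * c_H_tot * c_Pstar_tot))
  pmin(pmax(th, 0), 1)
}

#' Bound fraction of a trace-labeled species in a competition titration
#'
#' Fraction of trace-labeled P* bound to H when an unlabeled competitor P
#' (total concentration `c_P_tot`) shares the ligand pool, for the coupled
#' reactions P* + H = P*H (affinity `K_D_star`) and P + H = PH (affinity
#' `K_D`). Valid in the limit where the labeled species is present in trace
#' amounts (it does not deplete either pool); no explicit labeled
#' concentration enters.
#'
#' @param c_P_tot total competitor concentration (molar, scalar or vector).
#' @param c_H_tot total ligand concentration (molar).
#' @param K_D_star labeled-complex dissociation constant (molar).
#' @param K_D unlabeled-complex dissociation constant (molar).
#' @return bound fraction of the labeled species, in \[0, 1\].
#' @details The closed form is algebraically singular where the denominator
#'   vanishes (e.g. `c_P_tot = 0` with `K_D_star = K_D`); those points are
#'   evaluated through the free-ligand route, which is exact in the trace
#'   limit.
#' @export
competition_bound_fraction <- function(c_P_tot, c_H_tot, K_D_star, K_D) {
  check_nonneg(c_P_tot, "c_P_tot")
  check_nonneg(c_H_tot, "c_H_tot")
  check_pos(K_D_star, "K_D_star")
  check_pos(K_D, "K_D")
  num <- c_H_tot * K_D_star - c_P_tot * K_D_star - 2 * c_H_tot * K_D -
    K_D_star * K_D +
    K_D_star * sqrt((K_D + c_P_tot - c_H_tot)^2 + 4 * c_H_tot * K_D)
  den <- 2 * (c_H_tot * (K_D_star - K_D) + K_D_star * (K_D_star - c_P_tot - K_D))
  th <- num / den
  ## fall back to the (equivalent) free-ligand evaluation where the closed
  ## form is numerically degenerate
  bad <- !is.finite(th) | abs(den) < 1e-12 * K_D_star * (K_D_star + c_H_tot + c_P_tot)
  if (any(bad)) {
    th[bad] <- vapply(c_P_tot[bad], function(cp) {
      cH <- free_ligand_competition(cp, c_H_tot, K_D)
      cH / (cH + K_D_star)
    }, numeric(1))
  }
  pmin(pmax(th, 0), 1)
}

## free H for P + H = PH at totals (c_P_tot, c_H_tot): quadratic root
free_ligand_competition <- function(c_P_tot, c_H_tot, K_D) {
  b <- c_P_tot + K_D - c_H_tot
  (-b + sqrt(b^2 + 4 * K_D * c_H_tot)) / 2
}

#' Midpoint of a competition titration
#'
#' Total competitor concentration at which the bound fraction of the labeled
#' species equals one half (absolute, not half of the plateau).
#'
#' @inheritParams competition_bound_fraction
#' @param upper upper search bound (molar), default 1 mM.
#' @return midpoint concentration (molar).
#' @export
competition_midpoint <- function(c_H_tot, K_D_star, K_D, upper = 1e-3) {
  f <- function(cp) competition_bound_fraction(cp, c_H_tot, K_D_star, K_D) - 0.5
  if (f(0) < 0) stop("bound fraction below 1/2 already without competitor")
  stats::uniroot(f, c(0, upper), tol = 1e-18)$root
}

#' Bound fraction of the second-ligand (PHH) isotherm
#'
#' Fraction of the labeled species present as P*HH when the labeled pool is
#' entirely partitioned between P*H and P*HH (unbound P* negligible), for the
#' reaction P*H + H = P*HH. Formally identical to the depletion isotherm with
#' `K_D_PHH` in place of the dimer affinity.
#'
#' @param c_H_tot total ligand concentration (molar).
#' @param c_Pstar_tot total labeled concentration (molar).
#' @param K_D_PHH dissociation constant of the second ligand binding (molar).
#' @return fraction P*HH of total labeled species, in \[0, 1\].
#' @export
phh_bound_fraction <- function(c_H_tot, c_Pstar_tot, K_D_PHH) {
  two_state_bound_fraction(c_H_tot, c_Pstar_tot, K_D_PHH)
}

#' Solve the coupled multi-species equilibrium
#'
#' Free and complex concentrations for the scheme P + H = PH,
#' P + PH = PPH, PH + H = PHH at given totals. Given the free ligand
#' concentration `c_H`, the P mass balance is a quadratic in the free `c_P`
#' with an analytic positive root; the remaining scalar H mass-balance
#' residual is bracketed on \[0, c_H_tot\] and solved by 1-D root finding,
#' which is exact and unconditionally convergent for non-negative totals.
#'
#' @param c_P_tot,c_H_tot total concentrations (molar).
#' @param rates a [rate_set] (only the derived K_D values are used).
#' @param include_PHH logical; include the PHH ternary complex (default TRUE).
#' @param c_Pstar_tot labeled-species total, stored for bookkeeping only; the
#'   labeled species is treated as strictly infinitesimal and never depletes
#'   the pools.
#' @return An object of class `concentration_state`: list with `c_P`, `c_H`,
#'   `c_PH`, `c_PPH`, `c_PHH`, the totals, and `theta`, the equilibrium bound
#'   fraction of a trace-labeled P (all complex states counted as bound).
#' @examples
#' solve_species_concentrations(100e-9, 10e-9, prota_h1_rates(),
#'                              include_PHH = FALSE)
#' @export
solve_species_concentrations <- function(c_P_tot, c_H_tot, rates,
                                         include_PHH = TRUE,
                                         c_Pstar_tot = 0) {
  stopifnot(inherits(rates, "rate_set"))
  check_nonneg(c_P_tot, "c_P_tot")
  check_nonneg(c_H_tot, "c_H_tot")
  KD <- rates$K_D; KDpph <- rates$K_D_PPH
  KDphh <- if (include_PHH) rates$K_D_PHH else Inf

  cP_given_cH <- function(cH) {
    ## c_P (1 + cH/KD + cH^2/(KD*KDphh)) + 2 c_P^2 cH/(KD*KDpph) = c_P_tot
    a <- 2 * cH / (KD * KDpph)
    b <- 1 + cH / KD + (if (is.finite(KDphh)) cH^2 / (KD * KDphh) else 0)
    if (a * c_P_tot > 0) {
      ## stable quadratic root
      2 * c_P_tot / (b + sqrt(b^2 + 4 * a * c_P_tot))
    } else c_P_tot / b
  }
  residH <- function(cH) {
    cP <- cP_given_cH(cH)
    cPH <- cP * cH / KD
    cPPH <- cP * cPH / KDpph
    cPHH <- if (is.finite(KDphh)) cH * cPH / KDphh else 0
    cH + cPH + cPPH + 2 * cPHH - c_H_tot
  }
  cH <- if (c_H_tot == 0) 0 else
    stats::uniroot(residH, c(0, c_H_tot), tol = 1e-15 * max(c_H_tot, 1e-30),
                   maxiter = 10000L)$root
  cP <- cP_given_cH(cH)
  cPH <- cP * cH / KD
  cPPH <- cP * cPH / KDpph
  cPHH <- if (is.finite(KDphh)) cH * cPH / KDphh else 0
  bound <- cPH + cPPH + cPHH
  theta <- if (cP + bound > 0) bound / (cP + bound) else 0
  structure(list(c_P = cP, c_H = cH, c_PH = cPH, c_PPH = cPPH, c_PHH = cPHH,
                 c_P_tot = c_P_tot, c_H_tot = c_H_tot,
                 c_Pstar_tot = c_Pstar_tot, theta = theta,
                 include_PHH = include_PHH),
            class = "concentration_state")
}

#' @export
print.concentration_state <- function(x, ...) {
  cat("Equilibrium species concentrations (M):\n")
  v <- unlist(x[c("c_P", "c_H", "c_PH", "c_PPH", "c_PHH")])
  print(signif(v, 4))
  cat(sprintf("totals: c_P_tot = %.4g, c_H_tot = %.4g; theta = %.4f\n",
              x$c_P_tot, x$c_H_tot, x$theta))
  invisible(x)
}

#' Verify mass conservation of a concentration state
#'
#' @param conc a `concentration_state`.
#' @param tol relative tolerance, default 1e-9.
#' @return TRUE invisibly; errors if conservation is violated.
#' @export
check_conservation <- function(conc, tol = 1e-9) {
  pt <- conc$c_P + conc$c_PH + 2 * conc$c_PPH + conc$c_PHH
  ht <- conc$c_H + conc$c_PH + conc$c_PPH + 2 * conc$c_PHH
  relP <- abs(pt - conc$c_P_tot) / max(conc$c_P_tot, 1e-30)
  relH <- abs(ht - conc$c_H_tot) / max(conc$c_H_tot, 1e-30)
  if (relP > tol || relH > tol)
    stop(sprintf("mass conservation violated (rel. err. P: %.2e, H: %.2e)",
                 relP, relH))
  invisible(TRUE)
}

#' Species population fractions along a competitor titration
#'
#' Solves the coupled equilibrium on a grid of total competitor (P)
#' concentrations and normalizes as in a titration diagram: the free-P
#' fraction by the total P concentration; the H, PH, PPH and PHH fractions by
#' the total H concentration (so the H-normalized columns account for all H:
#' `H + PH + PPH + 2 PHH = c_H_tot`).
#'
#' @param c_P_tot_grid vector of total P concentrations (molar).
#' @param c_H_tot total H concentration (molar).
#' @param rates a [rate_set].
#' @param include_PHH include the PHH complex (default TRUE).
#' @return data.frame with columns `c_P_tot`, `P`, `H`, `PH`, `PPH`, `PHH`.
#' @export
population_fractions <- function(c_P_tot_grid, c_H_tot, rates,
                                 include_PHH = TRUE) {
  rows <- lapply(c_P_tot_grid, function(cp) {
    s <- solve_species_concentrations(cp, c_H_tot, rates, include_PHH)
    data.frame(c_P_tot = cp,
               P   = if (cp > 0) s$c_P / cp else 1,
               H   = s$c_H / c_H_tot,
               PH  = s$c_PH / c_H_tot,
               PPH = s$c_PPH / c_H_tot,
               PHH = s$c_PHH / c_H_tot)
  })
  do.call(rbind, rows)
}

#' Fit a binding isotherm to a titration table
#'
#' Weighted nonlinear least-squares fit of the depletion isotherm
#' ([two_state_bound_fraction], also used for the PHH second-ligand isotherm)
#' to measured bound fractions versus total ligand concentration.
#'
#' @param c_H_tot vector of total ligand concentrations (molar).
#' @param theta measured bound fractions.
#' @param c_Pstar_tot labeled total concentration (molar), fixed.
#' @param sd optional standard deviations for weighting.
#' @param K_D_init starting value (molar); default: concentration at
#'   half-maximal theta.
#' @return list with `K_D`, `K_D_sd`, and the `nls` fit object.
#' @export
fit_isotherm <- function(c_H_tot, theta, c_Pstar_tot, sd = NULL,
                         K_D_init = NULL) {
  stopifnot(length(c_H_tot) == length(theta))
  if (is.null(K_D_init))
    K_D_init <- stats::approx(theta, c_H_tot, xout = 0.5, ties = mean,
                              rule = 2)$y
  w <- if (is.null(sd)) rep(1, length(theta)) else 1 / sd^2
  dat <- data.frame(cH = c_H_tot, th = theta)
  fit <- minpack.lm::nlsLM(
    th ~ two_state_bound_fraction_v(cH, c_Pstar_tot, exp(lK)),
    data = dat, start = list(lK = log(K_D_init)), weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  lK <- stats::coef(fit)[["lK"]]
  lK_sd <- summary(fit)$coefficients["lK", "Std. Error"]
  list(K_D = exp(lK), K_D_sd = exp(lK) * lK_sd, fit = fit)
}

## vectorized isotherm for nls formulas
two_state_bound_fraction_v <- function(c_H_tot, c_Pstar_tot, K_D_star) {
  vapply(c_H_tot, two_state_bound_fraction, numeric(1),
         c_Pstar_tot = c_Pstar_tot, K_D_star = K_D_star)
}

#' Fit the competition isotherm to a competitor titration
#'
#' Fits the coupled-equilibrium closed form
#' ([competition_bound_fraction]) with the labeled affinity fixed and the
#' competitor affinity free.
#'
#' @param c_P_tot vector of total competitor concentrations (molar).
#' @param theta measured bound fractions of the labeled species.
#' @param c_H_tot total ligand concentration (molar), fixed.
#' @param K_D_star labeled affinity (molar), fixed.
#' @param sd optional standard deviations for weighting.
#' @return list with `K_D`, `K_D_sd`, and the `nls` fit object.
#' @export
fit_competition <- function(c_P_tot, theta, c_H_tot, K_D_star, sd = NULL) {
  w <- if (is.null(sd)) rep(1, length(theta)) else 1 / sd^2
  dat <- data.frame(cP = c_P_tot, th = theta)
  fit <- minpack.lm::nlsLM(
    th ~ competition_bound_fraction(cP, c_H_tot, K_D_star, exp(lK)),
    data = dat, start = list(lK = log(K_D_star)), weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  lK <- stats::coef(fit)[["lK"]]
  lK_sd <- summary(fit)$coefficients["lK", "Std. Error"]
  list(K_D = exp(lK), K_D_sd = exp(lK) * lK_sd, fit = fit)
}
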