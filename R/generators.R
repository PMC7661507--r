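#' Continuous-time Markov generator with equilibrium distribution
#'
#' Internal constructor: validates the generator property (non-negative
#' off-diagonal entries, zero column sums) and computes the stationary
#' distribution from the null space of K.
#'
#' @param K square rate matrix, column convention (dp/dt = K p), 1/s entries.
#' @param state_labels character vector of state names.
#' @return object of class `generator_matrix` with elements `K`,
#'   `state_labels`, `p_eq`.
#' @export
generator_matrix <- function(K, state_labels = colnames(K)) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  n <- nrow(K)
  if (is.null(state_labels)) state_labels <- paste0("S", seq_len(n))
  offdiag <- K; diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("off-diagonal generator entries must be >= 0")
  colsum <- colSums(K)
  if (any(abs(colsum) > 1e-10 * max(abs(K), 1)))
    stop("columns of a generator must sum to zero")
  p_eq <- stationary_distribution(K)
  dimnames(K) <- list(state_labels, state_labels)
  names(p_eq) <- state_labels
  structure(list(K = K, state_labels = state_labels, p_eq = p_eq),
            class = "generator_matrix")
}

#' Stationary distribution of a generator
#'
#' Solves K p = 0 with 1' p = 1 by replacing one balance equation with the
#' normalization constraint (well-conditioned for irreducible generators).
#'
#' @param K generator matrix (column convention).
#' @return probability vector.
#' @export
stationary_distribution <- function(K) {
  n <- nrow(K)
  A <- rbind(K[-n, , drop = FALSE], rep(1, n))
  b <- c(rep(0, n - 1), 1)
  p <- solve(A, b)
  if (any(p < -1e-8)) stop("no non-negative stationary distribution (reducible chain?)")
  p <- pmax(p, 0)
  p / sum(p)
}

#' @export
print.generator_matrix <- function(x, ...) {
  cat("Continuous-time Markov generator (", length(x$state_labels),
      " states)\n", sep = "")
  print(signif(x$K, 4))
  cat("p_eq:", paste(sprintf("%s=%.4g", x$state_labels, x$p_eq),
                     collapse = ", "), "\n")
  invisible(x)
}

#' Two-state generator for an immobilized labeled molecule
#'
#' States (unbound P*, bound P*H) with pseudo-first-order association
#' `k_on_obs = k_on * c_H` and dissociation `k_off`.
#'
#' @param rates a [rate_set].
#' @param c_H free ligand concentration (molar).
#' @return [generator_matrix] with states `c("U", "B")`.
#' @export
build_K2 <- function(rates, c_H) {
  stopifnot(inherits(rates, "rate_set"))
  check_nonneg(c_H, "c_H")
  kon_obs <- rates$k_on * c_H
  K <- matrix(c(-kon_obs, rates$k_off,
                 kon_obs, -rates$k_off), 2, 2, byrow = TRUE)
  generator_matrix(K, c("U", "B"))
}

#' Three-state generator for labeled P (PHH excluded)
#'
#' States (P*, P*H, P*PH). The ternary complex P*PH dissociates to
#' P* + PH or to P*H + P with equal likelihood, giving the factors 1/2 on the
#' two dissociation entries. Solution concentrations are those of the
#' unlabeled species at bulk equilibrium; the labeled molecule never depletes
#' them.
#'
#' @param rates a [rate_set].
#' @param conc a `concentration_state` solved with the PHH complex excluded.
#' @param branch_PPH branching fraction of P*PH dissociation towards
#'   P* + PH (default 0.5).
#' @return [generator_matrix] with states `c("P", "PH", "PPH")`.
#' @export
build_K3P <- function(rates, conc, branch_PPH = 0.5) {
  stopifnot(inherits(rates, "rate_set"), inherits(conc, "concentration_state"))
  if (isTRUE(conc$include_PHH))
    stop("conc must be solved with include_PHH = FALSE for the 3-state model")
  kD  <- rates$k_off; kPPH <- rates$k_off_PPH
  a1 <- rates$k_on * conc$c_H          # P* -> P*H
  a2 <- rates$k_on_PPH * conc$c_PH     # P* -> P*PH
  a3 <- rates$k_on_PPH * conc$c_P      # P*H -> P*PH
  K <- matrix(c(
    -(a1 + a2),  kD,                   branch_PPH * kPPH,
     a1,        -(kD + a3),            (1 - branch_PPH) * kPPH,
     a2,         a3,                  -kPPH), 3, 3, byrow = TRUE)
  generator_matrix(K, c("P", "PH", "PPH"))
}

#' Four-state generator for labeled P
#'
#' States (P*, P*H, P*PH, P*HH). The PPH dissociation splits 1/2 towards
#' P* + PH and 1/2 towards P*H + P; P*HH dissociates to P*H + H with its full
#' rate (loss of the labeled P from PHH would produce unlabeled species and
#' is not a pathway of the labeled molecule).
#'
#' @inheritParams build_K3P
#' @param conc a `concentration_state` (solved with PHH included).
#' @return [generator_matrix] with states `c("P", "PH", "PPH", "PHH")`.
#' @export
build_K4P <- function(rates, conc, branch_PPH = 0.5) {
  stopifnot(inherits(rates, "rate_set"), inherits(conc, "concentration_state"))
  kD <- rates$k_off; kPPH <- rates$k_off_PPH; kPHH <- rates$k_off_PHH
  a1 <- rates$k_on * conc$c_H          # P* -> P*H
  a2 <- rates$k_on_PPH * conc$c_PH     # P* -> P*PH
  a3 <- rates$k_on_PPH * conc$c_P      # P*H -> P*PH
  a4 <- rates$k_on_PHH * conc$c_H      # P*H -> P*HH
  K <- matrix(c(
    -(a1 + a2),  kD,                  branch_PPH * kPPH,       0,
     a1,        -(kD + a3 + a4),      (1 - branch_PPH) * kPPH, kPHH,
     a2,         a3,                 -kPPH,                    0,
     0,          a4,                  0,                      -kPHH),
    4, 4, byrow = TRUE)
  generator_matrix(K, c("P", "PH", "PPH", "PHH"))
}

#' Four-state generator for labeled H
#'
#' States (H*, PH*, PPH*, PH*H), valid for experiments observing labeled H.
#' Here the roles are mirrored: the PHH complex contains two H molecules, so
#' its dissociation carries the factors 1/2, while PPH* loses its single
#' labeled H with the full rate.
#'
#' @inheritParams build_K3P
#' @param conc a `concentration_state` (solved with PHH included).
#' @param branch_PHH branching fraction of PH*H dissociation towards
#'   H* + PH (default 0.5).
#' @return [generator_matrix] with states `c("H", "PH", "PPH", "PHH")`.
#' @export
build_K4H <- function(rates, conc, branch_PHH = 0.5) {
  stopifnot(inherits(rates, "rate_set"), inherits(conc, "concentration_state"))
  kD <- rates$k_off; kPPH <- rates$k_off_PPH; kPHH <- rates$k_off_PHH
  a1 <- rates$k_on * conc$c_P          # H* -> PH*
  a2 <- rates$k_on_PHH * conc$c_PH     # H* -> PH*H
  a3 <- rates$k_on_PPH * conc$c_P      # PH* -> PPH*
  a4 <- rates$k_on_PHH * conc$c_H      # PH* -> PH*H
  K <- matrix(c(
    -(a1 + a2),  kD,                  0,      branch_PHH * kPHH,
     a1,        -(kD + a3 + a4),      kPPH,   (1 - branch_PHH) * kPHH,
     0,          a3,                 -kPPH,   0,
     a2,         a4,                  0,     -kPHH),
    4, 4, byrow = TRUE)
  generator_matrix(K, c("H", "PH", "PPH", "PHH"))
}

#' Mean dwell times of aggregated low/high states
#'
#' Mean dwell time of a state aggregate at stationarity: equilibrium
#' occupancy of the aggregate divided by the equilibrium probability flux
#' leaving it. Reported for the `low` aggregate (unbound-like states) and its
#' complement, together with the observed pseudo-first-order rates
#' `k_on_obs = 1/tau_low`, `k_off_obs = 1/tau_high` and their sum `k_ex`.
#'
#' @param gen a [generator_matrix].
#' @param low_states labels (or indices) of the low-FRET (unbound) aggregate.
#' @return list of class `dwell_result`: `tau_low`, `tau_high`, `k_on_obs`,
#'   `k_off_obs`, `k_ex`.
#' @export
mean_dwell_times <- function(gen, low_states = "P") {
  stopifnot(inherits(gen, "generator_matrix"))
  n <- nrow(gen$K)
  idx <- if (is.character(low_states)) match(low_states, gen$state_labels)
         else as.integer(low_states)
  if (any(is.na(idx))) stop("unknown state labels in low_states")
  high <- setdiff(seq_len(n), idx)
  if (length(high) == 0L) stop("low_states must not cover all states")
  p <- gen$p_eq
  if (any(p <= 0))
    stop("reducible chain: states with zero equilibrium occupancy: ",
         paste(gen$state_labels[p <= 0], collapse = ", "))
  flux_low_out  <- sum(gen$K[high, idx, drop = FALSE] %*% p[idx])
  flux_high_out <- sum(gen$K[idx, high, drop = FALSE] %*% p[high])
  tau_low  <- sum(p[idx]) / flux_low_out
  tau_high <- sum(p[high]) / flux_high_out
  structure(list(tau_low = tau_low, tau_high = tau_high,
                 k_on_obs = 1 / tau_low, k_off_obs = 1 / tau_high,
                 k_ex = 1 / tau_low + 1 / tau_high),
            class = "dwell_result")
}

#' @export
print.dwell_result <- function(x, ...) {
  cat(sprintf("tau_low = %.4g s, tau_high = %.4g s\n", x$tau_low, x$tau_high))
  cat(sprintf("k_on_obs = %.4g /s, k_off_obs = %.4g /s, k_ex = %.4g /s\n",
              x$k_on_obs, x$k_off_obs, x$k_ex))
  invisible(x)
}

#' Closed-form mean bound-state dwell time of the three-state model
#'
#' Rational closed form for the mean dwell time of the aggregated bound
#' states (P*H, P*PH) of the three-state model, as a function of the bulk
#' equilibrium concentrations and rate coefficients. Equals
#' [mean_dwell_times] applied to [build_K3P].
#'
#' @param rates a [rate_set].
#' @param conc `concentration_state` solved with PHH excluded.
#' @return mean bound dwell time (seconds).
#' @export
tau_high_3state <- function(rates, conc) {
  stopifnot(inherits(rates, "rate_set"), inherits(conc, "concentration_state"))
  cH <- conc$c_H; cP <- conc$c_P; cPH <- conc$c_PH
  kon <- rates$k_on; koff <- rates$k_off
  konT <- rates$k_on_PPH; koffT <- rates$k_off_PPH
  num <- 2 * cH * kon * (koffT + cP * konT) +
    cPH * konT * (2 * koff + koffT + 2 * cP * konT)
  den <- koffT * (2 * koff + cP * konT) * (cH * kon + cPH * konT)
  if (den == 0) stop("degenerate rate/concentration combination (zero denominator)")
  num / den
}

#' Exchange rate between bound and unbound labeled species
#'
#' Sum of the observed pseudo-first-order association and dissociation rates,
#' `k_ex = 1/tau_low + 1/tau_high`, under the chosen kinetic model. For the
#' 2-state model this is `k_on * c_H + k_off` (observing P) or
#' `k_on * c_P + k_off` (observing H) exactly.
#'
#' @param rates a [rate_set].
#' @param conc a `concentration_state` at the conditions of interest. For
#'   `model = "3state"` it must be solved with PHH excluded.
#' @param observed which species carries the label, `"P"` or `"H"`.
#' @param model `"2state"`, `"3state"` or `"4state"`.
#' @return exchange rate (1/s).
#' @export
exchange_rate <- function(rates, conc, observed = c("P", "H"),
                          model = c("4state", "3state", "2state")) {
  observed <- match.arg(observed)
  model <- match.arg(model)
  if (model == "2state") {
    cX <- if (observed == "P") conc$c_H else conc$c_P
    return(rates$k_on * cX + rates$k_off)
  }
  gen <- if (model == "3state") {
    if (observed == "H") stop("3-state reduction is defined for observed P")
    build_K3P(rates, conc)
  } else if (observed == "P") build_K4P(rates, conc) else build_K4H(rates, conc)
  mean_dwell_times(gen, low_states = gen$state_labels[1])$k_ex
}

#' Observed rates of the three-state model at given conditions
#'
#' Convenience wrapper returning `k_on_obs` and `k_off_obs` for labeled P
#' under the three-state (PPH) model, used by the global concentration-
#' dependent fit. `k_on_obs = k_on c_H + k_on_PPH c_PH` is exact;
#' `k_off_obs = 1/tau_high` from the closed form.
#'
#' @param rates a [rate_set].
#' @param c_P_tot,c_H_tot totals (molar).
#' @return named vector `c(k_on_obs, k_off_obs)` (1/s).
#' @export
observed_rates_3state <- function(rates, c_P_tot, c_H_tot) {
  conc <- solve_species_concentrations(c_P_tot, c_H_tot, rates,
                                       include_PHH = FALSE)
  k_on_obs <- rates$k_on * conc$c_H + rates$k_on_PPH * conc$c_PH
  k_off_obs <- 1 / tau_high_3state(rates, conc)
  c(k_on_obs = k_on_obs, k_off_obs = k_off_obs)
}
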