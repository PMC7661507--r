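## Independent oracles used across the test files. These deliberately avoid
## the package's own solution paths: brute-force root scans, damped
## fixed-point iteration, Taylor-series matrix exponentials, and direct
## enumeration.

## Brute-force coupled equilibrium for P*/P/H with explicit labeled species:
## 1-D root scan over free H, mass balances solved per species.
oracle_competition_theta <- function(c_P_tot, c_H_tot, K_D_star, K_D,
                                     c_Pstar_tot = 1e-20) {
  resid <- function(cH) {
    cP <- c_P_tot / (1 + cH / K_D)
    cPs <- c_Pstar_tot / (1 + cH / K_D_star)
    cH + cP * cH / K_D + cPs * cH / K_D_star - c_H_tot
  }
  cH <- stats::uniroot(resid, c(0, c_H_tot), tol = 1e-20)$root
  (cH / K_D_star) / (1 + cH / K_D_star)
}

## Two-species isotherm with depletion, solved by root scan on free H.
oracle_isotherm_theta <- function(c_H_tot, c_Pstar_tot, K_D_star) {
  if (c_H_tot == 0) return(0)
  resid <- function(cH) cH + c_Pstar_tot * cH / (cH + K_D_star) - c_H_tot
  cH <- stats::uniroot(resid, c(0, c_H_tot), tol = 1e-20)$root
  cH / (cH + K_D_star)
}

## Damped (geometric-mean) alternating fixed point on (c_P, c_H) for the
## full ternary system; contraction-safe even for strong binding.
oracle_species_fixed_point <- function(c_P_tot, c_H_tot, KD, KDpph,
                                       KDphh = Inf, tol = 1e-13,
                                       max_iter = 500000) {
  cP <- c_P_tot; cH <- c_H_tot
  phh <- function(cH) if (is.finite(KDphh)) cH^2 / (KD * KDphh) else 0
  for (i in seq_len(max_iter)) {
    cP_new <- c_P_tot / (1 + cH / KD + 2 * cP * cH / (KD * KDpph) + phh(cH))
    cH_new <- c_H_tot / (1 + cP / KD + cP^2 / (KD * KDpph) +
                           2 * cP * cH / (KD * ifelse(is.finite(KDphh),
                                                      KDphh, Inf)))
    cP2 <- sqrt(cP * cP_new); cH2 <- sqrt(cH * cH_new)
    done <- abs(cP2 - cP) < tol * max(cP, 1e-300) &&
      abs(cH2 - cH) < tol * max(cH, 1e-300)
    cP <- cP2; cH <- cH2
    if (done) break
  }
  cPH <- cP * cH / KD
  c(P = cP, H = cH, PH = cPH, PPH = cP * cPH / KDpph,
    PHH = if (is.finite(KDphh)) cH * cPH / KDphh else 0)
}

## Dense matrix exponential by plain Taylor series (scaling by powers of 2).
oracle_matexp <- function(A, n_terms = 40) {
  n <- nrow(A)
  s <- max(0, ceiling(log2(max(max(abs(A)), 1e-300))) + 2)
  As <- A / 2^s
  E <- diag(n); term <- diag(n)
  for (k in seq_len(n_terms)) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

## Brute-force photon-trace likelihood using the Taylor matexp.
oracle_trace_loglik <- function(trace, K, nD, nA, p_eq) {
  M <- K - diag(nD + nA)
  v <- p_eq
  logl <- 0
  for (i in seq_along(trace$tau)) {
    if (i > 1) v <- oracle_matexp(M * trace$tau[i]) %*% v
    v <- v * (if (trace$color[i] == 0L) nD else nA)
    s <- sum(v)
    if (s <= 0) return(-Inf)
    logl <- logl + log(s)
    v <- v / s
  }
  logl
}

## Rate sets used repeatedly: the system defaults, and a generic random one.
default_rates <- function() prota_h1_rates()

random_rate_set <- function() {
  rate_set(k_on = 10^stats::runif(1, 8, 10), k_off = 10^stats::runif(1, -1, 1),
           k_on_PPH = 10^stats::runif(1, 8, 10),
           k_off_PPH = 10^stats::runif(1, 2, 4),
           k_on_PHH = 10^stats::runif(1, 8, 10),
           k_off_PHH = 10^stats::runif(1, 2, 4))
}

## True per-photon states of a simulated trace given its generating path.
true_photon_states <- function(trace, path) {
  seg_start <- path$t
  path$state[findInterval(trace$t, seg_start)]
}
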