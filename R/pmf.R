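#' Umbrella-sampling window
#'
#' @param center bias center r0 (nm).
#' @param k_umb harmonic force constant (kJ/mol/nm^2).
#' @param samples reaction-coordinate samples r (nm).
#' @return object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k_umb, samples) {
  check_pos(k_umb, "k_umb")
  check_nonneg(samples, "samples")
  structure(list(center = center, k_umb = k_umb, samples = samples),
            class = "umbrella_window")
}

#' One-dimensional weighted histogram analysis (WHAM)
#'
#' Self-consistent reconstruction of the unbiased potential of mean force
#' W(r) from harmonically biased umbrella windows. Iterates the standard
#' coupled equations for the unbiased density and the per-window free-energy
#' offsets until the offsets change by less than `tol`; W is anchored to zero
#' at the largest sampled distance.
#'
#' @param windows list of [umbrella_window] objects.
#' @param bins number of histogram bins (default 200) or an explicit vector
#'   of bin edges.
#' @param tol convergence tolerance on the free-energy offsets (kJ/mol),
#'   default 1e-8.
#' @param temperature kelvin, default 300.
#' @param max_iter iteration cap.
#' @return data.frame of class `pmf_profile`: `r` (bin centers), `W`
#'   (kJ/mol), `counts`; attributes `f_offsets`, `temperature`, `beta`.
#' @export
wham_1d <- function(windows, bins = 200, tol = 1e-8, temperature = 300,
                    max_iter = 50000) {
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, inherits, logical(1), "umbrella_window")))
  kB <- polyion_constants$kB_kJ
  beta <- 1 / (kB * temperature)
  allr <- unlist(lapply(windows, `[[`, "samples"))
  edges <- if (length(bins) == 1L)
    seq(min(allr), max(allr), length.out = bins + 1) else bins
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(mids)
  S <- length(windows)
  H <- vapply(windows, function(w)
    graphics::hist(w$samples, breaks = edges, plot = FALSE,
                   include.lowest = TRUE)$counts, numeric(nb))
  N <- colSums(H)                      # samples per window
  ## adjacent-window overlap check
  if (S > 1L) {
    ord <- order(vapply(windows, `[[`, numeric(1), "center"))
    for (i in seq_len(S - 1L)) {
      a <- ord[i]; b <- ord[i + 1L]
      if (sum(H[, a] > 0 & H[, b] > 0) == 0L)
        stop(sprintf("no histogram overlap between windows at %.3g and %.3g nm",
                     windows[[a]]$center, windows[[b]]$center))
    }
  }
  n_tot <- rowSums(H)                  # counts per bin over all windows
  ## bin-averaged bias weights (7-point midpoint rule per bin) rather than
  ## center-point evaluation: avoids the systematic offset drift that a
  ## steep bias accumulates across wide bins
  h <- diff(edges)
  sub <- (seq_len(7) - 4) / 7
  expb <- vapply(windows, function(w) {
    acc <- 0
    for (s in sub) {
      rr <- mids + s * h
      acc <- acc + exp(-beta * 0.5 * w$k_umb * (rr - w$center)^2)
    }
    acc / length(sub)
  }, numeric(nb))                       # nb x S
  f <- rep(0, S)                       # window free-energy offsets (kJ/mol)
  for (it in seq_len(max_iter)) {
    denom <- as.vector(expb %*% (N * exp(beta * f)))
    rho <- ifelse(denom > 0, n_tot / denom, 0)
    zs <- colSums(rho * expb)
    f_new <- -log(pmax(zs, 1e-300)) / beta
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  W <- -log(pmax(rho, 1e-300)) / beta
  keep <- n_tot > 0
  W[!keep] <- NA_real_
  ## anchor at the largest sampled r
  W <- W - W[max(which(keep))]
  out <- data.frame(r = mids, W = W, counts = n_tot)
  attr(out, "f_offsets") <- f
  attr(out, "temperature") <- temperature
  attr(out, "beta") <- beta
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Effective two-body radial potential
#'
#' `F(r) = W(r) + 2 k_B T ln r`, re-zeroed so that F vanishes at large
#' separation (mean over the outer 10 percent of the grid).
#'
#' @param pmf a `pmf_profile` (from [wham_1d]) or data.frame with `r`, `W`.
#' @param temperature kelvin, default taken from the profile (else 300).
#' @return data.frame `r`, `F` (kJ/mol) of class `effective_potential`, with
#'   attribute `beta`.
#' @export
effective_potential <- function(pmf, temperature = NULL) {
  if (is.null(temperature))
    temperature <- attr(pmf, "temperature") %||% 300
  kB <- polyion_constants$kB_kJ
  keep <- is.finite(pmf$W) & pmf$r > 0
  r <- pmf$r[keep]
  Fr <- pmf$W[keep] + 2 * kB * temperature * log(r)
  tail_idx <- r >= stats::quantile(r, 0.9)
  Fr <- Fr - mean(Fr[tail_idx])
  out <- data.frame(r = r, F = Fr)
  attr(out, "beta") <- 1 / (kB * temperature)
  attr(out, "temperature") <- temperature
  class(out) <- c("effective_potential", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## interpolator for F(r); constant extrapolation to 0 beyond the grid
f_interp <- function(Fprofile) {
  stats::splinefun(Fprofile$r, Fprofile$F, method = "monoH.FC")
}

## composite trapezoid with grid doubling until the relative change is
## below rel_tol; robust for integrands spanning many orders of magnitude
trap_integral <- function(f, lo, hi, rel_tol = 1e-6, n0 = 2001,
                          n_max = 2^21) {
  stopifnot(hi > lo)
  n <- n0
  last <- NA_real_
  repeat {
    x <- seq(lo, hi, length.out = n)
    y <- f(x)
    val <- sum((y[-1] + y[-n]) / 2) * (hi - lo) / (n - 1)
    if (!is.na(last) && abs(val - last) <= rel_tol * abs(val)) return(val)
    last <- val
    n <- 2L * n - 1L
    if (n > n_max) return(val)
  }
}

#' Equilibrium dissociation constant from a radial potential
#'
#' \deqn{K_D^{-1} = 4\pi N_A \int_0^c e^{-\beta F(r)} r^2\, dr}
#' with r in nm and F in kJ/mol; the result is molar. F is taken as its
#' interpolated value inside the grid and 0 outside. A warning is issued
#' when F is not flat at the cutoff `c`.
#'
#' @param Fprofile an `effective_potential` (data.frame `r`, `F`).
#' @param c_cut integration cutoff c (nm): the radius above which F is zero.
#' @param temperature kelvin (default from the profile).
#' @param rel_tol quadrature tolerance, default 1e-6.
#' @return K_D (molar), with attribute `KD_inv_M` (association constant).
#' @export
kd_from_pmf <- function(Fprofile, c_cut, temperature = NULL,
                        rel_tol = 1e-6) {
  temperature <- temperature %||% attr(Fprofile, "temperature") %||% 300
  beta <- 1 / (polyion_constants$kB_kJ * temperature)
  fi <- f_interp(Fprofile)
  rmin <- min(Fprofile$r); rmax <- max(Fprofile$r)
  Fval <- function(r) ifelse(r < rmin, fi(rmin), ifelse(r > rmax, 0, fi(r)))
  near_c <- abs(Fval(c_cut))
  if (near_c > 0.25 / beta)
    warning(sprintf(
      "F(c) = %.3g kJ/mol is not flat at c = %.3g nm; consider a larger cutoff",
      Fval(c_cut), c_cut))
  integrand <- function(r) exp(-beta * Fval(r)) * r^2
  I <- trap_integral(integrand, 0, c_cut, rel_tol = rel_tol)   # nm^3
  KD_inv <- 4 * pi * polyion_constants$N_A * I * polyion_constants$nm3_per_L
  structure(1 / KD_inv, KD_inv_M = KD_inv)
}

#' Diffusion-limited association rate from a radial potential
#'
#' Reactive flux onto an absorbing boundary at radius b through the
#' potential F(r):
#' \deqn{N_A\,k_{on}^{-1} = \int_b^c \frac{e^{\beta F(r)}}{4\pi r^2 D}dr +
#'   (4\pi D c)^{-1}.}
#' With F = 0 this reduces to the Smoluchowski rate `4 pi D b N_A`.
#'
#' @param Fprofile an `effective_potential`.
#' @param D relative diffusion coefficient (cm^2/s): sum of the monomer
#'   translational diffusion coefficients.
#' @param b absorbing-boundary radius (nm), 0 < b < c.
#' @param c_cut outer radius at which F vanishes (nm).
#' @param temperature kelvin.
#' @param rel_tol quadrature tolerance.
#' @return k_on (1/M/s).
#' @export
kon_from_pmf <- function(Fprofile, D, b, c_cut, temperature = NULL,
                         rel_tol = 1e-8) {
  if (b <= 0 || b >= c_cut) stop("need 0 < b < c")
  check_pos(D, "D")
  temperature <- temperature %||% attr(Fprofile, "temperature") %||% 300
  beta <- 1 / (polyion_constants$kB_kJ * temperature)
  D_nm <- D * polyion_constants$cm2_to_nm2        # nm^2/s
  fi <- f_interp(Fprofile)
  rmin <- min(Fprofile$r); rmax <- max(Fprofile$r)
  Fval <- function(r) ifelse(r < rmin, fi(rmin), ifelse(r > rmax, 0, fi(r)))
  integrand <- function(r) exp(beta * Fval(r)) / (4 * pi * r^2 * D_nm)
  I <- trap_integral(integrand, b, c_cut, rel_tol = rel_tol)   # s/nm^3
  inv_rate_nm <- I + 1 / (4 * pi * D_nm * c_cut)             # s/nm^3
  k_on_nm3 <- 1 / inv_rate_nm                                # nm^3/s
  k_on_nm3 * polyion_constants$nm3_per_L * polyion_constants$N_A
}

#' Capture radius from the plateau of the PMF-based association rate
#'
#' Scans the absorbing-boundary radius b downward from the outer cutoff and
#' returns the largest b at which k_on(b) has become constant: the relative
#' change of k_on per grid step falls below `tol`. A potential without an
#' attractive well has no plateau (k_on grows linearly in b); in that case
#' `NA` is returned rather than an error.
#'
#' @param Fprofile an `effective_potential`.
#' @param D relative diffusion coefficient (cm^2/s).
#' @param c_cut outer radius (nm).
#' @param tol relative plateau tolerance per step (default 0.01).
#' @param n_scan number of scan points (default 80).
#' @param b_min smallest boundary scanned (nm).
#' @return list with `b_star` (nm or NA), `scan` (data.frame `b`, `k_on`).
#' @export
capture_radius <- function(Fprofile, D, c_cut, tol = 0.01, n_scan = 80,
                           b_min = min(Fprofile$r[Fprofile$r > 0])) {
  bs <- seq(b_min, c_cut * 0.98, length.out = n_scan)
  ks <- vapply(bs, function(b) kon_from_pmf(Fprofile, D, b, c_cut),
               numeric(1))
  ## relative change of k_on between consecutive b (scanning downward)
  rel <- abs(diff(ks)) / ks[-1]
  plateau <- rel < tol
  b_star <- NA_real_
  ## contiguous plateau must start at the smallest b; its outer edge is b*
  run <- cumprod(plateau)
  if (any(run == 1)) b_star <- bs[max(which(run == 1)) + 1L]
  list(b_star = b_star, scan = data.frame(b = bs, k_on = ks))
}
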