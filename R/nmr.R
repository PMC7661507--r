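#' Spin system for multi-state lineshape simulation
#'
#' Per-residue Larmor frequencies (stored as offsets from a carrier) and
#' transverse relaxation rates for the chemical states (P, PH, PPH, PHH), as
#' needed by the exchange-coupled lineshape propagator.
#'
#' @param omega0 named numeric: state frequencies (rad/s, offsets from the
#'   carrier), names among `c("P", "PH", "PPH", "PHH")`.
#' @param R2 named numeric: transverse relaxation rates (1/s), same names.
#' @param residue optional residue label.
#' @return object of class `spin_system`.
#' @export
spin_system <- function(omega0, R2, residue = NA_character_) {
  states <- c("P", "PH", "PPH", "PHH")
  stopifnot(all(names(omega0) %in% states), all(names(R2) %in% states),
            length(omega0) == length(R2))
  check_pos(min(R2), "R2")
  if (any(!is.finite(omega0))) stop("frequencies must be finite")
  structure(list(omega0 = omega0, R2 = R2, states = names(omega0),
                 residue = residue), class = "spin_system")
}

#' Free-induction decay of an exchanging spin system
#'
#' Integrates the exchange-coupled transverse-magnetization equations
#' \deqn{\frac{d\mathbf{M}}{dt} = (-i\,\Omega - \mathbf{R}_2 + \mathbf{K})\,
#'   \mathbf{M}}
#' (relaxation damping the signal) with initial magnetization distributed as
#' the equilibrium populations of the kinetic generator, and returns the
#' complex signal `s(t) = 1' M(t)`. The propagator is evaluated by
#' diagonalization of the complex non-symmetric evolution matrix, with a
#' scaling-and-squaring fallback if the matrix is numerically defective.
#'
#' @param spin a [spin_system] whose states match the generator's.
#' @param gen a [generator_matrix] built at the titration-point
#'   concentrations (any subset of the four states; state labels must match).
#' @param t_grid time grid (s); if `NULL`, chosen automatically as
#'   `5 / min(R2)` with 4-fold Nyquist oversampling of the largest offset.
#' @return data.frame `t`, `re`, `im` with attribute `p_eq`.
#' @export
bm_fid <- function(spin, gen, t_grid = NULL) {
  stopifnot(inherits(spin, "spin_system"), inherits(gen, "generator_matrix"))
  st <- gen$state_labels
  if (!all(st %in% spin$states))
    stop("spin system lacks states: ",
         paste(setdiff(st, spin$states), collapse = ", "))
  om <- spin$omega0[st]; r2 <- spin$R2[st]
  A <- -1i * diag(om, length(om)) - diag(r2, length(r2)) + gen$K
  if (is.null(t_grid)) {
    duration <- 5 / min(r2)
    om_max <- max(abs(om), max(r2), 1)
    dwell <- pi / (4 * om_max)
    t_grid <- seq(0, duration, by = dwell)
  }
  M0 <- gen$p_eq
  ed <- tryCatch(eigen(A), error = function(e) NULL)
  s_t <- NULL
  if (!is.null(ed) && is.finite(rcond(abs(ed$vectors)))) {
    Vi <- tryCatch(solve(ed$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      c0 <- Vi %*% M0
      s_t <- vapply(t_grid, function(t)
        sum(ed$vectors %*% (exp(ed$values * t) * c0)), complex(1))
    }
  }
  if (is.null(s_t)) {
    warning("defective evolution matrix: falling back to scaling-and-squaring")
    s_t <- vapply(t_grid, function(t) sum(cmat_exp(A * t) %*% M0), complex(1))
  }
  out <- data.frame(t = t_grid, re = Re(s_t), im = Im(s_t))
  attr(out, "p_eq") <- gen$p_eq
  out
}

## complex matrix exponential via scaling and squaring with Taylor core
cmat_exp <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(1 + 0i, n); term <- diag(1 + 0i, n)
  for (k in 1:20) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Frequency-domain spectrum of an FID
#'
#' One-sided Fourier integral \eqn{S(\omega) = \mathrm{Re}\int_0^\infty
#' s(t)e^{i\omega t}dt}, evaluated by trapezoidal quadrature on the FID's
#' time grid. The time step must resolve the largest frequency offset
#' requested (checked; aliasing raises an error suggesting a finer dwell).
#'
#' @param fid data.frame from [bm_fid] (`t`, `re`, `im`).
#' @param omega_grid frequencies (rad/s) at which to evaluate the spectrum.
#' @return data.frame `omega`, `intensity`.
#' @export
fid_to_spectrum <- function(fid, omega_grid) {
  dt <- diff(fid$t)
  if (any(dt <= 0)) stop("FID time grid must be increasing")
  dwell <- max(dt)
  om_max <- max(abs(omega_grid))
  if (om_max * dwell > pi)
    stop(sprintf(
      "aliasing: dwell %.3g s cannot resolve |omega| = %.3g rad/s; use dwell <= %.3g s",
      dwell, om_max, pi / om_max))
  s_t <- complex(real = fid$re, imaginary = fid$im)
  w <- c(dt[1] / 2, (dt[-1] + dt[-length(dt)]) / 2, dt[length(dt)] / 2)
  intensity <- vapply(omega_grid, function(om)
    Re(sum(w * s_t * exp(1i * om * fid$t))), numeric(1))
  data.frame(omega = omega_grid, intensity = intensity)
}

#' Closed-form spectrum via the resolvent
#'
#' Exact one-sided Fourier transform of the exchange FID,
#' \eqn{S(\omega) = -\mathrm{Re}\,[\mathbf{1}^T (A + i\omega I)^{-1}
#' \mathbf{M}_0]} with `A` the evolution matrix. Used as an independent
#' cross-check of the quadrature route.
#'
#' @inheritParams bm_fid
#' @param omega_grid frequencies (rad/s).
#' @return data.frame `omega`, `intensity`.
#' @export
bm_spectrum_resolvent <- function(spin, gen, omega_grid) {
  st <- gen$state_labels
  om <- spin$omega0[st]; r2 <- spin$R2[st]
  A <- -1i * diag(om, length(om)) - diag(r2, length(r2)) + gen$K
  M0 <- gen$p_eq
  intensity <- vapply(omega_grid, function(w) {
    x <- solve(A + 1i * w * diag(nrow(A)), M0)
    -Re(sum(x))
  }, numeric(1))
  data.frame(omega = omega_grid, intensity = intensity)
}

#' Lorentzian peak fits of 1D projections
#'
#' Fits each projection with one Lorentzian (position, full width at half
#' height, area) after constant-background removal and volume normalization.
#' Projections that are significantly better described by two Lorentzians
#' (slow-exchange regime) are flagged as bimodal.
#'
#' @param spectra list of data.frames (`omega`, `intensity`), one per
#'   titration point.
#' @param detect_bimodal test a two-Lorentzian alternative (default TRUE).
#' @param bimodal_f_ratio residual-variance improvement factor above which a
#'   projection is flagged bimodal (default 3) provided the two peaks are
#'   separated by more than their mean width.
#' @return data.frame of class `peak_table`: `omega0`, `fwhh`, `area`,
#'   `omega0_se`, `fwhh_se`, `bimodal`, one row per projection.
#' @export
fit_lorentzian_projections <- function(spectra, detect_bimodal = TRUE,
                                       bimodal_f_ratio = 3) {
  if (is.data.frame(spectra)) spectra <- list(spectra)
  rows <- lapply(spectra, function(sp) {
    om <- sp$omega; y <- sp$intensity
    bg <- stats::median(c(utils::head(y, 5), utils::tail(y, 5)))
    y <- y - bg
    area <- sum(y) * mean(diff(om))
    if (area > 0) y <- y / area
    dat <- data.frame(om = om, y = y)
    i0 <- om[which.max(y)]
    hm <- max(y) / 2
    w0 <- diff(range(om[y > hm]))
    if (!is.finite(w0) || w0 <= 0) w0 <- diff(range(om)) / 10
    lor <- function(om, a, x0, g) a * (g / 2)^2 / ((om - x0)^2 + (g / 2)^2)
    f1 <- minpack.lm::nlsLM(y ~ lor(om, a, x0, exp(lg)), data = dat,
                            start = list(a = max(y), x0 = i0, lg = log(w0)),
                            control = minpack.lm::nls.lm.control(maxiter = 300))
    cf <- stats::coef(f1); se <- summary(f1)$coefficients
    fwhh <- exp(cf[["lg"]])
    bimodal <- FALSE
    if (detect_bimodal) {
      rss1 <- sum(stats::resid(f1)^2)
      ## start the two-peak alternative at the two dominant local maxima
      ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
      ys[is.na(ys)] <- y[is.na(ys)]
      loc <- which(diff(sign(diff(ys))) < 0) + 1L
      loc <- loc[order(ys[loc], decreasing = TRUE)]
      sep_ok <- if (length(loc) >= 2)
        loc[abs(om[loc] - om[loc[1]]) > 2 * mean(diff(om)) | loc == loc[1]]
        else loc
      x12 <- if (length(sep_ok) >= 2) om[sep_ok[1:2]] else
        c(i0 - w0, i0 + w0)
      f2 <- tryCatch(minpack.lm::nlsLM(
        y ~ lor(om, a1, x1, exp(lg1)) + lor(om, a2, x2, exp(lg2)), data = dat,
        start = list(a1 = max(y), x1 = x12[1], lg1 = log(w0 / 2),
                     a2 = max(y) / 2, x2 = x12[2], lg2 = log(w0 / 2)),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(f2)) {
        rss2 <- sum(stats::resid(f2)^2)
        cf2 <- stats::coef(f2)
        sep <- abs(cf2[["x1"]] - cf2[["x2"]])
        mw <- (exp(cf2[["lg1"]]) + exp(cf2[["lg2"]])) / 2
        both_tall <- min(abs(cf2[["a1"]]), abs(cf2[["a2"]])) >
          0.1 * max(abs(cf2[["a1"]]), abs(cf2[["a2"]]))
        bimodal <- rss1 / max(rss2, .Machine$double.eps) > bimodal_f_ratio &&
          sep > mw && both_tall
      }
    }
    data.frame(omega0 = cf[["x0"]], fwhh = fwhh,
               area = area,
               omega0_se = se["x0", "Std. Error"],
               fwhh_se = fwhh * se["lg", "Std. Error"],
               bimodal = bimodal)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("peak_table", "data.frame"))
}

#' Estimate bound-state frequencies from a titration of peak positions
#'
#' In fast exchange, the measured peak position at each titration point is
#' the population-weighted mean of the state frequencies. With the free-state
#' frequency fixed to the measurement without titrant, the remaining state
#' frequencies minimize
#' \deqn{\chi^2 = \sum_{titration}\left[\omega_0^{meas} -
#'   \mathbf{1}^T\Omega\,\mathbf{p}_{eq}\right]^2,}
#' a linear least-squares problem in the unknown frequencies.
#'
#' @param omega0_meas measured peak positions (rad/s), one per titration
#'   point.
#' @param p_eq_list list of equilibrium population vectors (named with state
#'   labels), one per titration point.
#' @param omega0_P fixed free-state frequency (rad/s).
#' @return list with `omega0` (named vector incl. the fixed P), `se`,
#'   `identifiable` (FALSE with a flag when the design is rank-deficient).
#' @export
estimate_state_shifts <- function(omega0_meas, p_eq_list, omega0_P) {
  states <- setdiff(names(p_eq_list[[1]]), "P")
  X <- do.call(rbind, lapply(p_eq_list, function(p) p[states]))
  y <- omega0_meas - vapply(p_eq_list, function(p) p[["P"]], numeric(1)) *
    omega0_P
  qrX <- qr(X)
  if (qrX$rank < length(states)) {
    return(list(omega0 = c(P = omega0_P,
                           stats::setNames(rep(NA_real_, length(states)),
                                           states)),
                se = NULL, identifiable = FALSE))
  }
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  dof <- max(length(y) - length(states), 1L)
  s2 <- sum(fit$residuals^2) / dof
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(XtXi) * s2, 0))
  list(omega0 = c(P = omega0_P, cf),
       se = stats::setNames(se, states), identifiable = TRUE,
       chisq = sum(fit$residuals^2))
}

#' Transverse relaxation rates from measured line widths
#'
#' `R2 = fwhh / 2` (rad/s in, 1/s out). The free-state rate comes from the
#' width without titrant; all bound-state rates are assigned the width at the
#' saturating titrant concentration (line widths change little beyond it for
#' highly dynamic disordered complexes).
#'
#' @param fwhh_free full width at half height without titrant (rad/s).
#' @param fwhh_sat full width at the saturating point (rad/s).
#' @return named numeric `R2` for states P, PH, PPH, PHH (1/s).
#' @export
r2_from_fwhh <- function(fwhh_free, fwhh_sat = fwhh_free) {
  check_pos(fwhh_free, "fwhh_free")
  check_pos(fwhh_sat, "fwhh_sat")
  c(P = fwhh_free / 2, PH = fwhh_sat / 2, PPH = fwhh_sat / 2,
    PHH = fwhh_sat / 2)
}

#' Simulated lineshape titration
#'
#' For each titrant concentration: solve the coupled equilibria, build the
#' kinetic generator for the labeled species, simulate the FID and transform
#' to a spectrum. `model = "2state"` uses the two-state generator (dimer
#' only) with the free-titrant concentration from the two-state equilibrium;
#' `model = "4state"` uses the full generator including both ternary
#' complexes.
#'
#' @param rates a [rate_set].
#' @param spin a [spin_system] covering the states of the chosen model.
#' @param c_P_tot labeled-species total concentration (molar).
#' @param c_H_tot_grid titrant concentrations (molar).
#' @param model `"4state"` or `"2state"`.
#' @param omega_grid frequency grid (rad/s); default spans the state
#'   frequencies with a margin of 10 mean widths.
#' @return list with `spectra` (list of data.frames), `populations` (matrix),
#'   `conc` (list of `concentration_state`), `omega_grid`.
#' @export
titration_lineshapes <- function(rates, spin, c_P_tot, c_H_tot_grid,
                                 model = c("4state", "2state"),
                                 omega_grid = NULL) {
  model <- match.arg(model)
  if (is.null(omega_grid)) {
    rng <- range(spin$omega0)
    pad <- 10 * mean(spin$R2)
    omega_grid <- seq(rng[1] - pad, rng[2] + pad, length.out = 400)
  }
  spectra <- list(); pops <- list(); concs <- list()
  for (i in seq_along(c_H_tot_grid)) {
    ch <- c_H_tot_grid[i]
    if (model == "4state") {
      conc <- solve_species_concentrations(c_P_tot, ch, rates,
                                           include_PHH = TRUE)
      gen <- build_K4P(rates, conc)
    } else {
      ## the two-state reference uses the dimer-only equilibrium
      c_H_free <- free_ligand_competition(c_P_tot, ch, rates$K_D)
      conc <- solve_species_concentrations(c_P_tot, ch, rates,
                                           include_PHH = FALSE)
      gen2 <- build_K2(rates, c_H_free)
      ## relabel to the spin-system state names
      gen <- generator_matrix(gen2$K, c("P", "PH"))
    }
    fid <- bm_fid(spin, gen)
    spectra[[i]] <- fid_to_spectrum(fid, omega_grid)
    pops[[i]] <- gen$p_eq
    concs[[i]] <- conc
  }
  list(spectra = spectra, populations = do.call(rbind, pops), conc = concs,
       omega_grid = omega_grid, model = model,
       c_H_tot_grid = c_H_tot_grid)
}

#' Sensitivity scan of the lineshape simulation
#'
#' Recomputes a reference titration spectrum while scanning one or more
#' parameters over ranges and reports an L2 spectral-difference metric for
#' each grid point, to expose which parameters the lineshapes actually
#' constrain.
#'
#' @param base_args list of arguments for [titration_lineshapes] (the
#'   reference).
#' @param scan named list: for each parameter, a numeric vector of
#'   multiplicative factors applied to the reference value. Supported names:
#'   `k_off_PPH`, `k_on_PPH`, `R2`, `shifts` (scales all bound-state
#'   offsets).
#' @return data.frame `parameter`, `factor`, `l2` (root-mean-square spectral
#'   difference summed over the titration).
#' @export
sensitivity_scan <- function(base_args, scan) {
  ref <- do.call(titration_lineshapes, base_args)
  metric <- function(a, b) {
    sqrt(mean(unlist(Map(function(x, y) (x$intensity - y$intensity)^2,
                         a$spectra, b$spectra))))
  }
  rows <- list(); k <- 1L
  for (pn in names(scan)) {
    for (f in scan[[pn]]) {
      args <- base_args
      if (pn %in% c("k_off_PPH", "k_on_PPH")) {
        r <- args$rates
        v <- as.list(r[c("k_on", "k_off", "k_on_PPH", "k_off_PPH",
                         "k_on_PHH", "k_off_PHH")])
        v[[pn]] <- v[[pn]] * f
        args$rates <- do.call(rate_set, v)
      } else if (pn == "R2") {
        sp <- args$spin
        args$spin <- spin_system(sp$omega0, sp$R2 * f, sp$residue)
      } else if (pn == "shifts") {
        sp <- args$spin
        om <- sp$omega0
        om[names(om) != "P"] <- om[names(om) != "P"] * f
        args$spin <- spin_system(om, sp$R2, sp$residue)
      } else stop("unknown scan parameter: ", pn)
      pert <- do.call(titration_lineshapes, args)
      rows[[k]] <- data.frame(parameter = pn, factor = f,
                              l2 = metric(ref, pert))
      k <- k + 1L
    }
  }
  do.call(rbind, rows)
}
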