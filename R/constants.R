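#' Physical constants used throughout the package
#'
#' Internal unit system: molar and seconds for solution work; nm, kJ/mol and
#' seconds for potential-of-mean-force work. All conversions go through the
#' constants below so that no module hard-codes its own factors.
#'
#' @format A list with elements:
#' \describe{
#'   \item{N_A}{Avogadro constant, 1/mol.}
#'   \item{kB_kJ}{Boltzmann constant in kJ/mol/K (i.e. the gas constant R).}
#'   \item{gamma_15N}{Gyromagnetic ratio of 15N as used for gradient-echo
#'     diffusion fits, rad/gauss/s.}
#'   \item{nm3_per_L}{Litres per cubic nanometre.}
#'   \item{cm2_to_nm2}{Square nanometres per square centimetre.}
#' }
#' @export
polyion_constants <- list(
  N_A        = 6.02214076e23,
  kB_kJ      = 0.008314462618,
  gamma_15N  = 26752,
  nm3_per_L  = 1e-24,
  cm2_to_nm2 = 1e14
)

#' Convert a concentration with unit suffix to molar
#'
#' Helper for configuration tables where concentrations are written as
#' `"10 nM"` or `"1.5 uM"`. Plain numerics are assumed to be molar already.
#'
#' @param x numeric (molar) or character like "10 nM", "2 uM", "50 pM", "1 mM".
#' @return numeric, molar.
#' @export
as_molar <- function(x) {
  if (is.numeric(x)) return(x)
  stopifnot(is.character(x))
  vapply(x, function(s) {
    m <- regmatches(s, regexec("^\\s*([0-9.eE+-]+)\\s*(pM|nM|uM|µM|mM|M)\\s*$", s))[[1]]
    if (length(m) != 3L) stop("cannot parse concentration: ", s)
    val <- as.numeric(m[2])
    val * switch(m[3], pM = 1e-12, nM = 1e-9, uM = 1e-6, "µM" = 1e-6,
                 mM = 1e-3, M = 1)
  }, numeric(1), USE.NAMES = FALSE)
}

## internal: positive, finite scalar check
check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(name, " must be a single positive finite number", call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(name, " must be non-negative and finite", call. = FALSE)
  invisible(x)
}
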