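#' Rate coefficients of the dimer/ternary-complex reaction scheme
#'
#' Bundles the six rate coefficients of the reaction scheme
#' \deqn{P + H \rightleftharpoons PH,\quad
#'       P + PH \rightleftharpoons PPH,\quad
#'       PH + H \rightleftharpoons PHH}
#' together with the derived dissociation constants
#' \eqn{K_D = k_{off}/k_{on}}, \eqn{K_D^{PPH} = k^{PPH}_{off}/k^{PPH}_{on}},
#' \eqn{K_D^{PHH} = k^{PHH}_{off}/k^{PHH}_{on}}.
#'
#' @param k_on dimer association rate coefficient, 1/M/s.
#' @param k_off dimer dissociation rate, 1/s.
#' @param k_on_PPH,k_off_PPH ternary PPH formation/dissociation (1/M/s, 1/s).
#' @param k_on_PHH,k_off_PHH ternary PHH formation/dissociation (1/M/s, 1/s).
#' @return An object of class `rate_set`: a list with the six rates and the
#'   three derived dissociation constants `K_D`, `K_D_PPH`, `K_D_PHH` (molar).
#' @examples
#' rs <- rate_set(1.45e9, 1.7, 0.53e9, 1.9e3, 0.53e9, 0.53e9 * 12e-6)
#' rs$K_D * 1e9   # nM
#' @export
rate_set <- function(k_on, k_off, k_on_PPH, k_off_PPH, k_on_PHH, k_off_PHH) {
  args <- list(k_on = k_on, k_off = k_off,
               k_on_PPH = k_on_PPH, k_off_PPH = k_off_PPH,
               k_on_PHH = k_on_PHH, k_off_PHH = k_off_PHH)
  for (nm in names(args)) check_pos(args[[nm]], nm)
  out <- c(args, list(
    K_D     = k_off / k_on,
    K_D_PPH = k_off_PPH / k_on_PPH,
    K_D_PHH = k_off_PHH / k_on_PHH))
  structure(out, class = "rate_set")
}

#' Default rate coefficients for the ProTa-H1 system
#'
#' Rate coefficients for the prothymosin-alpha/H1 polyelectrolyte complex at
#' 200 mM ionic strength: diffusion-limited dimer association
#' (`k_on` = 1.45e9 /M/s), slow dimer dissociation (`k_off` = 1.7 /s), fast
#' ternary-complex turnover (`k_on_PPH` = 0.53e9 /M/s,
#' `k_off_PPH` = 1.9e3 /s), and a PHH affinity of 12 uM. The two trimer
#' association rate coefficients are taken as equal, consistent with the
#' similarity of the corresponding potentials of mean force.
#'
#' @return A [rate_set].
#' @export
prota_h1_rates <- function() {
  k_on_tri <- 0.53e9
  rate_set(k_on = 1.45e9, k_off = 1.7,
           k_on_PPH = k_on_tri, k_off_PPH = 1.9e3,
           k_on_PHH = k_on_tri, k_off_PHH = k_on_tri * 12e-6)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Rate set (dimer + ternary complexes)\n")
  cat(sprintf("  k_on     = %.3g /M/s   k_off     = %.3g /s   K_D     = %.3g M\n",
              x$k_on, x$k_off, x$K_D))
  cat(sprintf("  k_on_PPH = %.3g /M/s   k_off_PPH = %.3g /s   K_D_PPH = %.3g M\n",
              x$k_on_PPH, x$k_off_PPH, x$K_D_PPH))
  cat(sprintf("  k_on_PHH = %.3g /M/s   k_off_PHH = %.3g /s   K_D_PHH = %.3g M\n",
              x$k_on_PHH, x$k_off_PHH, x$K_D_PHH))
  invisible(x)
}
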