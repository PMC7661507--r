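#' Read a titration table from delimited text
#'
#' Expected columns: one concentration column (`c_H_tot` or `c_P_tot`,
#' molar), `theta`, and optionally `sd`. Tab- or comma-separated with a
#' header.
#'
#' @param path file path.
#' @return data.frame with the columns found, checked for ranges.
#' @export
read_titration_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "",
                         stringsAsFactors = FALSE)
  if (ncol(d) == 1L) d <- utils::read.csv(path, stringsAsFactors = FALSE)
  conc_col <- intersect(c("c_H_tot", "c_P_tot"), names(d))
  if (length(conc_col) == 0L || !"theta" %in% names(d))
    stop("titration table needs a concentration column (c_H_tot or c_P_tot) ",
         "and theta")
  check_nonneg(d[[conc_col[1]]], conc_col[1])
  if (any(d$theta < -0.1 | d$theta > 1.1))
    stop("theta outside [0, 1] beyond noise allowance")
  d
}

#' Read a kinetic observed-rate table from delimited text
#'
#' Expected columns: `c_P_tot`, `c_H_tot` (molar), `observable` (one of
#' k_on_obs, k_off_obs, k_ex), `value` (1/s), optionally `sd` and `method`.
#' The result feeds [global_fit_ternary] directly.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_kinetic_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "",
                         stringsAsFactors = FALSE)
  if (ncol(d) == 1L) d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("c_P_tot", "c_H_tot", "observable", "value")
  if (!all(need %in% names(d)))
    stop("kinetic table needs columns: ", paste(need, collapse = ", "))
  if (!all(d$observable %in% c("k_on_obs", "k_off_obs", "k_ex")))
    stop("unknown observable name(s)")
  d
}

#' Write a fit result as JSON
#'
#' Serializes the numeric elements of a fit result (e.g. from
#' [fit_isotherm], [global_fit_ternary], [fit_two_state]) to a JSON record.
#'
#' @param fit a list-like fit result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  keep <- vapply(fit, function(v)
    is.numeric(v) && length(v) <= 32, logical(1))
  jsonlite::write_json(lapply(fit[keep], unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
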