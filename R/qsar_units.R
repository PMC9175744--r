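#' Potency-unit arithmetic: pIC50 and IC50
#'
#' pIC50 is the negative base-10 logarithm of the *molar* IC50, so
#' `IC50[uM] = 10^(-pIC50) * 1e6`. Higher pIC50 means more potent. The
#' conversions are exact inverses of each other; use [round_half_up()]
#' with 3 decimals to reproduce the conventional table precision.
#'
#' @param pic50 numeric vector of pIC50 values (molar scale).
#' @param digits optional: round the result half-up to this many decimals
#'   (table convention is 3); `NULL` returns full precision.
#' @return IC50 in micromolar.
#' @export
#' @examples
#' ic50_um_from_pic50(6)                 # 1 uM
#' ic50_um_from_pic50(3.787, digits = 3) # 163.305 uM
ic50_um_from_pic50 <- function(pic50, digits = NULL) {
  if (any(!is.finite(pic50))) {
    rlang::abort("pic50 must be finite", class = "signetpharm_value_error")
  }
  out <- 10^(-pic50) * 1e6
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' @rdname ic50_um_from_pic50
#' @param ic50_m IC50 in mol/L (must be positive).
#' @export
pic50_from_ic50_m <- function(ic50_m) {
  if (any(!is.finite(ic50_m)) || any(ic50_m <= 0)) {
    rlang::abort("IC50 must be positive and finite",
                 class = "signetpharm_value_error")
  }
  -log10(ic50_m)
}

#' @rdname ic50_um_from_pic50
#' @param ic50_um IC50 in micromolar (must be positive).
#' @export
pic50_from_ic50_um <- function(ic50_um) {
  pic50_from_ic50_m(ic50_um * 1e-6)
}

#' Consistency of a printed pIC50 / IC50 pair
#'
#' Published potency tables print both columns rounded, sometimes from the
#' unrounded value of the *other* column, so a pair is accepted when the
#' conversion matches in either direction: pIC50 -> uM within `tol_um`, or
#' uM -> pIC50 within `tol_pic50`.
#'
#' @param pic50,ic50_um the printed pair (vectorised).
#' @param tol_um tolerance on the micromolar side (default 0.002).
#' @param tol_pic50 tolerance on the pIC50 side (default 0.001).
#' @return logical vector.
#' @export
potency_pair_consistent <- function(pic50, ic50_um, tol_um = 0.002,
                                    tol_pic50 = 0.001) {
  fwd <- abs(round_half_up(ic50_um_from_pic50(pic50), 3) - ic50_um)
  bwd <- abs(round_half_up(pic50_from_ic50_um(ic50_um), 3) - pic50)
  fwd <= tol_um + 1e-12 | bwd <= tol_pic50 + 1e-12
}

#' Bundled reference tables
#'
#' `safi_components()` returns the five principal water-soluble components
#' of Salvianolic Acid For Injection (SAFI) with their PubChem identifiers
#' and canonical SMILES; note that salvianolic acids B and Y are
#' stereoisomers whose canonical SMILES, lacking stereo annotations,
#' coincide. `qsar_reference_potencies()` returns QSAR-predicted and
#' experimentally measured cyclooxygenase (PTGS1/PTGS2) potencies for
#' reference inhibitors and the SAFI components, as printed pIC50 /
#' micromolar IC50 pairs.
#'
#' @return a tibble.
#' @export
safi_components <- function() {
  path <- system.file("extdata", "safi_components.csv",
                      package = "signetpharm", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname safi_components
#' @export
qsar_reference_potencies <- function() {
  path <- system.file("extdata", "cox_potency_pairs.csv",
                      package = "signetpharm", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
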