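# Matthews coefficient and crystal solvent content.

#' Matthews coefficient and solvent content of a crystal form
#'
#' V_M = V / (z * n * MW), the crystal volume per Dalton of macromolecule;
#' solvent fraction S = 1 - 1.66054 * vbar / V_M, clamped to [0, 1].
#'
#' @param cell_volume Unit-cell volume V in cubic Angstrom.
#' @param z Space-group multiplicity.
#' @param n_copies Copies of the complex per asymmetric unit.
#' @param mw Molecular weight per complex in Dalton.
#' @param vbar Partial specific volume in cm^3/g (default 0.74, the protein
#'   consensus value).
#' @return A tibble with columns `vm` (A^3/Da) and `solvent_fraction`.
#' @export
matthews <- function(cell_volume, z, n_copies, mw, vbar = 0.74) {
  if (any(c(cell_volume, z, n_copies, mw, vbar) <= 0)) {
    abort("all crystal-form inputs must be positive")
  }
  vm <- cell_volume / (z * n_copies * mw)
  tibble(vm = vm, solvent_fraction = solvent_content(vm, vbar))
}

#' Solvent content from a Matthews coefficient
#'
#' @param vm Matthews coefficient in A^3/Da.
#' @param vbar Partial specific volume in cm^3/g (default 0.74).
#' @return Solvent fraction in [0, 1].
#' @export
solvent_content <- function(vm, vbar = 0.74) {
  if (any(vm <= 0) || any(vbar <= 0)) abort("vm and vbar must be positive")
  pmin(1, pmax(0, 1 - 1.66054 * vbar / vm))
}
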