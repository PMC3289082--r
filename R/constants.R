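#' Monoisotopic mass constants for fragment-ion arithmetic
#'
#' Bundles the masses that all fragment-relation predicates depend on: the
#' proton, the small neutrals whose loss is considered when matching peaks
#' (water, ammonia, CO, NH), the 20 monoisotopic amino-acid residue masses,
#' and the set of basic residues (K, R, H) whose side chains retain protons
#' in electrospray ionisation.
#'
#' All masses are in Dalton. Any entry can be overridden, e.g. to swap in an
#' average-mass residue table for instruments calibrated that way.
#'
#' @param proton Proton mass (Da).
#' @param h2o,nh3,co,nh Neutral-loss masses (Da).
#' @param residue_masses Named numeric vector of 20 monoisotopic residue
#'   masses (Da), names being one-letter amino-acid codes.
#' @param basic_residues Character vector of basic one-letter codes.
#'
#' @return An object of class `mass_constants` (a validated list).
#' @examples
#' mc <- mass_constants()
#' mc$residue_masses[["K"]]
#' @export
mass_constants <- function(proton = 1.00728,
                           h2o = 18.01056,
                           nh3 = 17.02655,
                           co = 27.99491,
                           nh = 15.01090,
                           residue_masses = NULL,
                           basic_residues = c("K", "R", "H")) {
  if (is.null(residue_masses)) {
    residue_masses <- c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
      T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
      N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
      E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
      R = 156.10111, Y = 163.06333, W = 186.07931
    )
  }
  stopifnot(
    length(residue_masses) == 20L,
    !is.null(names(residue_masses)),
    all(residue_masses > 0),
    proton > 0, h2o > 0, nh3 > 0, co > 0, nh > 0,
    all(basic_residues %in% names(residue_masses))
  )
  structure(
    list(
      proton = proton, h2o = h2o, nh3 = nh3, co = co, nh = nh,
      residue_masses = residue_masses,
      basic_residues = basic_residues
    ),
    class = "mass_constants"
  )
}

# neutral losses in the order they are tried (no-loss first is handled by callers)
.loss_vector <- function(constants) {
  c(h2o = constants$h2o, nh3 = constants$nh3, co = constants$co, nh = constants$nh)
}
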