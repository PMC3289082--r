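#' Theoretical m/z of a b or y fragment ion
#'
#' Peptide-bond cleavage in CID yields an N-terminal b ion and a C-terminal
#' y ion. The singly charged b ion carries the prefix residues plus one
#' proton; the singly charged y ion carries the suffix residues plus water
#' (the C-terminal OH and an extra hydrogen restored on fragmentation) plus
#' one proton. A doubly charged ion adds a second proton and halves the m/z:
#' `mz2 = (mz1 + proton) / 2`.
#'
#' @param residues Character vector of one-letter residue codes for the
#'   prefix (b) or suffix (y) of the peptide; must be non-empty.
#' @param terminal `"N"` for a b ion, `"C"` for a y ion.
#' @param charge Fragment charge, 1 or 2.
#' @param constants A [mass_constants()] object.
#' @return The theoretical m/z in Thomson.
#' @examples
#' by_ion_mz("K", "C", 1)  # y1 of a tryptic peptide ending in K
#' @export
by_ion_mz <- function(residues, terminal = c("N", "C"), charge = 1,
                      constants = mass_constants()) {
  terminal <- match.arg(terminal)
  stopifnot(length(residues) >= 1, charge %in% c(1, 2))
  residues <- toupper(residues)
  unknown <- setdiff(residues, names(constants$residue_masses))
  if (length(unknown) > 0) stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
  m1 <- sum(constants$residue_masses[residues]) + constants$proton
  if (terminal == "C") m1 <- m1 + constants$h2o
  if (charge == 2) (m1 + constants$proton) / 2 else m1
}

# Charge-weighted target sums. A (+1,+1) b/y pair from the same bond sums to
# the peptide mass M plus two protons; a (+1,+2) pair, weighting the +2
# member's m/z by 2, sums to M plus three protons. Substituting
# mp = (M + z*proton)/z gives the precursor-charge-hypothesis targets below.
.cp11_target <- function(mp, z, constants) {
  if (z == 2) 2 * mp else 3 * mp - constants$proton
}
.cp12_target <- function(mp, z, constants) {
  if (z == 2) 2 * mp + constants$proton else 3 * mp
}

#' Test a (+1, +1) complementary-pair relation
#'
#' True when two peaks are mass-consistent with a singly charged b ion and a
#' singly charged y ion cleaved at the same peptide bond, under the stated
#' precursor charge hypothesis: their m/z values must sum to `2*mp` (for a
#' +2 precursor) or `3*mp - proton` (for +3), within the tolerance.
#'
#' @param m1,m2 Peak m/z values (Th) with `m1 < m2`.
#' @param mp Precursor m/z (Th).
#' @param z Precursor charge hypothesis, 2 or 3.
#' @param constants A [mass_constants()] object.
#' @param tolerance Symmetric absolute mass window (Da); must be positive.
#' @return Logical.
#' @examples
#' is_cp11(200, 800, mp = 500, z = 2)  # 200 + 800 == 2 * 500
#' @export
is_cp11 <- function(m1, m2, mp, z, constants = mass_constants(), tolerance = 0.5) {
  stopifnot(m1 < m2, z %in% c(2, 3), tolerance > 0)
  abs(m1 + m2 - .cp11_target(mp, z, constants)) <= tolerance
}

#' Test a (+1, +2) complementary-pair relation
#'
#' True when two peaks are mass-consistent with a complementary b/y pair in
#' which the designated member is doubly charged: the charge-weighted sum
#' (`m1 + 2*m2` when the higher-m/z member is the +2 ion, `2*m1 + m2` when
#' the lower one is) must equal `2*mp + proton` (+2 precursor hypothesis) or
#' `3*mp` (+3), within the tolerance.
#'
#' @inheritParams is_cp11
#' @param which_is_2 `"high"` if the higher-m/z member is the putative +2
#'   ion, `"low"` if the lower one is.
#' @return Logical.
#' @examples
#' is_cp12(300, 450, mp = 400, z = 3, which_is_2 = "high")  # 300 + 900 == 3*400
#' @export
is_cp12 <- function(m1, m2, mp, z, which_is_2 = c("high", "low"),
                    constants = mass_constants(), tolerance = 0.5) {
  which_is_2 <- match.arg(which_is_2)
  stopifnot(m1 < m2, z %in% c(2, 3), tolerance > 0)
  lhs <- if (which_is_2 == "high") m1 + 2 * m2 else 2 * m1 + m2
  abs(lhs - .cp12_target(mp, z, constants)) <= tolerance
}

# Logical vector: for each peak, does any of the doubly-charged evidence
# relations hold? (d1) a +1 counterpart exists at 2*mz - proton;
# (d2)/(d3) the peak is the +2 member of a (+1,+2) pair under the +3
# precursor hypothesis. No neutral-loss variants here.
.doubly_charged_flags <- function(sp, constants, tolerance) {
  n <- length(sp$mz)
  if (n == 0) return(logical(0))
  mz <- sp$mz
  flags <- logical(n)
  tgt12 <- .cp12_target(sp$precursor_mz, 3, constants)
  for (k in seq_len(n)) {
    others <- mz[-k]
    if (length(others) == 0) next
    # d1: +1 counterpart of this putative +2 ion
    if (any(abs(others - (2 * mz[k] - constants$proton)) <= tolerance)) {
      flags[k] <- TRUE
      next
    }
    # d2/d3: this peak weighted by 2 plus a +1 partner reaches the +3 target
    if (any(abs(2 * mz[k] + others - tgt12) <= tolerance)) flags[k] <- TRUE
  }
  flags
}

#' Is a peak doubly charged?
#'
#' A peak is flagged as a putative +2 fragment ion when any of three
#' relations holds: a companion peak sits at its +1 counterpart position
#' `2*mz - proton`, or the peak participates as the +2 member of a (+1, +2)
#' complementary pair under the +3 precursor hypothesis (with either partner
#' orientation).
#'
#' @param k Peak index (1-based) into the spectrum's sorted peak list.
#' @param spectrum An [spectrum()] object.
#' @inheritParams is_cp11
#' @return Logical.
#' @export
is_doubly_charged_peak <- function(k, spectrum, constants = mass_constants(),
                                   tolerance = 0.5) {
  stopifnot(k >= 1, k <= length(spectrum$mz))
  .doubly_charged_flags(spectrum, constants, tolerance)[k]
}

#' Enumerate complementary-pair relations in a spectrum
#'
#' Tests every peak pair (i < j in m/z order) against the three
#' complementary-pair relation kinds -- `CP11` (+1,+1), `CP12_LOW2` (lower
#' member +2) and `CP12_HIGH2` (higher member +2) -- under both the +2 and
#' +3 precursor charge hypotheses. When `losses_enabled`, each failed test
#' is retried assuming one member lost a single neutral (water, ammonia, CO
#' or NH): a neutral loss of mass L on either member lowers the
#' charge-weighted pair sum by exactly L, so the variants add each loss mass
#' back before the window test, trying no-loss first. Each
#' (i, j, kind, hypothesis) combination is reported at most once, tagged
#' with the first matching loss.
#'
#' @param spectrum An [spectrum()] object.
#' @inheritParams is_cp11
#' @param losses_enabled Consider single neutral-loss variants (default TRUE).
#' @return A data frame with columns `i`, `j` (peak indices, `i < j`),
#'   `kind`, `z`, `loss` (`"none"` or the neutral lost). Zero rows when the
#'   spectrum has fewer than two peaks.
#' @export
enumerate_pair_relations <- function(spectrum, constants = mass_constants(),
                                     tolerance = 0.5, losses_enabled = TRUE) {
  n <- length(spectrum$mz)
  empty <- data.frame(i = integer(0), j = integer(0), kind = character(0),
                      z = integer(0), loss = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  mz <- spectrum$mz
  mp <- spectrum$precursor_mz
  ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  m1 <- mz[ii]
  m2 <- mz[jj]
  losses <- if (losses_enabled) c(none = 0, .loss_vector(constants)) else c(none = 0)
  kinds <- list(
    CP11       = list(lhs = m1 + m2,     tgt = function(z) .cp11_target(mp, z, constants)),
    CP12_LOW2  = list(lhs = 2 * m1 + m2, tgt = function(z) .cp12_target(mp, z, constants)),
    CP12_HIGH2 = list(lhs = m1 + 2 * m2, tgt = function(z) .cp12_target(mp, z, constants))
  )
  out <- vector("list", length(kinds) * 2L)
  slot <- 0L
  for (kind in names(kinds)) {
    lhs <- kinds[[kind]]$lhs
    for (z in c(2L, 3L)) {
      tgt <- kinds[[kind]]$tgt(z)
      hit_loss <- rep(NA_character_, length(lhs))
      for (ln in names(losses)) {  # no-loss first; first match wins
        cand <- is.na(hit_loss) & abs(lhs + losses[[ln]] - tgt) <= tolerance
        hit_loss[cand] <- ln
      }
      hits <- which(!is.na(hit_loss))
      slot <- slot + 1L
      if (length(hits) > 0) {
        out[[slot]] <- data.frame(
          i = ii[hits], j = jj[hits], kind = kind, z = z,
          loss = hit_loss[hits], stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$i, res$j, res$kind, res$z), , drop = FALSE]
}
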