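#' Complementary-pair count difference
#'
#' The number of distinct peak pairs consistent with a (+1, +1)
#' complementary b/y pair (under either precursor charge hypothesis) minus
#' the number of distinct pairs consistent with a (+1, +2) pair (either
#' hypothesis, either orientation). A +2 precursor tends to yield two +1
#' fragments at each bond while a +3 precursor tends to yield a +1/+2 pair,
#' so this feature is expected to be larger for +2 than for +3 spectra. A
#' pair belongs to each set at most once however many relation variants it
#' satisfies.
#'
#' @param spectrum An [spectrum()] object.
#' @param constants A [mass_constants()] object.
#' @param tolerance Mass-match window (Da).
#' @param losses_enabled Consider single neutral-loss variants.
#' @return Integer-valued count difference; 0 for spectra with < 2 peaks.
#' @export
delta_cp <- function(spectrum, constants = mass_constants(), tolerance = 0.5,
                     losses_enabled = TRUE) {
  rel <- enumerate_pair_relations(spectrum, constants, tolerance, losses_enabled)
  .delta_cp_from_relations(rel)
}

.pair_key <- function(rel) paste(rel$i, rel$j)

.delta_cp_from_relations <- function(rel) {
  cp1 <- unique(.pair_key(rel[rel$kind == "CP11", , drop = FALSE]))
  cp2 <- unique(.pair_key(rel[rel$kind != "CP11", , drop = FALSE]))
  length(cp1) - length(cp2)
}

#' Complementary-pair intensity-ratio difference
#'
#' Contrasts how intensity is shared within the two kinds of complementary
#' pairs. For the (+1, +1) set, the summed intensity of the lower-m/z
#' members (the b side, which in CID is typically weaker than the y side)
#' is divided by the summed intensity of the higher-m/z members, and 0.5 is
#' added to compensate for that b/y asymmetry. For the (+1, +2) set, the
#' summed intensity of the +2-designated members is divided by the summed
#' intensity of their +1 partners. The feature is the first term minus the
#' second; it is expected to be positive for +2 precursors and negative for
#' +3. An empty pair set contributes 0 to its term (so a spectrum with no
#' complementary pairs scores exactly 0); a present set whose denominator
#' sum is 0 contributes a 0 ratio.
#'
#' @inheritParams delta_cp
#' @return A dimensionless value.
#' @export
delta_rcp <- function(spectrum, constants = mass_constants(), tolerance = 0.5,
                      losses_enabled = TRUE) {
  rel <- enumerate_pair_relations(spectrum, constants, tolerance, losses_enabled)
  .delta_rcp_from_relations(rel, spectrum$intensity)
}

.safe_ratio <- function(num, den) if (den > 0) num / den else 0

.delta_rcp_from_relations <- function(rel, intensity) {
  r1 <- rel[rel$kind == "CP11", , drop = FALSE]
  r1 <- r1[!duplicated(.pair_key(r1)), , drop = FALSE]
  term1 <- if (nrow(r1) > 0) {
    .safe_ratio(sum(intensity[r1$i]), sum(intensity[r1$j])) + 0.5
  } else 0
  r2 <- rel[rel$kind != "CP11", , drop = FALSE]
  r2 <- r2[!duplicated(paste(r2$i, r2$j, r2$kind)), , drop = FALSE]
  term2 <- if (nrow(r2) > 0) {
    two <- ifelse(r2$kind == "CP12_LOW2", r2$i, r2$j)
    one <- ifelse(r2$kind == "CP12_LOW2", r2$j, r2$i)
    .safe_ratio(sum(intensity[two]), sum(intensity[one]))
  } else 0
  term1 - term2
}

#' Doubly charged intensity above the precursor m/z
#'
#' Sums the intensity of peaks flagged as doubly charged (see
#' [is_doubly_charged_peak()]) whose m/z lies in the closed region
#' `[mp, 1.5*mp]`. A +2 fragment from a +2 precursor cannot exceed the
#' precursor m/z, while one from a +3 precursor can reach `1.5*mp`, so this
#' regional intensity is expected to be larger for +3 spectra.
#'
#' @inheritParams delta_cp
#' @return Summed intensity (abundance units, non-negative).
#' @export
i_dc <- function(spectrum, constants = mass_constants(), tolerance = 0.5) {
  flags <- .doubly_charged_flags(spectrum, constants, tolerance)
  mp <- spectrum$precursor_mz
  in_region <- spectrum$mz >= mp & spectrum$mz <= 1.5 * mp
  sum(spectrum$intensity[flags & in_region])
}

#' Basic-site pseudo-count
#'
#' Counts unordered peak pairs whose m/z difference matches the residue mass
#' of a basic amino acid (K, R or H) within the tolerance -- directly, or
#' after adding a single neutral loss (water, ammonia, CO, NH) to either
#' member, which shifts the difference by plus or minus the loss mass. Each
#' peak pair is counted at most once, ignoring duplicate evidence for the
#' same pair. The count is divided by `nt`, the theoretical repeat number of
#' basic-residue evidence per site; the default `nt = 1` reports the raw
#' pseudo-count. More basic sites mean more protons retained in ESI, so the
#' feature is expected to be larger for +3 precursors.
#'
#' @inheritParams delta_cp
#' @param nt Theoretical repeat number; must be >= 1.
#' @return Pseudo-count divided by `nt`.
#' @export
n_bs <- function(spectrum, constants = mass_constants(), tolerance = 0.5, nt = 1) {
  if (nt < 1) stop("nt must be >= 1")
  n <- length(spectrum$mz)
  if (n < 2) return(0)
  mz <- spectrum$mz
  ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  d <- mz[jj] - mz[ii]  # > 0 since sorted ascending
  shifts <- c(0, .loss_vector(constants), -.loss_vector(constants))
  basics <- constants$residue_masses[constants$basic_residues]
  hit <- rep(FALSE, length(d))
  for (r in basics) {
    for (s in shifts) hit <- hit | abs(d + s - r) <= tolerance
  }
  sum(hit) / nt
}

#' All four charge-state features of one spectrum
#'
#' @inheritParams n_bs
#' @return Named numeric vector `c(delta_cp, delta_rcp, i_dc, n_bs)`.
#' @export
spectrum_features <- function(spectrum, constants = mass_constants(),
                              tolerance = 0.5, losses_enabled = TRUE, nt = 1) {
  rel <- enumerate_pair_relations(spectrum, constants, tolerance, losses_enabled)
  c(
    delta_cp = .delta_cp_from_relations(rel),
    delta_rcp = .delta_rcp_from_relations(rel, spectrum$intensity),
    i_dc = i_dc(spectrum, constants, tolerance),
    n_bs = n_bs(spectrum, constants, tolerance, nt)
  )
}

#' Build the scaled feature matrix for a spectrum collection
#'
#' Computes the selected features for every spectrum and divides each
#' column by its sample standard deviation so all features have unit
#' variance; the mixture model estimates the means, so centring is off by
#' default but available.
#'
#' @param collection An [spectrum_collection()] with at least two spectra.
#' @param features Ordered subset of
#'   `c("delta_cp", "delta_rcp", "i_dc", "n_bs")`. The default is the three
#'   most discriminant features.
#' @inheritParams n_bs
#' @param center Subtract column means before scaling (default FALSE).
#' @return An object of class `feature_matrix`: list with `scaled` (N x D
#'   numeric matrix), `raw` (unscaled), `scale_factors`, `centers` (0 when
#'   uncentred), and `feature_names`.
#' @export
build_feature_matrix <- function(collection,
                                 features = c("delta_cp", "delta_rcp", "i_dc"),
                                 constants = mass_constants(), tolerance = 0.5,
                                 losses_enabled = TRUE, nt = 1, center = FALSE) {
  stopifnot(inherits(collection, "ms_spectrum_collection"),
            length(collection$spectra) >= 2,
            length(features) >= 1,
            all(features %in% c("delta_cp", "delta_rcp", "i_dc", "n_bs")))
  raw <- t(vapply(
    collection$spectra,
    function(sp) spectrum_features(sp, constants, tolerance, losses_enabled, nt),
    numeric(4)
  ))
  rownames(raw) <- spectrum_ids(collection)
  scale_feature_matrix(raw[, features, drop = FALSE], center = center)
}

#' Scale a raw feature matrix to unit variance
#'
#' @param raw Numeric matrix (spectra x features) with column names.
#' @param center Subtract column means first.
#' @return A `feature_matrix` object (see [build_feature_matrix()]).
#' @export
scale_feature_matrix <- function(raw, center = FALSE) {
  stopifnot(is.matrix(raw), nrow(raw) >= 2, !is.null(colnames(raw)))
  sds <- apply(raw, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(colnames(raw)[sds == 0], collapse = ", "))
  }
  centers <- if (center) colMeans(raw) else rep(0, ncol(raw))
  scaled <- sweep(sweep(raw, 2, centers, "-"), 2, sds, "/")
  structure(
    list(scaled = scaled, raw = raw, scale_factors = sds, centers = centers,
         feature_names = colnames(raw)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d spectra x %d features (%s)\n",
              nrow(x$scaled), ncol(x$scaled), paste(x$feature_names, collapse = ", ")))
  cat("scale factors:", sprintf("%.4g", x$scale_factors), "\n")
  invisible(x)
}
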