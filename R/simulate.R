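# Synthetic ion-trap CID spectra of tryptic peptides at charge +2/+3, with
# the statistical structure the charge-state features exploit: b/y
# complementary pairs, (+1,+1) vs (+1,+2) emission asymmetry by precursor
# charge, doubly charged peaks above the precursor m/z for +3, a y-over-b
# intensity bias, and uniform noise peaks.

#' Parameters of the synthetic spectrum generator
#'
#' Defaults define the standard simulation conditions used throughout the
#' package's tests: half +2 and half +3 tryptic peptides of 8-20 residues,
#' 80% of bonds fragmenting into a detectable complementary pair, +3
#' peptides emitting a (+1,+2) pair at 70% of fragmented bonds, y ions with
#' twice the median intensity of b ions, 0.15 Da Gaussian m/z jitter (an
#' ion-trap-like centroid error), and on average 10 uniform noise peaks per
#' spectrum at half the median b-ion intensity. These defaults emulate the
#' charge-dependent structure the features exploit, not the full peak
#' density of real ion-trap spectra; see the vignette for what that
#' simplification implies.
#'
#' @param n_spectra Number of spectra to generate.
#' @param frac_plus3 Proportion of +3 precursors; the +3 count is
#'   `round(n_spectra * frac_plus3)` (deterministic, not Bernoulli).
#' @param peptide_length_range Integer range of residue counts.
#' @param fragmentation_efficiency Probability a peptide bond yields a
#'   detectable complementary pair.
#' @param plus12_fraction_for_3 Probability that a fragmented bond of a +3
#'   peptide emits a (+1,+2) pair rather than (+1,+1).
#' @param y_over_b_intensity_ratio Median intensity ratio of y over b ions.
#' @param noise_peaks_per_spectrum Poisson mean of uniform noise peaks.
#' @param noise_intensity_median Median intensity of noise peaks, on the
#'   scale where b ions have median 1; near-threshold chemical/electronic
#'   noise sits well below the real fragment ions.
#' @param mz_jitter_sd Gaussian m/z error (Da) added to every fragment peak.
#' @param intensity_cv Coefficient of variation of the lognormal peak
#'   intensities.
#' @param seed Integer seed making the whole dataset reproducible.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_spectra = 1000,
                       frac_plus3 = 0.5,
                       peptide_length_range = c(8L, 20L),
                       fragmentation_efficiency = 0.8,
                       plus12_fraction_for_3 = 0.7,
                       y_over_b_intensity_ratio = 2,
                       noise_peaks_per_spectrum = 10,
                       noise_intensity_median = 0.5,
                       mz_jitter_sd = 0.15,
                       intensity_cv = 0.5,
                       seed = 1L) {
  p <- list(
    n_spectra = as.integer(n_spectra),
    frac_plus3 = frac_plus3,
    peptide_length_range = as.integer(peptide_length_range),
    fragmentation_efficiency = fragmentation_efficiency,
    plus12_fraction_for_3 = plus12_fraction_for_3,
    y_over_b_intensity_ratio = y_over_b_intensity_ratio,
    noise_peaks_per_spectrum = noise_peaks_per_spectrum,
    noise_intensity_median = noise_intensity_median,
    mz_jitter_sd = mz_jitter_sd,
    intensity_cv = intensity_cv,
    seed = as.integer(seed)
  )
  stopifnot(
    p$n_spectra >= 1,
    p$frac_plus3 >= 0, p$frac_plus3 <= 1,
    length(p$peptide_length_range) == 2,
    p$peptide_length_range[1] >= 4,
    p$peptide_length_range[2] >= p$peptide_length_range[1],
    p$fragmentation_efficiency >= 0, p$fragmentation_efficiency <= 1,
    p$plus12_fraction_for_3 >= 0, p$plus12_fraction_for_3 <= 1,
    p$y_over_b_intensity_ratio > 0,
    p$noise_peaks_per_spectrum >= 0,
    p$noise_intensity_median > 0,
    p$mz_jitter_sd >= 0,
    p$intensity_cv >= 0,
    !is.na(p$seed)
  )
  class(p) <- "sim_params"
  p
}

#' Generate a random tryptic peptide for a given charge state
#'
#' The sequence ends in K or R (tryptic digestion). The number of basic
#' residues encodes the charge: a +2 peptide has no internal basic residue
#' (its two protons sit on the C-terminal basic site and the N-terminal
#' amine), while a +3 peptide carries exactly one additional internal K, R
#' or H. Uses the current R RNG; seed externally (or via
#' [generate_dataset()]) for reproducibility.
#'
#' @param charge Precursor charge, 2 or 3.
#' @param params A [sim_params()] object.
#' @param constants A [mass_constants()] object (supplies the residue
#'   alphabet).
#' @return Character vector of one-letter residue codes.
#' @export
generate_peptide <- function(charge, params = sim_params(),
                             constants = mass_constants()) {
  stopifnot(charge %in% c(2L, 3L))
  len <- sample(params$peptide_length_range[1]:params$peptide_length_range[2], 1L)
  nonbasic <- setdiff(names(constants$residue_masses), constants$basic_residues)
  seqs <- sample(nonbasic, len - 1L, replace = TRUE)
  if (charge == 3L) {
    pos <- sample.int(len - 1L, 1L)
    seqs[pos] <- sample(constants$basic_residues, 1L)
  }
  c(seqs, sample(c("K", "R"), 1L))
}

#' Generate one synthetic CID spectrum with ground truth
#'
#' For each peptide bond, with probability `fragmentation_efficiency` a
#' complementary b/y pair is emitted. A +2 precursor always emits (+1,+1);
#' a +3 precursor emits (+1,+2) with probability `plus12_fraction_for_3`,
#' else (+1,+1). The doubly charged member of a (+1,+2) pair is the y
#' fragment: it retains the C-terminal basic residue (and, for cleavages
#' N-terminal of the internal basic site, that site too), so it is the side
#' that keeps two protons; its m/z `(y1 + proton)/2` exceeds the precursor
#' m/z whenever the y fragment carries more than two thirds of the peptide
#' mass, populating the `[mp, 1.5*mp]` region that the regional-intensity
#' feature reads. Intensities are lognormal with the configured y-over-b median
#' ratio; every fragment m/z gets Gaussian jitter; Poisson-many noise peaks
#' are drawn uniformly in `(50, 2*mp)` with the configured median
#' intensity. Uses the current R RNG.
#'
#' @param sequence Character vector of residues (see [generate_peptide()]).
#' @param charge Precursor charge, 2 or 3.
#' @param params A [sim_params()] object.
#' @param constants A [mass_constants()] object.
#' @param spectrum_id Identifier for the resulting spectrum.
#' @return List with `spectrum` (an [spectrum()]) and `truth`, a list
#'   holding the sequence, charge, an `ions` data frame (bond, terminal,
#'   charge, theoretical and observed m/z) and the noise peak m/z values.
#' @export
generate_spectrum <- function(sequence, charge, params = sim_params(),
                              constants = mass_constants(),
                              spectrum_id = "synthetic") {
  stopifnot(charge %in% c(2L, 3L), length(sequence) >= 2)
  res_mass <- constants$residue_masses[sequence]
  if (any(is.na(res_mass))) stop("unknown residue in sequence")
  peptide_mass <- sum(res_mass) + constants$h2o
  mp <- (peptide_mass + charge * constants$proton) / charge
  nb <- length(sequence) - 1L
  prefix <- cumsum(res_mass)[seq_len(nb)]

  sdlog <- sqrt(log(1 + params$intensity_cv^2))
  ions <- list()
  for (bond in seq_len(nb)) {
    if (stats::runif(1) > params$fragmentation_efficiency) next
    b1 <- prefix[bond] + constants$proton
    y1 <- (peptide_mass - prefix[bond]) + constants$proton
    pair12 <- charge == 3L && stats::runif(1) < params$plus12_fraction_for_3
    b_charge <- 1L
    y_charge <- if (pair12) 2L else 1L
    b_mz <- if (b_charge == 2L) (b1 + constants$proton) / 2 else b1
    y_mz <- if (y_charge == 2L) (y1 + constants$proton) / 2 else y1
    b_int <- stats::rlnorm(1, meanlog = 0, sdlog = sdlog)
    y_int <- stats::rlnorm(1, meanlog = log(params$y_over_b_intensity_ratio),
                           sdlog = sdlog)
    ions[[length(ions) + 1L]] <- data.frame(
      bond = bond, terminal = c("N", "C"), charge = c(b_charge, y_charge),
      theo_mz = c(b_mz, y_mz),
      obs_mz = c(b_mz, y_mz) + stats::rnorm(2, sd = params$mz_jitter_sd),
      intensity = c(b_int, y_int),
      stringsAsFactors = FALSE
    )
  }
  ions <- if (length(ions) > 0) do.call(rbind, ions) else
    data.frame(bond = integer(0), terminal = character(0), charge = integer(0),
               theo_mz = numeric(0), obs_mz = numeric(0), intensity = numeric(0))

  n_noise <- stats::rpois(1, params$noise_peaks_per_spectrum)
  noise_mz <- stats::runif(n_noise, 50, 2 * mp)
  noise_int <- stats::rlnorm(n_noise, meanlog = log(params$noise_intensity_median),
                             sdlog = sdlog)

  sp <- spectrum(
    spectrum_id, mp,
    mz = c(ions$obs_mz, noise_mz),
    intensity = c(ions$intensity, noise_int),
    true_charge = charge
  )
  list(
    spectrum = sp,
    truth = list(sequence = sequence, charge = charge, precursor_mz = mp,
                 peptide_mass = peptide_mass, ions = ions, noise_mz = noise_mz)
  )
}

#' Generate a labeled synthetic dataset
#'
#' Seeds the RNG from `params$seed` (restoring the previous state on exit),
#' allocates `round(n_spectra * frac_plus3)` spectra to charge +3 and the
#' rest to +2, and generates one peptide and spectrum per slot. The
#' resulting collection carries the true charges and can be written as MGF
#' (with `CHARGE` lines) via [write_mgf()]; the per-spectrum ground truth is
#' returned alongside for oracle-style tests.
#'
#' @param params A [sim_params()] object.
#' @param constants A [mass_constants()] object.
#' @return List with `collection` (an [spectrum_collection()]) and `truth`
#'   (one ground-truth record per spectrum, in order).
#' @examples
#' sim <- generate_dataset(sim_params(n_spectra = 10, seed = 42))
#' table(true_charges(sim$collection))
#' @export
generate_dataset <- function(params = sim_params(), constants = mass_constants()) {
  stopifnot(inherits(params, "sim_params"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)

  n <- params$n_spectra
  n3 <- round(n * params$frac_plus3)
  charges <- c(rep(3L, n3), rep(2L, n - n3))
  spectra <- vector("list", n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    pep <- generate_peptide(charges[k], params, constants)
    g <- generate_spectrum(pep, charges[k], params, constants,
                           spectrum_id = sprintf("SYN_%05d", k))
    spectra[[k]] <- g$spectrum
    truth[[k]] <- g$truth
  }
  list(
    collection = spectrum_collection(
      spectra, source_path = sprintf("synthetic(seed=%d)", params$seed)
    ),
    truth = truth
  )
}
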