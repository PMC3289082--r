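test_that("peptide generation encodes charge in the basic-residue count", {
  p <- sim_params(seed = 90)
  mc <- mass_constants()
  set.seed(90)
  for (r in 1:200) {
    pep2 <- generate_peptide(2L, p)
    pep3 <- generate_peptide(3L, p)
    expect_true(pep2[length(pep2)] %in% c("K", "R"))
    expect_equal(sum(pep2 %in% mc$basic_residues), 1)  # C-terminus only
    expect_gte(sum(pep3 %in% mc$basic_residues), 2)
    expect_true(all(c(pep2, pep3) %in% names(mc$residue_masses)))
  }
  # same RNG state, same sequence
  set.seed(91)
  a <- generate_peptide(3L, p)
  set.seed(91)
  b <- generate_peptide(3L, p)
  expect_identical(a, b)
})

test_that("precursor and fragment masses follow the peptide mass arithmetic", {
  p <- sim_params(mz_jitter_sd = 0, noise_peaks_per_spectrum = 0,
                  fragmentation_efficiency = 1, seed = 92)
  mc <- mass_constants()
  set.seed(92)
  for (charge in c(2L, 3L)) {
    pep <- generate_peptide(charge, p)
    g <- generate_spectrum(pep, charge, p)
    M <- sum(mc$residue_masses[pep]) + mc$h2o
    expect_equal(g$truth$peptide_mass, M, tolerance = 1e-9)
    expect_equal(g$truth$precursor_mz, (M + charge * mc$proton) / charge,
                 tolerance = 1e-9)
    # every singly charged theoretical ion agrees with by_ion_mz
    ions <- g$truth$ions
    for (r in seq_len(nrow(ions))) {
      res <- if (ions$terminal[r] == "N") pep[1:ions$bond[r]] else
        pep[(ions$bond[r] + 1):length(pep)]
      expect_equal(ions$theo_mz[r],
                   by_ion_mz(res, ions$terminal[r], ions$charge[r], mc),
                   tolerance = 1e-9)
    }
  }
})

test_that("dataset allocation and seeding are deterministic", {
  sim <- generate_dataset(sim_params(n_spectra = 10, frac_plus3 = 0.5, seed = 93))
  expect_equal(sum(true_charges(sim$collection) == 3L), 5)
  f1 <- tempfile(fileext = ".mgf")
  f2 <- tempfile(fileext = ".mgf")
  write_mgf(generate_dataset(sim_params(n_spectra = 15, seed = 94))$collection, f1)
  write_mgf(generate_dataset(sim_params(n_spectra = 15, seed = 94))$collection, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the data
  f3 <- tempfile(fileext = ".mgf")
  write_mgf(generate_dataset(sim_params(n_spectra = 15, seed = 95))$collection, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("noiseless spectra expose their pair structure to the features", {
  p2 <- sim_params(fragmentation_efficiency = 1, noise_peaks_per_spectrum = 0,
                   mz_jitter_sd = 0, seed = 96)
  set.seed(96)
  pep <- generate_peptide(2L, p2)
  g <- generate_spectrum(pep, 2L, p2)
  # every bond contributes a CP11 pair at the default tolerance
  rel <- enumerate_pair_relations(g$spectrum)
  expect_gte(nrow(unique(rel[rel$kind == "CP11" & rel$z == 2, c("i", "j")])),
             length(unique(g$truth$ions$bond)))
  # a +3 spectrum emitting only (+1,+2) pairs has negative delta_cp
  p3 <- sim_params(fragmentation_efficiency = 1, noise_peaks_per_spectrum = 0,
                   mz_jitter_sd = 0, plus12_fraction_for_3 = 1, seed = 97)
  set.seed(97)
  pep3 <- generate_peptide(3L, p3)
  g3 <- generate_spectrum(pep3, 3L, p3)
  expect_lt(delta_cp(g3$spectrum), 0)
})

test_that("emitted pairs are always recovered under the true charge hypothesis", {
  p <- sim_params(mz_jitter_sd = 0, noise_peaks_per_spectrum = 0,
                  fragmentation_efficiency = 0.9, seed = 98)
  set.seed(98)
  for (charge in c(2L, 3L)) {
    for (r in 1:5) {
      pep <- generate_peptide(charge, p)
      g <- generate_spectrum(pep, charge, p)
      rel <- enumerate_pair_relations(g$spectrum)
      ions <- g$truth$ions
      for (bond in unique(ions$bond)) {
        pair <- ions[ions$bond == bond, ]
        i <- which(abs(g$spectrum$mz - min(pair$obs_mz)) < 1e-9)
        j <- which(abs(g$spectrum$mz - max(pair$obs_mz)) < 1e-9)
        kind_expected <- if (all(pair$charge == 1L)) "CP11" else
          if (pair$theo_mz[pair$charge == 2L] == max(pair$theo_mz))
            "CP12_HIGH2" else "CP12_LOW2"
        hit <- rel$i == i & rel$j == j & rel$kind == kind_expected &
          rel$z == charge
        expect_true(any(hit))
      }
    }
  }
})

test_that("noise-only spectra carry almost no feature signal", {
  p <- sim_params(n_spectra = 100, fragmentation_efficiency = 0, seed = 99)
  sim <- generate_dataset(p)
  feats <- t(vapply(sim$collection$spectra, spectrum_features, numeric(4)))
  expect_lt(mean(abs(feats[, "delta_cp"])), 0.5)
  expect_lt(mean(abs(feats[, "delta_rcp"])), 0.75)
  expect_lt(mean(feats[, "i_dc"]), 0.5)
  # the pseudo-count has a higher chance floor: three basic residues times
  # nine loss shifts give ~27 Da of matching window per peak pair
  expect_lt(mean(feats[, "n_bs"]), 2.5)
})

test_that("heavier noise degrades the end-to-end separation", {
  aucs <- vapply(c(0, 60), function(noise) {
    mean(vapply(c(301, 302), function(sd) {
      sim <- generate_dataset(sim_params(n_spectra = 200, seed = sd,
                                         noise_peaks_per_spectrum = noise))
      m <- charge_gmm(sim$collection, seed = sd)
      keep <- !is.na(true_charges(sim$collection))
      roc_auc(m$predictions$posterior_plus3[keep],
              true_charges(sim$collection)[keep])$auc
    }, numeric(1)))
  }, numeric(1))
  expect_gte(aucs[1], aucs[2])
})
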