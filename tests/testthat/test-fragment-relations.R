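test_that("b/y ion m/z arithmetic matches hand-computed monoisotopic sums", {
  # y1 of K: residue + water + proton
  expect_equal(by_ion_mz("K", "C", 1), 128.09496 + 18.01056 + 1.00728,
               tolerance = 1e-9)
  # b1 of G: residue + proton
  expect_equal(by_ion_mz("G", "N", 1), 57.02146 + 1.00728, tolerance = 1e-9)
  # the doubly charged counterpart of any fragment: (mz1 + proton)/2 exactly
  mc <- mass_constants()
  for (res in list(c("G", "A", "K"), c("P", "E", "P", "T", "I", "D", "E"))) {
    for (term in c("N", "C")) {
      expect_identical(by_ion_mz(res, term, 2, mc),
                       (by_ion_mz(res, term, 1, mc) + mc$proton) / 2)
    }
  }
  expect_error(by_ion_mz(c("G", "Z"), "N", 1), "unknown residue")
})

test_that("complementary-pair predicates accept constructed identities and reject others", {
  expect_true(is_cp11(200, 800, mp = 500, z = 2, tolerance = 0.5))
  expect_false(is_cp11(200, 800.6, mp = 500, z = 2, tolerance = 0.5))
  expect_true(is_cp12(300, 450, mp = 400, z = 3, which_is_2 = "high", tolerance = 0.5))
  expect_false(is_cp12(300, 450.3, mp = 400, z = 3, which_is_2 = "high", tolerance = 0.1))
  expect_error(is_cp11(800, 200, mp = 500, z = 2))  # m1 < m2 enforced
})

test_that("generated sibling pairs satisfy the predicate for their true charge", {
  p <- sim_params(fragmentation_efficiency = 1, noise_peaks_per_spectrum = 0,
                  mz_jitter_sd = 0, plus12_fraction_for_3 = 1, seed = 5)
  mc <- mass_constants()
  set.seed(5)
  for (charge in c(2L, 3L)) {
    pep <- generate_peptide(charge, p)
    g <- generate_spectrum(pep, charge, p)
    ions <- g$truth$ions
    for (bond in unique(ions$bond)) {
      pair <- ions[ions$bond == bond, ]
      lo <- min(pair$theo_mz)
      hi <- max(pair$theo_mz)
      if (charge == 2L) {
        expect_true(is_cp11(lo, hi, g$truth$precursor_mz, 2, mc, 0.5))
      } else {
        which2 <- if (pair$theo_mz[pair$charge == 2L] == hi) "high" else "low"
        expect_true(is_cp12(lo, hi, g$truth$precursor_mz, 3, which2, mc, 0.5))
      }
    }
  }
})

test_that("doubly charged peak detection follows the three evidence relations", {
  # d1: +1 counterpart at 2*mz - proton
  sp <- spectrum("d1", 600, c(250.0, 499.0), c(1, 1))
  expect_true(is_doubly_charged_peak(1, sp))
  # a lone peak has no partner
  sp1 <- spectrum("lone", 600, 250, 1)
  expect_false(is_doubly_charged_peak(1, sp1))
})

test_that("pair enumeration agrees with brute force on random spectra", {
  set.seed(20)
  for (r in 1:100) {
    sp <- random_spectrum(n_peaks = sample(2:14, 1))
    for (losses in c(TRUE, FALSE)) {
      got <- enumerate_pair_relations(sp, tolerance = 0.5, losses_enabled = losses)
      want <- bf_pair_relations(sp, tol = 0.5, losses_enabled = losses)
      expect_identical(relation_key(got), relation_key(want))
    }
    flags <- vapply(seq_along(sp$mz), is_doubly_charged_peak, logical(1),
                    spectrum = sp)
    expect_identical(flags, bf_doubly_charged(sp))
  }
})

test_that("enumeration honours its structural invariants", {
  expect_equal(nrow(enumerate_pair_relations(spectrum("e", 500, 100, 1))), 0)
  sp <- spectrum("one-pair", 500, c(200, 800), c(1, 1))
  rel <- enumerate_pair_relations(sp, losses_enabled = FALSE)
  expect_equal(nrow(rel), 1)
  expect_identical(rel$kind, "CP11")

  set.seed(33)
  for (r in 1:20) {
    sp <- random_spectrum(n_peaks = 10)
    narrow <- enumerate_pair_relations(sp, tolerance = 0.2)
    wide <- enumerate_pair_relations(sp, tolerance = 0.8)
    # widening the window never removes a relation
    expect_true(all(paste(narrow$i, narrow$j, narrow$kind, narrow$z) %in%
                      paste(wide$i, wide$j, wide$kind, wide$z)))
    # disabling losses yields a subset
    noloss <- enumerate_pair_relations(sp, losses_enabled = FALSE)
    withloss <- enumerate_pair_relations(sp, losses_enabled = TRUE)
    expect_true(all(paste(noloss$i, noloss$j, noloss$kind, noloss$z) %in%
                      paste(withloss$i, withloss$j, withloss$kind, withloss$z)))
    # each (i, j, kind, z) at most once
    expect_false(anyDuplicated(withloss[, c("i", "j", "kind", "z")]) > 0)
  }
})

test_that("noiseless +2 spectra recover a CP11 relation for every emitted bond", {
  p <- sim_params(fragmentation_efficiency = 1, noise_peaks_per_spectrum = 0,
                  mz_jitter_sd = 0, seed = 8)
  set.seed(8)
  pep <- generate_peptide(2L, p)
  g <- generate_spectrum(pep, 2L, p)
  rel <- enumerate_pair_relations(g$spectrum)
  n_bonds <- length(unique(g$truth$ions$bond))
  cp11_z2 <- unique(rel[rel$kind == "CP11" & rel$z == 2, c("i", "j")])
  expect_gte(nrow(cp11_z2), n_bonds)
})
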