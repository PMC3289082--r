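# msCharge

Unsupervised precursor charge-state assignment (+2 vs +3) for
low-resolution CID tandem mass spectra.

## Why

Ion-trap and triple-quadrupole instruments cannot resolve the isotope
spacing of a fragment-spectrum precursor, so its charge state is unknown
and every spectrum must be database-searched under each plausible charge —
doubling search time and multiplying false positives. For tryptic peptides
from electrospray ionisation the ambiguity is almost always +2 versus +3
(singly charged spectra are reliably recognised upstream). `msCharge`
resolves it directly from the fragment peaks, without any labeled training
data.

## How

Cleavage at a peptide bond produces a complementary b/y ion pair whose
masses are tied to the precursor. With `m_p` the precursor m/z under charge
hypothesis `z` and `p` the proton mass:

* (+1, +1) pair: `m1 + m2 = 2·m_p` (z = 2) or `3·m_p − p` (z = 3)
* (+1, +2) pair: `m1 + 2·m2 = 2·m_p + p` (z = 2) or `3·m_p` (z = 3)
  (`2·m1 + m2` when the lower-m/z member is the +2 ion)

all within a configurable window (default 0.5 Da) and with single
neutral-loss variants (H2O, NH3, CO, NH) considered. Four per-spectrum
features are built on these relations: the (+1,+1)-minus-(+1,+2)
complementary-pair count difference `delta_cp`, the complementary-pair
intensity-ratio difference `delta_rcp`, the doubly charged intensity in
`[m_p, 1.5·m_p]` (`i_dc`), and a basic-site pseudo-count `n_bs` from
K/R/H residue-mass peak differences. The features are scaled to unit
variance and clustered by a two-component spherical Gaussian mixture
fitted with EM; components are mapped to +2/+3 by the features' expected
directions, and each spectrum is called from its posterior.

The package includes an MGF reader/writer, ROC/AUC evaluation with
rank-statistic tie handling, and a seeded generator of synthetic ion-trap
CID spectra (b/y series, charge-dependent pair emission, y/b intensity
asymmetry, m/z jitter, noise peaks) so the whole pipeline is testable
without instrument data.

## Worked example

```r
library(msCharge)

sim   <- generate_dataset(sim_params(n_spectra = 300, seed = 11))
model <- charge_gmm(sim$collection, seed = 11)   # or charge_gmm("spectra.mgf")
summary(model)
```

```
Unsupervised charge-state classifier (2-component spherical GMM)
  300 spectra, features: delta_cp, delta_rcp, i_dc
  EM: 29 iteration(s), log-likelihood -1125.062
  component 2 -> +2, component 1 -> +3
  predicted: 116 spectra +2, 184 spectra +3 (threshold 0.50)

Component means (scaled features):
            delta_cp delta_rcp   i_dc
component_1  -0.1399   -0.0767 1.1507
component_2   1.2354    0.5975 0.0408
mixing: 0.632 0.368  variances: 1.058 0.137 

Against known charges: AUC 0.9605, accuracy 0.8867
    feature mean_plus2  mean_plus3 expected pass
1  delta_cp 1.21974953 -0.48754264  +2 > +3 TRUE
2 delta_rcp 0.37633594 -0.03362122  +2 > +3 TRUE
3      i_dc 0.06545988  1.41923393  +2 < +3 TRUE
```

The component with high `delta_cp`/`delta_rcp` means and low `i_dc` is the
+2 cluster; the AUC and accuracy lines appear because the synthetic
collection carries known charges (`CHARGE=2+/3+` lines in an MGF do the
same). `predict(model)` returns per-spectrum rows — the four raw feature
values, the posterior probability of +3 and the called charge — which
`write_predictions()` saves as a TSV:

```
  spectrum_id delta_cp delta_rcp  i_dc n_bs posterior_plus3 predicted_charge
1   SYN_00001      -15    0.6701 6.625   18               1                3
2   SYN_00002       -4    0.3252 7.965   10               1                3
```

A command-line front end with `predict`, `simulate` and `evaluate`
subcommands is at `inst/cli/mscharge.R`:

```sh
Rscript inst/cli/mscharge.R simulate --n 500 --output spectra.mgf --seed 1
Rscript inst/cli/mscharge.R predict  --input spectra.mgf --output pred.tsv --seed 1
Rscript inst/cli/mscharge.R evaluate --input pred.tsv --labels spectra.mgf
```

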