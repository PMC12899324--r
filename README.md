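# irdesc — infrared spectral descriptors for reaction yield prediction

`irdesc` is an R package for chemists and cheminformaticians who model
catalytic reaction yields on small high-throughput experimentation (HTE)
datasets and need a ligand encoding that generalizes to ligands absent
from the training data. Instead of one-hot indicators or generic
fingerprints, it derives fixed-length descriptors directly from a
ligand's discrete IR peak-list spectrum — the (wavenumber, intensity)
lines of a harmonic frequency calculation — which reflects both the
electronic distribution and the three-dimensional geometry of the
molecule.

## The method

The peak wavenumbers of **all** ligands in a set are pooled and the
wavenumber axis is partitioned into *k* bins by one-dimensional k-means
(k-means++ initialization, 10 restarts, Lloyd iteration; clusters
relabeled by ascending center). Each cluster *i*, with fitted point range
$[w^{min}_i, w^{max}_i]$, contributes one coordinate per ligand:

- **IntIR**: the maximum normalized intensity among the ligand's peaks in
  cluster *i* (per-spectrum normalization to max = 100), or **0** if the
  ligand has no peak there;
- **WaveIR**: the wavenumber of the ligand's most intense peak in cluster
  *i*, or **$w^{min}_i$** if the ligand has no peak there.

Descriptors are computed on the full harmonic range 0–4000 cm⁻¹ or on
the fingerprint region 0–1700 cm⁻¹, giving names like `IntIR040` and
`WaveIR017`. Around the descriptor sit: reaction-table handling
(full-factorial condition spaces, zero-yield exclusion, one-hot bases and
solvents, Celsius→Kelvin), nested leave-one-group-out (LOGO)
cross-validation over nine regressors (OLS, PLS, ridge, lasso, elastic
net, linear/Gaussian SVR, random forest, gradient boosting) with inner
LOGO hyperparameter selection, pooled R² / MAE / Spearman ρ reporting,
per-ligand deviation diagnostics (yield STD vs prediction MAE, with
Pearson r and two-sided p), an exact dynamic-programming oracle for 1-D
clustering, and a synthetic spectra/yield generator with known ground
truth. See the vignette in `vignettes/ir-descriptors.Rmd` for the full
model description.

## Worked example

Twelve synthetic ligands whose band positions encode a latent electronic
parameter θ, a 12 × 4 × 4 × 3 × 3 full-factorial reaction table (1,728
conditions), and an OLS model on the fingerprint-region wavenumber
descriptor, evaluated ligand-out:

```r
library(irdesc)

gen <- generateSpectra(12, seed = 1)                 # spectra + theta
rt  <- generateReactionTable(gen$theta, seed = 101)  # yields with known truth
rep_ <- evaluateDescriptorConfig(gen$spectra, rt$table,
                                 "WaveIR", fingerprintRegion(), k = 8,
                                 defaultRegistry("OLS")[[1]], seed = 1)
rep_
#> EvaluationReport WaveIR017 (k = 8) + OLS over 1728 rows, 12 ligands
#>   pooled R2 = 0.938, MAE = 4.23, rho = 0.971
head(perLigandMetrics(rep_), 3)
#>   ligand   n std_g mae_g rho_g
#> 1    L01 144  9.62  4.08 0.872
#> 2    L02 144  9.05  3.74 0.864
#> 3    L03 144  9.67  4.14 0.846
```

Every prediction here is for a ligand the model never saw: pooled
R² = 0.94 means the wavenumber descriptor recovered the latent ligand
effect (a 30 % yield swing) from band positions alone, with a mean
absolute error of 4.2 yield points against a noise SD of 5. The
per-ligand table feeds `diagnoseDeviations()`, which correlates each
ligand's yield variability with its prediction error.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/irdesc synth    --out-dir demo --seed 1
Rscript inst/scripts/irdesc ir2desc  --spectra demo/peaks.csv --kind WaveIR --region 017 --k 8 --out-dir demo
Rscript inst/scripts/irdesc evaluate --spectra demo/peaks.csv --reactions demo/reactions.csv \
    --kind WaveIR --region 017 --k 8 --method OLS --out-dir demo
```

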