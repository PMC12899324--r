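# Fixtures are built in code: no data files.

# Text of a harmonic-frequency job log with the standard
# three-modes-per-line layout. freqs/intens are split into blocks of <= 3.
gaussianLogLines <- function(freqs, intens) {
  stopifnot(length(freqs) == length(intens))
  lines <- c(" Entering vibrational analysis.",
             " Harmonic frequencies (cm**-1), IR intensities (KM/Mole):")
  idx <- split(seq_along(freqs), ceiling(seq_along(freqs) / 3))
  for (b in idx) {
    lines <- c(lines,
      paste0(" Frequencies --", paste(sprintf("%12.4f", freqs[b]), collapse = "")),
      paste0(" Red. masses --", paste(sprintf("%12.4f", seq_along(b)), collapse = "")),
      paste0(" IR Inten    --", paste(sprintf("%12.4f", intens[b]), collapse = "")))
  }
  c(lines, " Normal termination.")
}

# Two-cluster toy: spectra whose pooled fingerprint-region peaks are
# {500, 800, 1100, 1450, 1525, 1600}. The SSE-optimal 2-partition of that
# set is {500,800,1100} | {1450,1525,1600} (checked against the DP oracle
# in the clustering tests), so the fitted ranges are (500,1100), (1450,1600).
toyClusterModel <- function() {
  sp <- list(irSpectrum("f1", c(500, 1100, 1525), c(1, 1, 1)),
             irSpectrum("f2", c(800, 1450, 1600), c(1, 1, 1)))
  fitWavenumberClusters(sp, k = 2, region = fingerprintRegion(), seed = 0)
}

# Random peak-list spectrum for property tests.
randomSpectrum <- function(id, n = 10, lo = 50, hi = 3900) {
  irSpectrum(id, runif(n, lo, hi), rlnorm(n, log(20), 1))
}

# Small synthetic dataset for evaluation tests: nLigands ligands, 4 bases x
# 4 solvents (x temps/concs optional).
smallSynthData <- function(nLigands = 6, seed = 3, tempsC = NULL,
                           concentrations = NULL, ...) {
  gen <- generateSpectra(nLigands, seed = seed)
  rt <- generateReactionTable(gen$theta, tempsC = tempsC,
                              concentrations = concentrations,
                              seed = seed + 50, ...)
  list(spectra = gen$spectra, theta = gen$theta, table = rt$table,
       truth = rt$truth)
}
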