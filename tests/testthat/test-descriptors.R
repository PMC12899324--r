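test_that("IntIR and WaveIR follow the per-cluster extraction and fallback rules", {
  m <- toyClusterModel()
  expect_equal(unname(clusterRanges(m)),
               matrix(c(500, 1100, 1450, 1600), 2, byrow = TRUE))

  # three normalized peaks: cluster 1 holds (700, 25) and (1100, 100),
  # cluster 2 holds (1500, 56.25)
  toy <- irSpectrum("toy", c(700, 1100, 1500), c(25, 100, 56.25))
  expect_equal(intIrVector(toy, m), c(100, 56.25))
  expect_equal(waveIrVector(toy, m), c(1100, 1500))

  # a spectrum populating only cluster 1: IntIR falls back to 0, WaveIR to
  # the empty cluster's range minimum
  lone <- normalizeIntensities(irSpectrum("lone", 500, 7))
  expect_equal(intIrVector(lone, m), c(100, 0))
  expect_equal(waveIrVector(lone, m), c(500, 1450))

  # intensity tie inside one cluster resolves to the lower wavenumber
  tie <- irSpectrum("tie", c(800, 900), c(100, 100))
  expect_equal(waveIrVector(tie, m), c(800, 1450))
})

test_that("empty spectra take the degenerate fallback vectors", {
  m <- toyClusterModel()
  empty <- irSpectrum("none")
  expect_warning(v <- intIrVector(empty, m), "all zeros")
  expect_equal(v, c(0, 0))
  expect_equal(waveIrVector(empty, m), unname(clusterRanges(m)[, 1]))
  expect_error(intIrVector(irSpectrum("raw", 700, 3), m), "normalized")
})

test_that("descriptor tables are named by kind and region and shaped n x k", {
  spectra <- withr::with_seed(21, lapply(1:8, function(i)
    randomSpectrum(paste0("L", i), 12, lo = 100, hi = 3900)))
  t1 <- buildDescriptorTable(spectra, "WaveIR", fingerprintRegion(), 6, 0)
  expect_identical(descriptorName(t1), "WaveIR017")
  t2 <- buildDescriptorTable(spectra, "IntIR", fullRegion(), 6, 0)
  expect_identical(descriptorName(t2), "IntIR040")
  expect_equal(dim(descriptorValues(t2)), c(8L, 6L))
  expect_identical(rownames(descriptorValues(t1)), paste0("L", 1:8))
  expect_identical(colnames(descriptorValues(t1)),
                   sprintf("WaveIR017_c%02d", 1:6))
  expect_true(all(descriptorValues(t2) >= 0 & descriptorValues(t2) <= 100))
})

test_that("descriptors are invariant to intensity scale and peak order", {
  withr::with_seed(31, {
    spectra <- lapply(1:6, function(i) randomSpectrum(paste0("L", i), 10))
    m <- fitWavenumberClusters(spectra, 5, fingerprintRegion(), 0)
    for (i in 1:10) {
      s <- spectra[[sample(6, 1)]]
      c_ <- runif(1, 1e-3, 1e3)
      f <- suppressWarnings(filterRegion(s, fingerprintRegion()))
      scaled <- irSpectrum(compoundId(f), peakWavenumbers(f),
                           peakIntensities(f) * c_)
      expect_equal(intIrVector(normalizeIntensities(f), m),
                   intIrVector(normalizeIntensities(scaled), m))
      expect_equal(waveIrVector(f, m), waveIrVector(scaled, m))
      perm <- sample(nPeaks(f))
      shuffled <- irSpectrum(compoundId(f), peakWavenumbers(f)[perm],
                             peakIntensities(f)[perm])
      expect_equal(waveIrVector(f, m), waveIrVector(shuffled, m))
    }
  })
})

test_that("structural invariants hold for fitting ligands", {
  withr::with_seed(41, {
    spectra <- lapply(1:6, function(i)
      randomSpectrum(paste0("L", i), 8, lo = 100, hi = 1650))
    m <- fitWavenumberClusters(spectra, 5, fingerprintRegion(), 0)
    rng <- clusterRanges(m)
    for (s in spectra) {
      w <- waveIrVector(s, m)
      expect_true(all(w >= rng[, 1] & w <= rng[, 2]))
      # the cluster holding the spectrum's global maximum reads exactly 100
      norm <- normalizeIntensities(s)
      v <- intIrVector(norm, m)
      top <- assignClusters(m, norm)[which.max(peakIntensities(norm))]
      expect_equal(v[top], 100)
    }
  })
})

test_that("k = distinct pooled wavenumbers reduces WaveIR to point identity", {
  sp <- list(irSpectrum("a", c(300, 900), c(1, 2)),
             irSpectrum("b", c(600, 1200), c(3, 4)))
  tab <- buildDescriptorTable(sp, "WaveIR", fingerprintRegion(), k = 4)
  vals <- descriptorValues(tab)
  # every coordinate is either the ligand's own fitting wavenumber or the
  # singleton cluster's range minimum — and with singleton fitting clusters
  # both equal the unique pooled point
  pooled <- c(300, 600, 900, 1200)
  expect_equal(unname(vals["a", ]), pooled)
  expect_equal(unname(vals["b", ]), pooled)
})

test_that("descriptor tables write a CSV plus a model sidecar", {
  spectra <- withr::with_seed(51, lapply(1:4, function(i)
    randomSpectrum(paste0("L", i), 9)))
  tab <- buildDescriptorTable(spectra, "WaveIR", fingerprintRegion(), 5, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDescriptorTable(tab, path)
  back <- read.csv(path, check.names = FALSE)
  expect_identical(names(back)[1], "compound_id")
  expect_equal(dim(back), c(4L, 6L))
  expect_equal(as.matrix(back[, -1]), descriptorValues(tab),
               ignore_attr = TRUE)
  sidecar <- sub("\\.csv$", "_model.json", path)
  expect_true(file.exists(sidecar))
  m <- readClusterModel(sidecar)
  expect_equal(clusterCenters(m), clusterCenters(descriptorModel(tab)))
})

test_that("degenerate descriptor-table inputs are rejected", {
  sp <- withr::with_seed(61, lapply(1:3, function(i)
    randomSpectrum(paste0("L", i), 3, lo = 100, hi = 1000)))
  expect_error(buildDescriptorTable(sp[1], "IntIR", fullRegion(), 2),
               "at least 2 spectra")
  dup <- c(sp, list(irSpectrum("L1", 500, 1)))
  expect_error(buildDescriptorTable(dup, "IntIR", fullRegion(), 2),
               "duplicate compound ids")
  expect_error(buildDescriptorTable(sp, "WaveIR", fullRegion(), 50),
               "infeasible")
})
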