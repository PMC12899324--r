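test_that("full factorial enumeration reproduces the screened space sizes", {
  aryl <- enumerateFullFactorial(list(
    ligand_id = sprintf("L%02d", 1:12), base_id = paste0("B", 1:4),
    solvent_id = paste0("S", 1:4), concentration = c(0.05, 0.1, 0.15),
    temperature_k = celsiusToKelvin(c(60, 90, 120))))
  expect_equal(nrow(aryl), 1728L)
  smc <- enumerateFullFactorial(list(ligand_id = paste0("L", 1:8),
                                     base_id = paste0("B", 1:8),
                                     solvent_id = paste0("S", 1:4)))
  expect_equal(nrow(smc), 256L)
  one <- enumerateFullFactorial(list(a = "x", b = 1, c = TRUE))
  expect_equal(nrow(one), 1L)
  expect_error(enumerateFullFactorial(list(a = 1:2, b = character())),
               "at least one level")
  expect_error(enumerateFullFactorial(list(1:2)), "named list")
})

test_that("enumeration is lexicographic with the first factor slowest", {
  g <- enumerateFullFactorial(list(a = c("a1", "a2"), b = c("b1", "b2", "b3")))
  expect_equal(g$a, rep(c("a1", "a2"), each = 3))
  expect_equal(g$b, rep(c("b1", "b2", "b3"), 2))
  # row count equals the product of level counts for random level shapes
  withr::with_seed(71, {
    for (i in 1:5) {
      sizes <- sample(1:6, sample(2:4, 1), replace = TRUE)
      levels <- lapply(sizes, seq_len)
      names(levels) <- paste0("f", seq_along(levels))
      expect_equal(nrow(enumerateFullFactorial(levels)), prod(sizes))
    }
  })
})

test_that("zero-yield exclusion removes exactly the 0% rows", {
  tab <- data.frame(ligand_id = "L", base_id = "B", solvent_id = "S",
                    yield = c(0, 10, 0, 55, 100))
  suppressMessages(kept <- excludeZeroYield(tab))
  expect_equal(kept$yield, c(10, 55, 100))
  suppressMessages(expect_equal(excludeZeroYield(kept), kept))
  allzero <- transform(tab, yield = 0)
  suppressMessages(expect_warning(out <- excludeZeroYield(allzero),
                                  "all rows"))
  expect_equal(nrow(out), 0L)
  # partition property: removed set == zero set, order preserved
  withr::with_seed(81, {
    y <- round(runif(200, 0, 100)); y[sample(200, 60)] <- 0
    big <- data.frame(ligand_id = "L", base_id = "B", solvent_id = "S",
                      yield = y)
    suppressMessages(res <- excludeZeroYield(big))
    expect_equal(res$yield, y[y > 0])
  })
})

test_that("Celsius converts to Kelvin by the exact offset", {
  expect_equal(celsiusToKelvin(25), 298.15)
  expect_equal(celsiusToKelvin(0), 273.15)
  expect_equal(celsiusToKelvin(-273.15), 0)
  expect_error(celsiusToKelvin(-300), "absolute zero")
})

test_that("feature assembly lays out descriptor, one-hot and numeric blocks", {
  withr::with_seed(91, {
    spectra <- lapply(1:8, function(i) randomSpectrum(paste0("L", i), 10))
    desc <- buildDescriptorTable(spectra, "WaveIR", fingerprintRegion(), 6, 0)
    tab <- expand.grid(ligand_id = paste0("L", 1:8),
                       base_id = paste0("B", 1:8),
                       solvent_id = paste0("S", 1:4),
                       stringsAsFactors = FALSE)
    tab$yield <- runif(nrow(tab), 1, 99)
    fm <- assembleFeatureMatrix(tab, desc)
    X <- featureX(fm)
    expect_equal(ncol(X), 6L + 8L + 4L)     # descriptor + bases + solvents
    expect_equal(nrow(X), 256L)
    baseBlock <- X[, grepl("^base_", colnames(X))]
    solvBlock <- X[, grepl("^solvent_", colnames(X))]
    expect_true(all(rowSums(baseBlock) == 1))
    expect_true(all(rowSums(solvBlock) == 1))
    expect_identical(featureGroups(fm), tab$ligand_id)
    # rows sharing a ligand share the descriptor sub-vector
    d <- X[, 1:6]
    same <- which(tab$ligand_id == "L3")
    expect_true(all(apply(d[same, ], 2, function(col) all(col == col[1]))))
    # numeric columns appended when present
    tab2 <- tab; tab2$concentration <- 0.1; tab2$temperature_k <- 333.15
    X2 <- featureX(assembleFeatureMatrix(tab2, desc))
    expect_identical(tail(colnames(X2), 2), c("concentration", "temperature_k"))
  })
})

test_that("feature assembly is permutation-equivariant and validates ligands", {
  withr::with_seed(101, {
    spectra <- lapply(1:4, function(i) randomSpectrum(paste0("L", i), 8))
    desc <- buildDescriptorTable(spectra, "IntIR", fullRegion(), 5, 0)
    tab <- data.frame(ligand_id = rep(paste0("L", 1:4), each = 3),
                      base_id = rep(c("B1", "B2", "B3"), 4),
                      solvent_id = "S1", yield = runif(12, 1, 99))
    fm <- assembleFeatureMatrix(tab, desc)
    perm <- sample(nrow(tab))
    fmP <- assembleFeatureMatrix(tab[perm, ], desc)
    expect_equal(featureX(fmP), featureX(fm)[perm, ], ignore_attr = TRUE)
    expect_equal(featureY(fmP), featureY(fm)[perm])

    bad <- rbind(tab, data.frame(ligand_id = "L9", base_id = "B1",
                                 solvent_id = "S1", yield = 5))
    expect_error(assembleFeatureMatrix(bad, desc), "L9")
    oor <- tab; oor$yield[1] <- 150
    expect_error(assembleFeatureMatrix(oor, desc), "yield")
  })
})

test_that("reaction CSV round-trips with Celsius temperatures", {
  tab <- data.frame(ligand_id = c("L1", "L2"), base_id = "B1",
                    solvent_id = "S1", concentration = c(0.05, 0.1),
                    temperature_k = celsiusToKelvin(c(60, 90)),
                    yield = c(12.5, 80))
  path <- withr::local_tempfile(fileext = ".csv")
  writeReactionCsv(tab, path)
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "temperature_c")
  back <- readReactionCsv(path)
  expect_equal(back$temperature_k, tab$temperature_k)
  expect_equal(back$yield, tab$yield)
  expect_error(readReactionCsv(withr::local_tempfile(fileext = ".csv",
                                                     lines = "a,b")),
               "missing column")
})
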