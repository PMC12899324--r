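test_that("LOGO splits partition rows with one fold per group", {
  folds <- logoSplits(c("A", "A", "B", "C"))
  expect_length(folds, 3L)
  expect_equal(folds[[1]]$test, c(1L, 2L))
  expect_equal(folds[[2]]$test, 3L)
  expect_equal(folds[[3]]$test, 4L)
  withr::with_seed(7, {
    g <- sample(letters[1:6], 40, replace = TRUE)
    folds <- logoSplits(g)
    expect_length(folds, length(unique(g)))
    tests <- unlist(lapply(folds, `[[`, "test"))
    expect_setequal(tests, seq_along(g))
    expect_equal(anyDuplicated(tests), 0L)
    for (f in folds) expect_false(f$group %in% g[f$train])
  })
  expect_error(logoSplits(rep("A", 5)), "at least 2 distinct groups")
})

test_that("pooled metrics match their definitions", {
  m <- computeMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(r2 = 1, mae = 0, rho = 1))
  expect_equal(computeMetrics(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  const <- computeMetrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(const$r2, 0)
  expect_equal(const$mae, 2 / 3)
  expect_true(is.na(const$rho))            # undefined, reported missing
  expect_error(computeMetrics(c(5, 5, 5), c(1, 2, 3)), "constant yTrue")
  expect_error(computeMetrics(1:3, 1:4), "same length")
  # ties receive average ranks
  expect_equal(computeMetrics(c(1, 2, 2, 4), c(1, 3, 3, 9))$rho, 1)
})

test_that("noiseless linear yields are recovered exactly by nested-LOGO OLS", {
  gen <- generateSpectra(8, jitterSd = 0, seed = 5)
  rt <- generateReactionTable(gen$theta, noiseSd = 0, seed = 6)
  rep_ <- evaluateDescriptorConfig(gen$spectra, rt$table, "WaveIR",
                                   fingerprintRegion(), 6,
                                   defaultRegistry("OLS")[[1]], seed = 5)
  m <- pooledMetrics(rep_)
  expect_gt(m$r2, 1 - 1e-8)
  expect_lt(m$mae, 1e-6)
})

test_that("permuted labels give no spurious generalization", {
  gen <- generateSpectra(8, seed = 15)
  rt <- generateReactionTable(gen$theta, seed = 16)
  tab <- rt$table
  tab$yield <- withr::with_seed(99, sample(tab$yield))
  rep_ <- evaluateDescriptorConfig(gen$spectra, tab, "WaveIR",
                                   fingerprintRegion(), 6,
                                   defaultRegistry("OLS")[[1]], seed = 15)
  expect_lte(pooledMetrics(rep_)$r2, 0.05)
})

test_that("test-ligand rows never reach training or inner selection", {
  withr::with_seed(111, {
    spectra <- lapply(1:5, function(i) randomSpectrum(paste0("L", i), 8))
    desc <- buildDescriptorTable(spectra, "WaveIR", fingerprintRegion(), 5, 0)
    tab <- expand.grid(ligand_id = paste0("L", 1:5),
                       base_id = c("B1", "B2"), solvent_id = c("S1", "S2"),
                       stringsAsFactors = FALSE)
    tab$yield <- runif(nrow(tab), 1, 99)   # continuous: a.s. unique per row
    fm <- assembleFeatureMatrix(tab, desc)
  })
  seen <- list()
  spy <- irdesc:::makeRegressorSpec(
    "SPY", list(dummy = c(1, 2)), TRUE,
    fit = function(X, y, params, seed) { seen[[length(seen) + 1]] <<- y
                                         irdesc:::fitOls(X, y, params, seed) },
    predict = irdesc:::predictOls)
  rep_ <- nestedLogoEvaluate(fm, spy, seed = 0)
  # per outer fold: 2 candidates x 4 inner folds + 1 final fit = 9 calls
  expect_length(seen, 5L * 9L)
  y <- featureY(fm); groups <- featureGroups(fm)
  for (fi in 1:5) {
    testY <- y[groups == paste0("L", fi)]
    foldCalls <- seen[((fi - 1) * 9 + 1):(fi * 9)]
    for (trainY in foldCalls) expect_length(intersect(trainY, testY), 0L)
  }
  # out-of-fold predictions partition the rows
  preds <- oofPredictions(rep_)
  expect_false(anyNA(preds$y_pred))
  expect_equal(sort(preds$row), seq_along(y))
  expect_equal(unname(table(preds$fold)), rep(4L, 5L), ignore_attr = TRUE)
})

test_that("pooled MAE equals the group-size-weighted mean of per-ligand MAEs", {
  dat <- smallSynthData(5, seed = 23)
  rep_ <- evaluateDescriptorConfig(dat$spectra, dat$table, "WaveIR",
                                   fingerprintRegion(), 5,
                                   defaultRegistry("OLS")[[1]], seed = 2)
  per <- perLigandMetrics(rep_)
  weighted <- sum(per$mae_g * per$n) / sum(per$n)
  expect_equal(weighted, pooledMetrics(rep_)$mae, tolerance = 1e-12)
})

test_that("stochastic methods reproduce bit-identically under a fixed seed", {
  dat <- smallSynthData(4, seed = 33)
  r1 <- evaluateDescriptorConfig(dat$spectra, dat$table, "WaveIR",
                                 fingerprintRegion(), 5,
                                 defaultRegistry("RF")[[1]], seed = 8)
  r2 <- evaluateDescriptorConfig(dat$spectra, dat$table, "WaveIR",
                                 fingerprintRegion(), 5,
                                 defaultRegistry("RF")[[1]], seed = 8)
  expect_identical(oofPredictions(r1)$y_pred, oofPredictions(r2)$y_pred)
})

test_that("hyperparameter selection needs enough groups, OLS does not", {
  dat <- smallSynthData(3, seed = 43)
  sub <- dat$table[dat$table$ligand_id %in% c("L01", "L02"), ]
  spectra2 <- dat$spectra[c("L01", "L02")]
  ols <- evaluateDescriptorConfig(spectra2, sub, "WaveIR",
                                  fingerprintRegion(), 4,
                                  defaultRegistry("OLS")[[1]], seed = 1)
  expect_s4_class(ols, "EvaluationReport")
  expect_error(evaluateDescriptorConfig(spectra2, sub, "WaveIR",
                                        fingerprintRegion(), 4,
                                        defaultRegistry("RR")[[1]], seed = 1),
               ">= 2 training groups")
})

test_that("wavenumber descriptors generalize to held-out ligands where one-hot cannot", {
  dat <- smallSynthData(8, seed = 53)
  wave <- evaluateDescriptorConfig(dat$spectra, dat$table, "WaveIR",
                                   fingerprintRegion(), 6,
                                   defaultRegistry("OLS")[[1]], seed = 3)
  # one-hot ligand encoding: held-out ligand columns are all-zero at test
  tab <- dat$table
  X <- cbind(irdesc:::oneHot(tab$ligand_id, "ligand"),
             irdesc:::oneHot(tab$base_id, "base"),
             irdesc:::oneHot(tab$solvent_id, "solvent"))
  fmOhe <- new("FeatureMatrix", X = X, y = tab$yield,
               groups = tab$ligand_id, descriptorName = "OHE")
  ohe <- nestedLogoEvaluate(fmOhe, defaultRegistry("OLS")[[1]], seed = 3)
  expect_gt(pooledMetrics(wave)$r2, pooledMetrics(ohe)$r2)
  expect_lt(pooledMetrics(ohe)$r2, 0.2)
})

test_that("configuration sweeps tabulate every combination and pick min-MAE", {
  dat <- smallSynthData(6, seed = 63)
  res <- sweepAndSelect(dat$spectra, dat$table, kinds = c("IntIR", "WaveIR"),
                        regions = list(fingerprintRegion()), kRange = 5:6,
                        registry = defaultRegistry(c("OLS", "PLS")),
                        seed = 1)
  expect_equal(nrow(res$summary), 2 * 1 * 2 * 2)
  expect_setequal(unique(res$summary$descriptor), c("IntIR017", "WaveIR017"))
  expect_equal(res$best$mae, min(res$summary$mae))
  expect_s4_class(res$bestReport, "EvaluationReport")
  expect_identical(res$bestReport@method, res$best$method)
  # report serialization
  path <- withr::local_tempfile(fileext = ".json")
  writeEvaluationReport(res$bestReport, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$pooled$mae, res$best$mae)
})

test_that("the PLS1 implementation matches an independent PLS routine", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(7, {
    X <- matrix(rnorm(300), 30, 10)
    colnames(X) <- paste0("v", 1:10)
    y <- drop(X %*% rnorm(10)) + rnorm(30, 0, 0.2)
  })
  for (ncomp in c(1, 3, 5)) {
    mine <- irdesc:::fitPls(X, y, list(ncomp = ncomp), 0)
    ref <- mixOmics::pls(X, y, ncomp = ncomp, mode = "regression",
                         scale = FALSE)
    refPred <- drop(predict(ref, X)$predict[, 1, ncomp])
    expect_equal(irdesc:::predictPls(mine, X), refPred, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})
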