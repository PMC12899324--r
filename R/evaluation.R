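#' @include regressors.R
NULL

# ---- LOGO splits ------------------------------------------------------------

#' Leave-one-group-out fold indices
#'
#' One fold per distinct group (here, per ligand): the fold's test set is
#' all rows of that group, its training set the rest. Folds are ordered by
#' first appearance of the group. The test sets partition the row index
#' set, so every row receives exactly one out-of-fold prediction.
#'
#' @param groups vector of group ids, one per row (at least 2 distinct)
#' @return list of folds, each `list(group, train, test)` with integer row
#'   indices
#' @examples
#' logoSplits(c("A", "A", "B", "C"))
#' @export
logoSplits <- function(groups) {
  groups <- as.character(groups)
  ids <- unique(groups)
  if (length(ids) < 2L)
    stop("leave-one-group-out needs at least 2 distinct groups",
         call. = FALSE)
  lapply(ids, function(g)
    list(group = g, train = which(groups != g), test = which(groups == g)))
}

# ---- Metrics ----------------------------------------------------------------

#' Pooled prediction metrics: R-squared, MAE, Spearman rho
#'
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; `mae` is the mean
#' absolute error; `rho` is Spearman's rank correlation (Pearson
#' correlation of average-ranked vectors, ties receiving average ranks).
#' A constant prediction vector leaves rho undefined: it is reported as
#' `NA` (missing), never coerced to 0. Constant observed values leave both
#' r2 and rho undefined and raise an error.
#'
#' @param yTrue observed values (length >= 2, not constant)
#' @param yPred predicted values, same length
#' @return named list `list(r2, mae, rho)`
#' @examples
#' computeMetrics(c(1, 2, 3), c(1.1, 2.1, 2.9))
#' @export
computeMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have the same length", call. = FALSE)
  if (length(yTrue) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(yTrue) || anyNA(yPred))
    stop("missing values in yTrue or yPred", call. = FALSE)
  ssTot <- sum((yTrue - mean(yTrue))^2)
  if (ssTot == 0)
    stop("constant yTrue: r2 and rho are undefined", call. = FALSE)
  r2 <- 1 - sum((yTrue - yPred)^2) / ssTot
  mae <- mean(abs(yTrue - yPred))
  rho <- if (stats::sd(yPred) == 0) NA_real_ else
    cor(yTrue, yPred, method = "spearman")
  list(r2 = r2, mae = mae, rho = rho)
}

# ---- EvaluationReport -------------------------------------------------------

#' Nested-LOGO evaluation report
#'
#' Out-of-fold predictions and pooled metrics for one
#' (descriptor, k, method) configuration, plus per-ligand metrics for
#' deviation diagnostics. Metrics are pooled over all out-of-fold
#' predictions (per-fold R2 on one ligand's conditions is too unstable to
#' be the primary report); per-ligand MAEs recombine to the pooled MAE as a
#' group-size-weighted mean.
#'
#' @slot descriptorName descriptor used for the ligand block
#' @slot k cluster count of that descriptor
#' @slot method registry name of the regressor
#' @slot predictions data.frame `row`, `ligand`, `y_true`, `y_pred`, `fold`
#' @slot pooled list `r2`, `mae`, `rho`
#' @slot perLigand data.frame `ligand`, `n`, `std_g`, `mae_g`, `rho_g`
#' @slot chosenParams per-fold selected hyperparameters
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(descriptorName = "character", k = "integer",
                 method = "character", predictions = "data.frame",
                 pooled = "list", perLigand = "data.frame",
                 chosenParams = "list"))

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport %s (k = %d) + %s over %d rows, %d ligands\n",
              object@descriptorName, object@k, object@method,
              nrow(object@predictions), nrow(object@perLigand)))
  cat(sprintf("  pooled R2 = %.3f, MAE = %.2f, rho = %s\n",
              object@pooled$r2, object@pooled$mae,
              ifelse(is.na(object@pooled$rho), "NA",
                     sprintf("%.3f", object@pooled$rho))))
})

#' EvaluationReport accessors
#' @param x an [EvaluationReport-class]
#' @return `pooledMetrics()` list `r2`/`mae`/`rho`; `oofPredictions()` the
#'   out-of-fold prediction data.frame; `perLigandMetrics()` the per-ligand
#'   table (`n`, `std_g`, `mae_g`, `rho_g`)
#' @export
pooledMetrics <- function(x) { stopifnot(is(x, "EvaluationReport")); x@pooled }

#' @rdname pooledMetrics
#' @export
oofPredictions <- function(x) { stopifnot(is(x, "EvaluationReport")); x@predictions }

#' @rdname pooledMetrics
#' @export
perLigandMetrics <- function(x) { stopifnot(is(x, "EvaluationReport")); x@perLigand }

perLigandTable <- function(predictions) {
  split_ <- split(predictions, predictions$ligand)
  out <- do.call(rbind, lapply(split_, function(d) {
    rho <- if (nrow(d) < 2L || stats::sd(d$y_true) == 0 ||
               stats::sd(d$y_pred) == 0) NA_real_ else
      cor(d$y_true, d$y_pred, method = "spearman")
    data.frame(ligand = d$ligand[1L], n = nrow(d),
               std_g = if (nrow(d) >= 2L) stats::sd(d$y_true) else NA_real_,
               mae_g = mean(abs(d$y_true - d$y_pred)), rho_g = rho)
  }))
  out <- out[order(match(out$ligand, unique(predictions$ligand))), ]
  rownames(out) <- NULL
  out
}

makeEvaluationReport <- function(descriptorName, k, method, predictions,
                                 chosenParams) {
  new("EvaluationReport", descriptorName = descriptorName,
      k = as.integer(k), method = method, predictions = predictions,
      pooled = computeMetrics(predictions$y_true, predictions$y_pred),
      perLigand = perLigandTable(predictions), chosenParams = chosenParams)
}

# ---- training-fold scaling --------------------------------------------------

trainScaler <- function(Xtr) {
  center <- colMeans(Xtr)
  scale <- apply(Xtr, 2L, stats::sd)
  scale[scale == 0] <- 1            # constant columns pass through centered
  function(X) sweep(sweep(X, 2L, center), 2L, scale, `/`)
}

# ---- single-fold nested fit -------------------------------------------------

# Inner LOGO over the training ligands selects the grid candidate with the
# minimal pooled inner MAE (ties -> first candidate in declared order);
# the model is then refit on the full outer-training set.
fitPredictFold <- function(Xtr, ytr, gtr, Xte, spec, seed) {
  if (spec$scale) {
    scaler <- trainScaler(Xtr)
    XtrS <- scaler(Xtr); XteS <- scaler(Xte)
  } else {
    XtrS <- Xtr; XteS <- Xte
  }
  cand <- gridCandidates(spec)
  if (nrow(cand) > 1L) {
    if (length(unique(gtr)) < 2L)
      stop("inner hyperparameter selection needs >= 2 training groups",
           call. = FALSE)
    inner <- logoSplits(gtr)
    maes <- vapply(seq_len(nrow(cand)), function(ci) {
      params <- as.list(cand[ci, , drop = FALSE])
      pred <- numeric(length(ytr))
      for (f in inner) {
        if (spec$scale) {
          sc <- trainScaler(Xtr[f$train, , drop = FALSE])
          Xi <- sc(Xtr[f$train, , drop = FALSE])
          Xo <- sc(Xtr[f$test, , drop = FALSE])
        } else {
          Xi <- Xtr[f$train, , drop = FALSE]
          Xo <- Xtr[f$test, , drop = FALSE]
        }
        m <- spec$fit(Xi, ytr[f$train], params, seed)
        pred[f$test] <- spec$predict(m, Xo)
      }
      mean(abs(ytr - pred))
    }, numeric(1))
    best <- which.min(maes)         # ties -> first in declared order
  } else {
    best <- 1L
  }
  params <- as.list(cand[best, , drop = FALSE])
  model <- spec$fit(XtrS, ytr, params, seed)
  list(pred = spec$predict(model, XteS), params = params)
}

# ---- nested LOGO evaluation -------------------------------------------------

#' Evaluate one regressor under nested leave-one-group-out CV
#'
#' Outer loop: each ligand in turn is the test set, never seen during
#' training. Inner loop: LOGO over the remaining (training) ligands selects
#' the hyperparameter grid point with minimal pooled inner MAE (ties go to
#' the first candidate in declared grid order); the model is refit on the
#' full outer-training set and predicts the held-out ligand. Out-of-fold
#' predictions pooled over all folds yield the reported R2 / MAE / rho.
#' Methods requiring hyperparameters need at least 3 distinct groups so the
#' inner loop has >= 2 groups.
#'
#' @param fm a [FeatureMatrix-class]
#' @param spec a `RegressorSpec` from [defaultRegistry()]
#' @param seed seed plumbed into stochastic fits (RF, GBM)
#' @return an [EvaluationReport-class]
#' @export
nestedLogoEvaluate <- function(fm, spec, seed = 0L) {
  stopifnot(is(fm, "FeatureMatrix"), inherits(spec, "RegressorSpec"))
  seed <- assertCount(seed, "seed", min = 0L)
  X <- featureX(fm); y <- featureY(fm); groups <- featureGroups(fm)
  folds <- logoSplits(groups)
  predictions <- data.frame(row = seq_along(y), ligand = groups,
                            y_true = y, y_pred = NA_real_,
                            fold = NA_integer_)
  chosen <- vector("list", length(folds))
  names(chosen) <- vapply(folds, `[[`, character(1), "group")
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    res <- fitPredictFold(X[f$train, , drop = FALSE], y[f$train],
                          groups[f$train], X[f$test, , drop = FALSE],
                          spec, seed)
    predictions$y_pred[f$test] <- res$pred
    predictions$fold[f$test] <- fi
    chosen[[fi]] <- res$params
  }
  makeEvaluationReport(fm@descriptorName, NA_integer_, spec$name,
                       predictions, chosen)
}

# ---- descriptor-level evaluation --------------------------------------------

#' Evaluate one descriptor configuration end to end
#'
#' Builds the `(kind, region, k)` descriptor table from the spectra,
#' assembles the feature matrix against the reaction table, and runs
#' [nestedLogoEvaluate()]. By default the wavenumber clustering is fitted
#' once on all ligands before modeling (descriptor generation precedes
#' regression in the workflow); `refitPerFold = TRUE` instead refits the
#' clustering inside each outer fold on the training ligands' spectra only,
#' for a fully leakage-free variant.
#'
#' @param spectra list of [IRSpectrum-class], one per ligand
#' @param table a reaction table (see [validateReactionTable()])
#' @param kind `"IntIR"` or `"WaveIR"`
#' @param region a [SpectralRegion-class]
#' @param k cluster count
#' @param spec a `RegressorSpec`
#' @param seed seed for clustering and stochastic fits
#' @param refitPerFold refit clustering inside each outer fold?
#' @return an [EvaluationReport-class]
#' @export
evaluateDescriptorConfig <- function(spectra, table, kind, region, k, spec,
                                     seed = 0L, refitPerFold = FALSE) {
  validateReactionTable(table)
  if (!refitPerFold) {
    desc <- buildDescriptorTable(spectra, kind, region, k, seed)
    rep_ <- nestedLogoEvaluate(assembleFeatureMatrix(table, desc), spec, seed)
    rep_@k <- as.integer(k)
    return(rep_)
  }
  ids <- vapply(spectra, compoundId, character(1))
  names(spectra) <- ids
  groups <- as.character(table$ligand_id)
  folds <- logoSplits(groups)
  y <- as.numeric(table$yield)
  predictions <- data.frame(row = seq_along(y), ligand = groups,
                            y_true = y, y_pred = NA_real_,
                            fold = NA_integer_)
  chosen <- vector("list", length(folds))
  names(chosen) <- vapply(folds, `[[`, character(1), "group")
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    trainIds <- setdiff(ids, f$group)
    model <- fitWavenumberClusters(spectra[trainIds], k, region, seed)
    desc <- buildDescriptorTable(spectra, kind, model = model)
    fm <- assembleFeatureMatrix(table, desc)
    X <- featureX(fm)
    res <- fitPredictFold(X[f$train, , drop = FALSE], y[f$train],
                          groups[f$train], X[f$test, , drop = FALSE],
                          spec, seed)
    predictions$y_pred[f$test] <- res$pred
    predictions$fold[f$test] <- fi
    chosen[[fi]] <- res$params
  }
  makeEvaluationReport(paste0(kind, regionTag(region)), k, spec$name,
                       predictions, chosen)
}

# ---- sweep and selection ----------------------------------------------------

#' Sweep descriptor configurations and select the best method
#'
#' Evaluates every combination of descriptor kind, spectral region, cluster
#' count and registry method under nested LOGO CV and tabulates pooled
#' R2 / MAE / rho, one summary row per combination (the layout of the
#' benchmark tables this mirrors: descriptor, cluster number, method,
#' metrics). The best configuration minimizes pooled MAE; ties break to
#' higher R2, then lower k, then registry order.
#'
#' @param spectra list of [IRSpectrum-class]
#' @param table a reaction table
#' @param kinds character subset of `c("IntIR", "WaveIR")`
#' @param regions list of [SpectralRegion-class] objects
#' @param kRange integer vector of cluster counts (descriptor sweeps use
#'   5-20)
#' @param registry named list of `RegressorSpec`s, see [defaultRegistry()]
#' @param seed seed for clustering and stochastic fits
#' @param refitPerFold refit clustering inside each outer fold?
#' @return list with `summary` (data.frame: descriptor, cluster_number,
#'   method, r2, mae, rho), `best` (the winning row), and `bestReport`
#'   (its [EvaluationReport-class])
#' @export
sweepAndSelect <- function(spectra, table,
                           kinds = c("IntIR", "WaveIR"),
                           regions = list(fullRegion(), fingerprintRegion()),
                           kRange = 5:20, registry = defaultRegistry(),
                           seed = 0L, refitPerFold = FALSE) {
  stopifnot(all(kinds %in% c("IntIR", "WaveIR")), length(registry) >= 1L)
  rows <- list(); reports <- list()
  for (region in regions) for (kind in kinds) for (k in kRange) {
    for (mi in seq_along(registry)) {
      spec <- registry[[mi]]
      rep_ <- evaluateDescriptorConfig(spectra, table, kind, region, k,
                                       spec, seed, refitPerFold)
      m <- pooledMetrics(rep_)
      rows[[length(rows) + 1L]] <- data.frame(
        descriptor = rep_@descriptorName, cluster_number = k,
        method = spec$name, method_order = mi,
        r2 = m$r2, mae = m$mae, rho = m$rho)
      reports[[length(rows)]] <- rep_
    }
  }
  summary <- do.call(rbind, rows)
  ord <- order(summary$mae, -summary$r2, summary$cluster_number,
               summary$method_order)
  bestIdx <- ord[1L]
  summary$method_order <- NULL
  rownames(summary) <- NULL
  list(summary = summary, best = summary[bestIdx, , drop = FALSE],
       bestReport = reports[[bestIdx]])
}

#' Write an evaluation summary / report to disk
#'
#' `writeEvaluationSummary()` writes the sweep summary CSV (columns
#' descriptor, cluster_number, method, r2, mae, rho);
#' `writeEvaluationReport()` writes one report as JSON (configuration,
#' pooled metrics, per-ligand metrics, out-of-fold predictions).
#'
#' @param summary the summary data.frame from [sweepAndSelect()]
#' @param report an [EvaluationReport-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeEvaluationSummary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEvaluationSummary
#' @export
writeEvaluationReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  obj <- list(descriptor = report@descriptorName, k = report@k,
              method = report@method, pooled = report@pooled,
              per_ligand = report@perLigand,
              predictions = report@predictions,
              chosen_params = report@chosenParams)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
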