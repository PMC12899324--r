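#' @include evaluation.R
NULL

#' Per-ligand deviation statistics
#'
#' For each ligand group in an evaluation report: the number of conditions,
#' the sample standard deviation of the actual yields (`std_g`, n-1
#' denominator; missing for singleton groups), the mean absolute error of
#' the out-of-fold predictions (`mae_g`), and Spearman's rho over that
#' ligand's rows (`rho_g`, missing when undefined). Greater spread in a
#' ligand's observed yields tends to accompany larger prediction error;
#' this table is the input to that correlation analysis.
#'
#' @param report an [EvaluationReport-class]
#' @return data.frame with columns `ligand`, `n`, `std_g`, `mae_g`, `rho_g`
#' @export
perGroupDeviationStats <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  if (anyNA(report@predictions$y_pred))
    stop("report lacks out-of-fold predictions for some rows", call. = FALSE)
  report@perLigand
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation between two vectors, with the two-sided
#' p-value from the t transform `t = r * sqrt((n - 2) / (1 - r^2))` on
#' n - 2 degrees of freedom (`method = "t"`), or from a seeded permutation
#' test (`method = "permutation"`, useful at small n).
#'
#' @param x,y numeric vectors, equal length n >= 3, neither constant
#' @param method `"t"` (exact t transform) or `"permutation"`
#' @param nPerm number of permutation resamples
#' @param seed permutation seed
#' @return list `list(r, p, n)`
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 2, 4))
#' @export
pearsonR <- function(x, y, method = c("t", "permutation"), nPerm = 9999L,
                     seed = 0L) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Pearson correlation undefined", call. = FALSE)
  r <- cor(x, y)
  p <- if (method == "t") {
    cor.test(x, y, method = "pearson", alternative = "two.sided")$p.value
  } else {
    withSeed(seed, {
      perm <- vapply(seq_len(nPerm), function(i) cor(x, sample(y)),
                     numeric(1))
      (1 + sum(abs(perm) >= abs(r) - 1e-12)) / (nPerm + 1)
    })
  }
  list(r = r, p = p, n = n)
}

#' Deviation-diagnostics summary for an evaluation report
#'
#' Computes the per-ligand deviation table and the two correlations of
#' interest: yield STD vs prediction MAE (positive when experimental
#' variability drives prediction error) and MAE vs Spearman rho (no sign is
#' expected a priori — large absolute error need not degrade ranking).
#' Ligands with missing entries are dropped pairwise.
#'
#' @param report an [EvaluationReport-class]
#' @param method p-value method, see [pearsonR()]
#' @return list with `perLigand` (the deviation table), `stdMae` and
#'   `maeRho` (each `list(r, p, n)`)
#' @export
diagnoseDeviations <- function(report, method = "t") {
  tab <- perGroupDeviationStats(report)
  list(perLigand = tab,
       stdMae = pearsonR(tab$std_g, tab$mae_g, method = method),
       maeRho = pearsonR(tab$mae_g, tab$rho_g, method = method))
}

#' Write deviation diagnostics to disk
#'
#' The per-ligand table goes to `<path>` as CSV (columns ligand, n, std,
#' mae, rho); the correlation summaries go to a JSON sidecar
#' `<path basename>_correlations.json` with entries `std_mae` and
#' `mae_rho`, each `{r, p, n}`.
#'
#' @param diagnostics result of [diagnoseDeviations()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeDiagnostics <- function(diagnostics, path) {
  tab <- diagnostics$perLigand
  write.csv(data.frame(ligand = tab$ligand, n = tab$n, std = tab$std_g,
                       mae = tab$mae_g, rho = tab$rho_g),
            path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(std_mae = diagnostics$stdMae,
                            mae_rho = diagnostics$maeRho),
                       sub("\\.csv$", "", path) |> paste0("_correlations.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
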