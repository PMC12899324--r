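#' @include clustering.R
NULL

# ---- DescriptorTable --------------------------------------------------------

#' Per-ligand IR descriptor table
#'
#' A fixed-length descriptor vector per compound, one coordinate per
#' wavenumber cluster, together with the fitted [ClusterModel-class].
#' Descriptor names follow the `<kind><region tag>` convention: `IntIR040`,
#' `IntIR017`, `WaveIR040`, `WaveIR017`, where `040`/`017` tag the 0-4000
#' and 0-1700 cm^-1 regions.
#'
#' @slot descriptorName e.g. `"WaveIR017"`
#' @slot kind `"IntIR"` or `"WaveIR"`
#' @slot k number of clusters (vector length)
#' @slot region the [SpectralRegion-class]
#' @slot values n_compounds x k numeric matrix, rownames = compound ids
#' @slot model the fitted [ClusterModel-class]
#'
#' @seealso [buildDescriptorTable()]
#' @exportClass DescriptorTable
setClass("DescriptorTable",
  representation(descriptorName = "character", kind = "character",
                 k = "integer", region = "SpectralRegion",
                 values = "matrix", model = "ClusterModel"))

setValidity("DescriptorTable", function(object) {
  if (!object@kind %in% c("IntIR", "WaveIR"))
    return("kind must be 'IntIR' or 'WaveIR'")
  if (!identical(object@descriptorName,
                 paste0(object@kind, regionTag(object@region))))
    return("descriptorName must be kind + region tag")
  if (ncol(object@values) != object@k)
    return("values must have k columns")
  if (is.null(rownames(object@values)) ||
      anyDuplicated(rownames(object@values)))
    return("values must have unique compound-id rownames")
  if (object@kind == "IntIR" &&
      (any(object@values < 0) || any(object@values > 100)))
    return("IntIR values must lie in [0, 100]")
  if (object@kind == "WaveIR" &&
      (any(object@values < object@region@lo) ||
       any(object@values > object@region@hi)))
    return("WaveIR values must lie within the region")
  TRUE
})

setMethod("show", "DescriptorTable", function(object) {
  cat(sprintf("DescriptorTable %s: %d compound(s) x %d cluster(s)\n",
              object@descriptorName, nrow(object@values), object@k))
})

#' DescriptorTable accessors
#' @param x a [DescriptorTable-class]
#' @return `descriptorName()` the name string; `descriptorValues()` the
#'   compounds x k matrix; `descriptorModel()` the fitted
#'   [ClusterModel-class]; `descriptorKind()` `"IntIR"` or `"WaveIR"`
#' @export
descriptorName <- function(x) { stopifnot(is(x, "DescriptorTable")); x@descriptorName }

#' @rdname descriptorName
#' @export
descriptorValues <- function(x) { stopifnot(is(x, "DescriptorTable")); x@values }

#' @rdname descriptorName
#' @export
descriptorModel <- function(x) { stopifnot(is(x, "DescriptorTable")); x@model }

#' @rdname descriptorName
#' @export
descriptorKind <- function(x) { stopifnot(is(x, "DescriptorTable")); x@kind }

# ---- Vector extraction ------------------------------------------------------

# Index of the representative peak per cluster: the highest-intensity peak,
# intensity ties broken toward the lower wavenumber. Returns NA for empty
# clusters.
representativePeak <- function(model, spectrum) {
  cl <- assignClusters(model, spectrum)
  int <- peakIntensities(spectrum)
  vapply(seq_len(nClusters(model)), function(j) {
    idx <- which(cl == j)
    if (!length(idx)) return(NA_integer_)
    # peaks are wavenumber-sorted, so which.max takes the lowest-wavenumber
    # peak among intensity ties
    idx[which.max(int[idx])]
  }, integer(1))
}

#' Intensity-based IR descriptor vector (IntIR)
#'
#' Coordinate i is the maximum normalized intensity among the peaks
#' assigned to cluster i; a cluster with no peak contributes 0. The
#' spectrum must be region-filtered and intensity-normalized (maximum 100)
#' so coordinates are comparable across compounds. An empty spectrum yields
#' the all-zero vector with a warning.
#'
#' @param spectrum a normalized, region-filtered [IRSpectrum-class]
#' @param model a [ClusterModel-class]
#' @return numeric vector of length `nClusters(model)`, values in `[0, 100]`
#' @export
intIrVector <- function(spectrum, model) {
  stopifnot(is(spectrum, "IRSpectrum"), is(model, "ClusterModel"))
  if (!nPeaks(spectrum)) {
    warning(sprintf("empty spectrum '%s': IntIR vector is all zeros",
                    compoundId(spectrum)), call. = FALSE)
    return(rep(0, nClusters(model)))
  }
  if (abs(max(peakIntensities(spectrum)) - 100) > 1e-8)
    stop("IntIR requires a normalized spectrum (max intensity 100); ",
         "call normalizeIntensities() first", call. = FALSE)
  rep_ <- representativePeak(model, spectrum)
  int <- peakIntensities(spectrum)
  ifelse(is.na(rep_), 0, int[ifelse(is.na(rep_), 1L, rep_)])
}

#' Wavenumber-based IR descriptor vector (WaveIR)
#'
#' Coordinate i is the wavenumber of the highest-intensity peak assigned to
#' cluster i (intensity ties go to the lower wavenumber); a cluster with no
#' peak contributes the minimum of that cluster's fitted wavenumber range.
#' The result is invariant to any positive rescaling of the intensities, so
#' normalization is optional.
#'
#' @param spectrum a region-filtered [IRSpectrum-class]
#' @param model a [ClusterModel-class]
#' @return numeric vector of length `nClusters(model)`, values in cm^-1
#' @export
waveIrVector <- function(spectrum, model) {
  stopifnot(is(spectrum, "IRSpectrum"), is(model, "ClusterModel"))
  fallback <- clusterRanges(model)[, 1L]
  if (!nPeaks(spectrum)) return(unname(fallback))
  rep_ <- representativePeak(model, spectrum)
  w <- peakWavenumbers(spectrum)
  unname(ifelse(is.na(rep_), fallback, w[ifelse(is.na(rep_), 1L, rep_)]))
}

# ---- Table assembly ---------------------------------------------------------

#' Build a named per-ligand descriptor table
#'
#' Runs the descriptor workflow for one `(kind, region, k)` configuration:
#' filter every spectrum to the region, fit the pooled wavenumber clustering
#' on the whole set, then extract one IntIR or WaveIR vector per compound
#' (IntIR spectra are normalized after filtering, so the in-region maximum
#' defines 100).
#'
#' @param spectra list of [IRSpectrum-class], one per ligand
#' @param kind `"IntIR"` or `"WaveIR"`
#' @param region a [SpectralRegion-class]
#' @param k number of wavenumber clusters (sweeps use 5-20)
#' @param seed RNG seed for the clustering restarts
#' @param model optionally, a pre-fitted [ClusterModel-class] to apply
#'   instead of fitting (used for fold-internal refitting workflows)
#' @return a [DescriptorTable-class]
#' @examples
#' sp <- list(irSpectrum("a", c(500, 700, 1100, 1500), c(1, 25, 100, 56)),
#'            irSpectrum("b", c(600, 1450, 1600), c(9, 2, 3)))
#' buildDescriptorTable(sp, "WaveIR", fingerprintRegion(), k = 2)
#' @export
buildDescriptorTable <- function(spectra, kind = c("IntIR", "WaveIR"),
                                 region = fingerprintRegion(), k = 10L,
                                 seed = 0L, model = NULL) {
  kind <- match.arg(kind)
  assertSpectrumList(spectra)
  if (length(spectra) < 2L)
    stop("need at least 2 spectra to build a descriptor table", call. = FALSE)
  ids <- vapply(spectra, compoundId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (is.null(model)) {
    model <- fitWavenumberClusters(spectra, k, region, seed)
  } else {
    stopifnot(is(model, "ClusterModel"))
    k <- nClusters(model)
    region <- clusterRegion(model)
  }
  filtered <- lapply(spectra, function(s)
    suppressWarnings(filterRegion(s, region)))
  rows <- lapply(filtered, function(s) {
    if (kind == "IntIR") {
      if (nPeaks(s)) s <- normalizeIntensities(s)
      suppressWarnings(intIrVector(s, model))
    } else {
      waveIrVector(s, model)
    }
  })
  values <- do.call(rbind, rows)
  rownames(values) <- ids
  name <- paste0(kind, regionTag(region))
  colnames(values) <- sprintf("%s_c%02d", name, seq_len(nClusters(model)))
  new("DescriptorTable", descriptorName = name, kind = kind,
      k = nClusters(model), region = region, values = values, model = model)
}

#' Write / read a descriptor table as CSV (+ cluster-model JSON sidecar)
#'
#' The CSV has a `compound_id` column followed by the k descriptor columns
#' `<name>_c01..c<k>`; the fitted [ClusterModel-class] is stored alongside
#' as `<path basename>_model.json` so the table can be re-applied to new
#' compounds.
#'
#' @param table a [DescriptorTable-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeDescriptorTable <- function(table, path) {
  stopifnot(is(table, "DescriptorTable"))
  df <- data.frame(compound_id = rownames(table@values),
                   table@values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  writeClusterModel(table@model, sidecarPath(path))
  invisible(path)
}

sidecarPath <- function(path) sub("\\.csv$", "", path) |> paste0("_model.json")
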