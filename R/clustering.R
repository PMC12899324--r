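#' @include spectra.R
NULL

# ---- ClusterModel -----------------------------------------------------------

#' Fitted 1-D wavenumber clustering
#'
#' The result of k-means on the pooled 1-D multiset of peak wavenumbers of a
#' ligand set. Clusters are relabeled in ascending center order; each
#' cluster records the range (minimum to maximum wavenumber) of the fitting
#' points assigned to it, which supplies the WaveIR empty-cluster fallback
#' value.
#'
#' @slot k number of clusters
#' @slot centers strictly ascending cluster centers, cm^-1
#' @slot ranges k x 2 matrix (`min`, `max`) of fitting-point extremes per
#'   cluster
#' @slot region the [SpectralRegion-class] the model was fitted on
#' @slot fitSSE within-cluster sum of squared deviations at convergence
#' @slot seed RNG seed used for the k-means++ restarts
#'
#' @seealso [fitWavenumberClusters()], [assignClusters()]
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(k = "integer", centers = "numeric", ranges = "matrix",
                 region = "SpectralRegion", fitSSE = "numeric",
                 seed = "integer"))

setValidity("ClusterModel", function(object) {
  k <- object@k
  if (length(object@centers) != k) return("centers length must equal k")
  if (k > 1L && is.unsorted(object@centers, strictly = TRUE))
    return("centers must be strictly ascending")
  if (!identical(dim(object@ranges), c(k, 2L))) return("ranges must be k x 2")
  if (any(object@ranges[, 1L] > object@ranges[, 2L]))
    return("each range must have min <= max")
  if (k > 1L && any(object@ranges[-1L, 1L] <= object@ranges[-k, 2L]))
    return("ranges must be non-overlapping and ordered")
  if (any(object@ranges[, 1L] < object@region@lo) ||
      any(object@ranges[, 2L] > object@region@hi))
    return("ranges must lie within the model region")
  if (length(object@fitSSE) != 1L || object@fitSSE < 0)
    return("fitSSE must be a single non-negative number")
  TRUE
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d on [%g, %g] cm-1 (seed %d), SSE = %g\n",
              object@k, object@region@lo, object@region@hi, object@seed,
              object@fitSSE))
  cat("  centers:", paste(signif(object@centers, 6), collapse = ", "), "\n")
})

#' ClusterModel accessors
#' @param x a [ClusterModel-class]
#' @return `clusterCenters()` ascending centers; `clusterRanges()` a k x 2
#'   matrix of fitting-point extremes; `nClusters()` k; `clusterSSE()` the
#'   within-cluster sum of squares; `clusterRegion()` the fitted region
#' @export
clusterCenters <- function(x) { stopifnot(is(x, "ClusterModel")); x@centers }

#' @rdname clusterCenters
#' @export
clusterRanges <- function(x) { stopifnot(is(x, "ClusterModel")); x@ranges }

#' @rdname clusterCenters
#' @export
nClusters <- function(x) { stopifnot(is(x, "ClusterModel")); x@k }

#' @rdname clusterCenters
#' @export
clusterSSE <- function(x) { stopifnot(is(x, "ClusterModel")); x@fitSSE }

#' @rdname clusterCenters
#' @export
clusterRegion <- function(x) { stopifnot(is(x, "ClusterModel")); x@region }

# ---- 1-D Lloyd k-means ------------------------------------------------------

# Nearest ascending center for each point; exact midpoint ties go to the
# lower-index (lower-wavenumber) center. With sorted centers this is a
# threshold rule on the midpoints, so assignment is O(n log k) and exact.
nearestCenter <- function(points, centers) {
  if (length(centers) == 1L) return(rep(1L, length(points)))
  mids <- (centers[-1L] + centers[-length(centers)]) / 2
  # points strictly greater than midpoint j belong to a cluster above j
  findInterval(points, mids, left.open = TRUE) + 1L
}

# k-means++ seeding on 1-D points; consumes the caller's RNG stream.
kppInit <- function(points, k) {
  centers <- numeric(k)
  centers[1L] <- points[sample.int(length(points), 1L)]
  d2 <- (points - centers[1L])^2
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j] <- points[sample.int(length(points), 1L)]
    } else {
      centers[j] <- points[sample.int(length(points), 1L, prob = d2)]
      d2 <- pmin(d2, (points - centers[j])^2)
    }
  }
  centers
}

# One Lloyd run from a given init. An empty cluster is repaired
# deterministically: its center is re-seeded at the point farthest from it
# (requires k <= number of distinct points, checked by the caller).
lloyd1d <- function(points, k, init, maxIter = 300L) {
  centers <- sort(init)
  assign <- rep(-1L, length(points))
  for (iter in seq_len(maxIter)) {
    newAssign <- nearestCenter(points, centers)
    repair <- 0L
    while (length(empty <- setdiff(seq_len(k), unique(newAssign))) &&
           (repair <- repair + 1L) <= k) {
      j <- empty[1L]
      centers[j] <- points[which.max(abs(points - centers[j]))]
      centers <- sort(centers)
      newAssign <- nearestCenter(points, centers)
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
    centers <- sort(vapply(seq_len(k),
                           function(j) mean(points[assign == j]), numeric(1)))
  }
  assign <- nearestCenter(points, centers)
  sse <- sum((points - centers[assign])^2)
  list(centers = centers, assign = assign, sse = sse)
}

#' Fit a shared wavenumber binning by pooled 1-D k-means
#'
#' Pools the in-region peak wavenumbers of all spectra into one 1-D multiset
#' (each peak one unweighted point; intensities play no role) and fits
#' k-means with k-means++ initialization, `restarts` restarts keeping the
#' best within-cluster sum of squares, and Lloyd iteration until assignments
#' stop changing (at most 300 iterations). Fitting is pooled so that the
#' resulting bins are shared across the whole ligand set — the descriptor
#' empty-cluster fallbacks are only meaningful for bins a given compound may
#' not populate. The fit is deterministic: the same spectra, `k`, `region`
#' and `seed` reproduce the model bit-identically, and the pooled multiset
#' (not the order of spectra) determines the result.
#'
#' @param spectra list of [IRSpectrum-class] (region filtering is applied
#'   internally)
#' @param k number of clusters; descriptor sweeps use 5-20
#' @param region a [SpectralRegion-class]
#' @param seed RNG seed for the k-means++ restarts (default 0)
#' @param restarts number of k-means++ restarts (default 10)
#' @return a [ClusterModel-class]
#' @examples
#' sp <- list(irSpectrum("a", c(500, 1100, 1500), c(1, 2, 3)),
#'            irSpectrum("b", c(700, 1450, 1600), c(1, 2, 3)))
#' fitWavenumberClusters(sp, k = 2, region = fingerprintRegion())
#' @export
fitWavenumberClusters <- function(spectra, k, region, seed = 0L,
                                  restarts = 10L) {
  assertSpectrumList(spectra)
  k <- assertCount(k, "k")
  stopifnot(is(region, "SpectralRegion"))
  seed <- assertCount(seed, "seed", min = 0L)
  points <- sort(unlist(lapply(spectra, function(s)
    suppressWarnings(peakWavenumbers(filterRegion(s, region)))),
    use.names = FALSE))
  if (!length(points))
    stop("no pooled peaks inside the region: clustering infeasible",
         call. = FALSE)
  if (length(points) < k)
    stop(sprintf("only %d pooled in-region peak(s) but k = %d: infeasible",
                 length(points), k), call. = FALSE)
  if (length(unique(points)) < k)
    stop(sprintf("only %d distinct pooled wavenumber(s) but k = %d: infeasible",
                 length(unique(points)), k), call. = FALSE)
  best <- withSeed(seed, {
    b <- NULL
    for (r in seq_len(restarts)) {
      fit <- lloyd1d(points, k, kppInit(points, k))
      if (is.null(b) || fit$sse < b$sse) b <- fit
    }
    b
  })
  ranges <- t(vapply(seq_len(k), function(j) {
    p <- points[best$assign == j]
    c(min(p), max(p))
  }, numeric(2)))
  colnames(ranges) <- c("min", "max")
  new("ClusterModel", k = k, centers = best$centers, ranges = ranges,
      region = region, fitSSE = best$sse, seed = seed)
}

#' Assign the peaks of a spectrum to fitted clusters
#'
#' Each peak goes to the cluster with the nearest center (1-D distance);
#' a peak exactly at the midpoint of two centers goes to the lower-index
#' (lower-wavenumber) cluster. Deterministic.
#'
#' @param model a [ClusterModel-class]
#' @param spectrum an [IRSpectrum-class], already filtered to the model
#'   region
#' @return integer vector of cluster indices (1-based), one per peak;
#'   length 0 for an empty spectrum
#' @export
assignClusters <- function(model, spectrum) {
  stopifnot(is(model, "ClusterModel"), is(spectrum, "IRSpectrum"))
  w <- peakWavenumbers(spectrum)
  if (!length(w)) return(integer())
  if (any(w < model@region@lo | w > model@region@hi))
    stop("spectrum has peaks outside the model region; apply filterRegion() first",
         call. = FALSE)
  nearestCenter(w, model@centers)
}

# ---- Exact DP oracle --------------------------------------------------------

#' Optimal 1-D clustering by dynamic programming
#'
#' The SSE-optimal k-clustering of points on a line is a contiguous
#' partition of the sorted points, so the global optimum is computable
#' exactly by dynamic programming over split positions (O(k n^2) with
#' prefix sums). This serves as an independent oracle for the Lloyd fit:
#' restarted Lloyd can never beat this SSE, and in 1-D it almost always
#' attains it.
#'
#' @param points numeric vector (sorted internally)
#' @param k number of clusters, `k <= length(points)`
#' @return a list with `blocks` (list of k sorted point vectors, ascending),
#'   `sizes`, and `sse` (the optimal within-cluster sum of squares)
#' @examples
#' optimal1dClusters(c(0, 2, 10, 12), 2)  # blocks {0,2},{10,12}, sse 4
#' @export
optimal1dClusters <- function(points, k) {
  x <- sort(as.numeric(points))
  n <- length(x)
  k <- assertCount(k, "k")
  if (n < k)
    stop(sprintf("%d point(s) cannot form %d clusters", n, k), call. = FALSE)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  blockCost <- function(i, j) {        # SSE of x[i..j]
    s <- cs[j + 1L] - cs[i]
    cs2[j + 1L] - cs2[i] - s^2 / (j - i + 1L)
  }
  # D[m, j]: best SSE of x[1..j] in m blocks; B[m, j]: start of last block
  D <- matrix(Inf, k, n); B <- matrix(NA_integer_, k, n)
  for (j in seq_len(n)) { D[1L, j] <- blockCost(1L, j); B[1L, j] <- 1L }
  if (k > 1L) for (m in 2L:k) for (j in m:n) {
    for (i in m:j) {
      cand <- D[m - 1L, i - 1L] + blockCost(i, j)
      if (cand < D[m, j]) { D[m, j] <- cand; B[m, j] <- i }
    }
  }
  blocks <- vector("list", k)
  j <- n
  for (m in k:1L) {
    i <- B[m, j]
    blocks[[m]] <- x[i:j]
    j <- i - 1L
  }
  list(blocks = blocks, sizes = lengths(blocks), sse = D[k, n])
}

# ---- JSON persistence -------------------------------------------------------

#' Serialize a ClusterModel to JSON
#'
#' Writes `{k, centers, ranges, region: {lo, hi, code}, seed, fit_sse}`;
#' `readClusterModel()` restores an identical model (numbers are written
#' at full precision).
#'
#' @param model a [ClusterModel-class]
#' @param path JSON file path
#' @return `path` (write) or the restored [ClusterModel-class] (read)
#' @export
writeClusterModel <- function(model, path) {
  stopifnot(is(model, "ClusterModel"))
  obj <- list(k = model@k, centers = model@centers,
              ranges = unname(apply(model@ranges, 1L, c, simplify = FALSE)),
              region = list(lo = model@region@lo, hi = model@region@hi,
                            code = model@region@code),
              seed = model@seed, fit_sse = model@fitSSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeClusterModel
#' @export
readClusterModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranges <- if (is.matrix(obj$ranges)) obj$ranges else
    matrix(unlist(obj$ranges), ncol = 2L, byrow = TRUE)
  colnames(ranges) <- c("min", "max")
  new("ClusterModel", k = as.integer(obj$k), centers = as.numeric(obj$centers),
      ranges = ranges,
      region = spectralRegion(obj$region$lo, obj$region$hi),
      fitSSE = as.numeric(obj$fit_sse), seed = as.integer(obj$seed))
}
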