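#' @include utils.R
NULL

# ---- SpectralRegion ---------------------------------------------------------

#' Wavenumber region of an IR spectrum
#'
#' A closed wavenumber interval `[lo, hi]` (cm^-1) with a two-digit code tag
#' used in descriptor names. The two canonical regions are the full harmonic
#' range 0-4000 cm^-1 (code `"40"`) and the fingerprint region 0-1700 cm^-1
#' (code `"17"`), giving descriptor names such as `"IntIR040"` and
#' `"WaveIR017"`.
#'
#' @slot lo lower bound, cm^-1 (inclusive)
#' @slot hi upper bound, cm^-1 (inclusive)
#' @slot code two-digit character tag, `hi`/100 zero-padded
#'
#' @seealso [fullRegion()], [fingerprintRegion()]
#' @exportClass SpectralRegion
setClass("SpectralRegion",
  representation(lo = "numeric", hi = "numeric", code = "character"))

setValidity("SpectralRegion", function(object) {
  if (length(object@lo) != 1L || length(object@hi) != 1L)
    return("lo and hi must be scalars")
  if (!is.finite(object@lo) || !is.finite(object@hi))
    return("lo and hi must be finite")
  if (object@lo < 0) return("lo must be >= 0")
  if (object@lo >= object@hi) return("lo must be < hi")
  if (!grepl("^[0-9]{2}$", object@code))
    return("code must be a two-digit string")
  TRUE
})

#' Construct a spectral region
#'
#' @param lo,hi closed interval bounds in cm^-1
#' @return a [SpectralRegion-class] object; the code tag is derived as
#'   `hi`/100, zero-padded to two digits (`"40"` for 0-4000, `"17"` for
#'   0-1700)
#' @examples
#' spectralRegion(0, 1700)
#' @export
spectralRegion <- function(lo, hi) {
  assertScalarNumber(lo, "lo")
  assertScalarNumber(hi, "hi")
  code <- sprintf("%02d", as.integer(round(hi / 100)))
  new("SpectralRegion", lo = as.numeric(lo), hi = as.numeric(hi), code = code)
}

#' Canonical spectral regions
#'
#' `fullRegion()` is the full harmonic range 0-4000 cm^-1 (tag `040`);
#' `fingerprintRegion()` is the fingerprint region 0-1700 cm^-1 (tag `017`),
#' rich in skeletal vibrational modes.
#'
#' @return a [SpectralRegion-class]
#' @export
fullRegion <- function() spectralRegion(0, 4000)

#' @rdname fullRegion
#' @export
fingerprintRegion <- function() spectralRegion(0, 1700)

#' @param region a [SpectralRegion-class]
#' @return `regionTag()`: the three-digit descriptor-name tag, e.g. `"017"`
#' @rdname fullRegion
#' @export
regionTag <- function(region) {
  stopifnot(is(region, "SpectralRegion"))
  paste0("0", region@code)
}

setMethod("show", "SpectralRegion", function(object) {
  cat(sprintf("SpectralRegion [%g, %g] cm-1 (tag %s)\n",
              object@lo, object@hi, regionTag(object)))
})

#' Region accessors
#' @param x a [SpectralRegion-class]
#' @return numeric bound (cm^-1) or code string
#' @export
regionLo <- function(x) { stopifnot(is(x, "SpectralRegion")); x@lo }

#' @rdname regionLo
#' @export
regionHi <- function(x) { stopifnot(is(x, "SpectralRegion")); x@hi }

# ---- IRSpectrum -------------------------------------------------------------

#' Discrete IR peak-list spectrum
#'
#' A compound's vibrational spectrum as a list of discrete peaks
#' (wavenumber in cm^-1, intensity in arbitrary absorption units), the form
#' produced by harmonic frequency calculations. Construction canonicalizes
#' the peak list: zero-intensity lines are dropped (a line with no
#' absorption is not a peak), duplicate wavenumbers are merged keeping the
#' maximum intensity, and peaks are sorted by ascending wavenumber.
#'
#' @slot compoundId single compound identifier
#' @slot wavenumber strictly increasing positive wavenumbers, cm^-1
#' @slot intensity positive intensities, parallel to `wavenumber`
#'
#' @seealso [irSpectrum()], [filterRegion()], [normalizeIntensities()]
#' @exportClass IRSpectrum
setClass("IRSpectrum",
  representation(compoundId = "character",
                 wavenumber = "numeric",
                 intensity  = "numeric"))

setValidity("IRSpectrum", function(object) {
  if (length(object@compoundId) != 1L || is.na(object@compoundId) ||
      !nzchar(object@compoundId))
    return("compoundId must be a single non-empty string")
  w <- object@wavenumber; i <- object@intensity
  if (length(w) != length(i)) return("wavenumber and intensity lengths differ")
  if (length(w)) {
    if (any(!is.finite(w)) || any(!is.finite(i)))
      return("wavenumbers and intensities must be finite")
    if (any(w <= 0)) return("all wavenumbers must be > 0")
    if (any(i <= 0)) return("all stored intensities must be > 0")
    if (is.unsorted(w, strictly = TRUE))
      return("wavenumbers must be strictly increasing")
  }
  TRUE
})

#' Construct an IR peak-list spectrum
#'
#' @param compoundId compound identifier (single string)
#' @param wavenumber peak positions in cm^-1; must be positive and finite
#' @param intensity peak intensities (arbitrary units); must be >= 0 and
#'   finite. Zero-intensity entries are dropped; duplicated wavenumbers are
#'   merged keeping the maximum intensity.
#' @return an [IRSpectrum-class] with peaks sorted by wavenumber
#' @examples
#' irSpectrum("L1", c(1500, 700, 700), c(5, 2, 9))
#' @export
irSpectrum <- function(compoundId, wavenumber = numeric(), intensity = numeric()) {
  w <- as.numeric(wavenumber); i <- as.numeric(intensity)
  if (length(w) != length(i))
    stop("wavenumber and intensity must have the same length", call. = FALSE)
  if (any(!is.finite(w)) || any(!is.finite(i)))
    stop("wavenumbers and intensities must be finite (no NA/NaN/Inf)",
         call. = FALSE)
  if (any(w <= 0)) stop("all wavenumbers must be > 0", call. = FALSE)
  if (any(i < 0)) stop("all intensities must be >= 0", call. = FALSE)
  keep <- i > 0
  w <- w[keep]; i <- i[keep]
  if (anyDuplicated(w)) {
    i <- vapply(split(i, w), max, numeric(1))
    w <- as.numeric(names(i))       # split() sorts by the numeric key
    names(i) <- NULL
  }
  o <- order(w)
  new("IRSpectrum", compoundId = as.character(compoundId),
      wavenumber = w[o], intensity = i[o])
}

#' IRSpectrum accessors
#'
#' @param x an [IRSpectrum-class]
#' @return `compoundId()` the identifier; `peakWavenumbers()` /
#'   `peakIntensities()` numeric vectors; `nPeaks()` peak count;
#'   `peakTable()` a two-column data.frame
#' @export
compoundId <- function(x) { stopifnot(is(x, "IRSpectrum")); x@compoundId }

#' @rdname compoundId
#' @export
peakWavenumbers <- function(x) { stopifnot(is(x, "IRSpectrum")); x@wavenumber }

#' @rdname compoundId
#' @export
peakIntensities <- function(x) { stopifnot(is(x, "IRSpectrum")); x@intensity }

#' @rdname compoundId
#' @export
nPeaks <- function(x) { stopifnot(is(x, "IRSpectrum")); length(x@wavenumber) }

#' @rdname compoundId
#' @export
peakTable <- function(x) {
  stopifnot(is(x, "IRSpectrum"))
  data.frame(wavenumber_cm1 = x@wavenumber, intensity = x@intensity)
}

setMethod("show", "IRSpectrum", function(object) {
  n <- length(object@wavenumber)
  cat(sprintf("IRSpectrum '%s': %d peak%s", object@compoundId, n,
              if (n == 1L) "" else "s"))
  if (n)
    cat(sprintf(" in [%g, %g] cm-1, max intensity %g",
                min(object@wavenumber), max(object@wavenumber),
                max(object@intensity)))
  cat("\n")
})

assertSpectrumList <- function(spectra) {
  if (!is.list(spectra) || !length(spectra) ||
      !all(vapply(spectra, is, logical(1), "IRSpectrum")))
    stop("expected a non-empty list of IRSpectrum objects", call. = FALSE)
  invisible(spectra)
}

# ---- Frequency-job parsing --------------------------------------------------

#' Read a harmonic-frequency job log into an IR spectrum
#'
#' Parses the harmonic vibrational analysis block of a quantum-chemistry
#' frequency job (the standard three-modes-per-line layout in which
#' `Frequencies --` rows are paired with `IR Inten --` rows) and returns the
#' line spectrum: one peak per mode with positive IR intensity.
#'
#' Imaginary modes (negative frequencies) indicate a non-minimum structure
#' and are rejected with an error naming the offending mode; zero-intensity
#' modes are silently dropped by spectrum construction.
#'
#' @param input path to a log file, or a character vector of its lines
#' @param compoundId identifier to attach to the spectrum
#' @return an [IRSpectrum-class]
#' @export
readGaussianFrequencies <- function(input, compoundId) {
  lines <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    readLines(input, warn = FALSE) else as.character(input)
  grabNumbers <- function(pattern) {
    hits <- grep(pattern, lines, value = TRUE)
    unlist(lapply(hits, function(l) {
      txt <- sub(pattern, "", l)
      as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
    }), use.names = FALSE)
  }
  freq <- grabNumbers("^\\s*Frequencies\\s+--\\s*")
  inten <- grabNumbers("^\\s*IR Inten\\s+--\\s*")
  if (!length(freq))
    stop("no harmonic frequency block found in input", call. = FALSE)
  if (any(is.na(freq)) || any(is.na(inten)))
    stop("malformed numeric field in frequency block", call. = FALSE)
  if (length(freq) != length(inten))
    stop(sprintf(paste0("frequency/intensity count mismatch: %d frequencies ",
                        "but %d IR intensities"),
                 length(freq), length(inten)), call. = FALSE)
  if (any(freq < 0)) {
    bad <- which(freq < 0)[1L]
    stop(sprintf("imaginary mode %d (frequency %g cm-1): not a minimum-energy structure",
                 bad, freq[bad]), call. = FALSE)
  }
  if (any(freq == 0))
    stop("zero-frequency mode present in frequency block", call. = FALSE)
  irSpectrum(compoundId, freq, inten)
}

# ---- Canonical peak CSV -----------------------------------------------------

peaksCsvColumns <- c("compound_id", "wavenumber_cm1", "intensity")

#' Read and write the canonical peak-list CSV
#'
#' The canonical exchange format is a UTF-8 CSV with header
#' `compound_id,wavenumber_cm1,intensity` and one row per peak.
#' `writePeaksCsv()` followed by `readPeaksCsv()` reproduces the spectra
#' exactly (numbers are written with 17 significant digits). Compounds are
#' returned in order of first appearance in the file.
#'
#' @param path CSV file path
#' @return `readPeaksCsv()`: a named list of [IRSpectrum-class] objects
#' @export
readPeaksCsv <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(peaksCsvColumns, names(df))
  if (length(missing))
    stop("peak CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) return(setNames(list(), character()))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) || anyNA(df[[col]]))
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, c(bad, which(is.na(df[[col]])))[1L]), call. = FALSE)
    v
  }
  w <- num("wavenumber_cm1"); i <- num("intensity")
  ids <- unique(df$compound_id)
  out <- lapply(ids, function(id) {
    sel <- df$compound_id == id
    irSpectrum(id, w[sel], i[sel])
  })
  setNames(out, ids)
}

#' @param spectra a list of [IRSpectrum-class] objects
#' @rdname readPeaksCsv
#' @return `writePeaksCsv()`: `path`, invisibly
#' @export
writePeaksCsv <- function(spectra, path) {
  assertSpectrumList(spectra)
  rows <- lapply(spectra, function(s)
    data.frame(compound_id = compoundId(s),
               wavenumber_cm1 = sprintf("%.17g", s@wavenumber),
               intensity = sprintf("%.17g", s@intensity)))
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(compound_id = character(), wavenumber_cm1 = character(),
                     intensity = character())
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Region filtering and normalization -------------------------------------

#' Restrict a spectrum to a wavenumber region
#'
#' Keeps exactly the peaks with `lo <= wavenumber <= hi` (closed interval:
#' a peak sitting on a region bound is kept). An all-peaks-filtered result
#' is permitted — downstream descriptor fallbacks handle the empty case —
#' but raises a warning.
#'
#' @param spectrum an [IRSpectrum-class]
#' @param region a [SpectralRegion-class]
#' @return the filtered [IRSpectrum-class]
#' @export
filterRegion <- function(spectrum, region) {
  stopifnot(is(spectrum, "IRSpectrum"), is(region, "SpectralRegion"))
  keep <- spectrum@wavenumber >= region@lo & spectrum@wavenumber <= region@hi
  out <- new("IRSpectrum", compoundId = spectrum@compoundId,
             wavenumber = spectrum@wavenumber[keep],
             intensity = spectrum@intensity[keep])
  if (!length(out@wavenumber) && length(spectrum@wavenumber))
    warning(sprintf("spectrum '%s' has no peaks in [%g, %g] cm-1",
                    spectrum@compoundId, region@lo, region@hi), call. = FALSE)
  out
}

#' Normalize peak intensities to a 0-100 scale
#'
#' Rescales intensities per spectrum so that the maximum equals 100,
#' preserving relative ratios; wavenumbers are untouched. Normalization is
#' per spectrum (not per dataset): absolute IR intensities are not
#' comparable across samples, so only within-spectrum ratios are retained.
#' Apply after [filterRegion()] so the in-region maximum defines 100.
#'
#' @param spectrum an [IRSpectrum-class] with at least one peak
#' @return the normalized [IRSpectrum-class] (max intensity exactly 100)
#' @export
normalizeIntensities <- function(spectrum) {
  stopifnot(is(spectrum, "IRSpectrum"))
  if (!length(spectrum@wavenumber))
    stop(sprintf("cannot normalize empty spectrum '%s'", spectrum@compoundId),
         call. = FALSE)
  new("IRSpectrum", compoundId = spectrum@compoundId,
      wavenumber = spectrum@wavenumber,
      # divide first: the maximal element becomes exactly 1, hence exactly 100
      intensity = (spectrum@intensity / max(spectrum@intensity)) * 100)
}
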