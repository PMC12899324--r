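#' @include diagnostics.R
NULL

#' Default synthetic band layout
#'
#' Eight vibrational band families: six in the fingerprint region
#' (0-1700 cm^-1) and two in the functional-group region, so region
#' filtering is exercised. Each family has a center (cm^-1) and a shift
#' coefficient (cm^-1 per unit of the latent ligand parameter theta);
#' family spacing comfortably exceeds the theta-induced spread so bands do
#' not cross.
#'
#' @return data.frame with columns `center` and `shift`
#' @export
defaultBandFamilies <- function() {
  data.frame(center = c(450, 700, 950, 1200, 1450, 1630, 2250, 2980),
             shift  = c(35, -30, 40, -35, 30, 25, 20, 15))
}

#' Generate synthetic peak-list spectra with a latent ligand parameter
#'
#' Emulates a ligand series whose band positions encode a single latent
#' electronic parameter theta, equally spaced in [-1, 1] across the
#' ligands (so a held-out ligand interpolates rather than extrapolates).
#' Ligand i receives one peak per band family at
#' `center_f + shift_f * theta_i + jitter`, with jitter ~ Normal(0,
#' `jitterSd`) and intensities drawn log-normal — intensities carry no
#' theta information, mirroring the instability of computed IR intensities
#' relative to band positions. Deterministic per seed.
#'
#' @param nLigands number of ligands (>= 3); ids `L01`, `L02`, ...
#' @param bandFamilies data.frame with `center` (cm^-1, within 0-4000) and
#'   `shift` (cm^-1 per unit theta); default [defaultBandFamilies()]
#' @param jitterSd per-peak positional noise SD, cm^-1 (default 2)
#' @param intensityMeanlog,intensitySdlog log-normal intensity parameters
#' @param seed RNG seed
#' @return list with `spectra` (named list of [IRSpectrum-class]) and
#'   `theta` (named numeric vector)
#' @examples
#' gen <- generateSpectra(12, seed = 1)
#' nPeaks(gen$spectra[["L01"]])  # 8
#' @export
generateSpectra <- function(nLigands = 12L, bandFamilies = defaultBandFamilies(),
                            jitterSd = 2, intensityMeanlog = log(50),
                            intensitySdlog = 0.7, seed = 0L) {
  nLigands <- assertCount(nLigands, "nLigands", min = 3L)
  stopifnot(is.data.frame(bandFamilies),
            all(c("center", "shift") %in% names(bandFamilies)))
  if (nrow(bandFamilies) < 2L)
    stop("need at least 2 band families", call. = FALSE)
  if (any(bandFamilies$center <= 0 | bandFamilies$center > 4000))
    stop("band family centers must lie inside (0, 4000] cm-1", call. = FALSE)
  if (sum(bandFamilies$center <= 1700) < 2L)
    stop("need at least 2 band families inside the fingerprint region",
         call. = FALSE)
  theta <- seq(-1, 1, length.out = nLigands)
  ids <- sprintf("L%02d", seq_len(nLigands))
  names(theta) <- ids
  spectra <- withSeed(seed, {
    lapply(seq_len(nLigands), function(i) {
      w <- bandFamilies$center + bandFamilies$shift * theta[i] +
        rnorm(nrow(bandFamilies), 0, jitterSd)
      int <- rlnorm(nrow(bandFamilies), intensityMeanlog, intensitySdlog)
      irSpectrum(ids[i], w, int)
    })
  })
  list(spectra = setNames(spectra, ids), theta = theta)
}

#' Generate a synthetic full-factorial reaction table with known truth
#'
#' Enumerates the full factorial of ligands x bases x solvents
#' (x concentrations x temperatures when given) and draws yields from the
#' additive ground-truth surface
#' `yield = clip(mu0 + a * theta + baseEffect + solventEffect +
#' tempSlope * (T - Tref) + eps, 0, 100)` with
#' `eps ~ Normal(0, noiseSd)`. `ligandNoiseSd` switches on heteroscedastic
#' per-ligand noise (a named vector overriding `noiseSd`), the regime used
#' to study the yield-variability vs prediction-error relationship.
#' Deterministic per seed; the ground truth travels with the table.
#'
#' @param theta named numeric vector of latent ligand parameters (names =
#'   ligand ids), e.g. from [generateSpectra()]
#' @param baseEffects,solventEffects named numeric vectors of additive
#'   yield effects (percent); names become the base / solvent ids
#' @param tempsC temperature levels in Celsius, or `NULL` for no
#'   temperature factor
#' @param concentrations concentration levels (mol/L), or `NULL`
#' @param mu0 intercept yield (percent)
#' @param a yield response to theta (percent per unit theta)
#' @param tempSlope yield response to temperature (percent per Kelvin),
#'   about the mean temperature
#' @param noiseSd homoscedastic noise SD (percent)
#' @param ligandNoiseSd optional named per-ligand noise SDs (percent)
#' @param seed RNG seed
#' @return list with `table` (a reaction table, see
#'   [validateReactionTable()]) and `truth` (all generator parameters)
#' @examples
#' gen <- generateSpectra(12, seed = 1)
#' rt <- generateReactionTable(gen$theta, seed = 1)
#' nrow(rt$table)  # 12 * 4 * 4 * 3 * 3 = 1728
#' @export
generateReactionTable <- function(theta,
                                  baseEffects = c(B1 = -9, B2 = -3,
                                                  B3 = 3, B4 = 9),
                                  solventEffects = c(S1 = -6, S2 = -2,
                                                     S3 = 2, S4 = 6),
                                  tempsC = c(60, 90, 120),
                                  concentrations = c(0.05, 0.10, 0.15),
                                  mu0 = 50, a = 30, tempSlope = 0.05,
                                  noiseSd = 5, ligandNoiseSd = NULL,
                                  seed = 0L) {
  if (is.null(names(theta)) || anyDuplicated(names(theta)))
    stop("theta must be named by unique ligand ids", call. = FALSE)
  stopifnot(!is.null(names(baseEffects)), !is.null(names(solventEffects)))
  levels <- list(ligand_id = names(theta), base_id = names(baseEffects),
                 solvent_id = names(solventEffects))
  if (!is.null(concentrations)) levels$concentration <- concentrations
  if (!is.null(tempsC)) levels$temperature_k <- celsiusToKelvin(tempsC)
  grid <- enumerateFullFactorial(levels)
  tRef <- if (is.null(tempsC)) NULL else mean(celsiusToKelvin(tempsC))
  sdRow <- if (is.null(ligandNoiseSd)) rep(noiseSd, nrow(grid)) else {
    missing <- setdiff(names(theta), names(ligandNoiseSd))
    if (length(missing))
      stop("ligandNoiseSd missing ligand(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    unname(ligandNoiseSd[grid$ligand_id])
  }
  mean_ <- mu0 + a * unname(theta[grid$ligand_id]) +
    unname(baseEffects[grid$base_id]) +
    unname(solventEffects[grid$solvent_id]) +
    if (is.null(tempsC)) 0 else tempSlope * (grid$temperature_k - tRef)
  eps <- withSeed(seed, rnorm(nrow(grid), 0, sdRow))
  grid$yield <- pmin(100, pmax(0, mean_ + eps))
  validateReactionTable(grid)
  list(table = grid,
       truth = list(theta = theta, baseEffects = baseEffects,
                    solventEffects = solventEffects, tempsC = tempsC,
                    concentrations = concentrations, mu0 = mu0, a = a,
                    tempSlope = tempSlope, noiseSd = noiseSd,
                    ligandNoiseSd = ligandNoiseSd, tRefK = tRef,
                    seed = seed))
}
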