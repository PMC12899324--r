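#' @include descriptors.R
NULL

# A reaction table is a plain data.frame with columns ligand_id, base_id,
# solvent_id, optional concentration (mol/L) and temperature_k (Kelvin),
# and yield (percent). validateReactionTable() enforces the contract.

reactionRequired <- c("ligand_id", "base_id", "solvent_id", "yield")

#' Validate a reaction table
#'
#' A reaction table records one screened condition per row: categorical
#' ligand / base / solvent identifiers, optional numeric concentration
#' (mol/L, > 0) and temperature (Kelvin, > 0), and the observed yield in
#' percent (0-100).
#'
#' @param table a data.frame with columns `ligand_id`, `base_id`,
#'   `solvent_id`, optional `concentration` and `temperature_k`, and `yield`
#' @return the table, invisibly, or an error describing the violation
#' @export
validateReactionTable <- function(table) {
  if (!is.data.frame(table)) stop("reaction table must be a data.frame",
                                  call. = FALSE)
  missing <- setdiff(reactionRequired, names(table))
  if (length(missing))
    stop("reaction table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  y <- table$yield
  if (!is.numeric(y) || anyNA(y) || any(y < 0) || any(y > 100))
    stop("yield must be numeric in [0, 100] with no missing values",
         call. = FALSE)
  if (!is.null(table$temperature_k) &&
      (anyNA(table$temperature_k) || any(table$temperature_k <= 0)))
    stop("temperature_k must be > 0 K", call. = FALSE)
  if (!is.null(table$concentration) &&
      (anyNA(table$concentration) || any(table$concentration <= 0)))
    stop("concentration must be > 0", call. = FALSE)
  invisible(table)
}

#' Enumerate a full-factorial condition space
#'
#' Cartesian product of the given factor levels in deterministic
#' lexicographic order: the first factor varies slowest and the last
#' fastest, with levels in the order supplied. The screened HTE spaces this
#' emulates are e.g. 12 ligands x 4 bases x 4 solvents x 3 concentrations x
#' 3 temperatures = 1,728 conditions, or 8 x 8 x 4 = 256.
#'
#' @param factorLevels named list, factor name -> vector of levels (each
#'   non-empty)
#' @return a data.frame with one column per factor and one row per
#'   combination (`prod(lengths(factorLevels))` rows)
#' @examples
#' nrow(enumerateFullFactorial(list(ligand_id = letters[1:12],
#'   base_id = 1:4, solvent_id = 1:4, concentration = 1:3,
#'   temperature_k = 1:3)))  # 1728
#' @export
enumerateFullFactorial <- function(factorLevels) {
  if (!is.list(factorLevels) || !length(factorLevels) ||
      is.null(names(factorLevels)) || any(!nzchar(names(factorLevels))))
    stop("factorLevels must be a named list", call. = FALSE)
  if (any(lengths(factorLevels) == 0L))
    stop("every factor must have at least one level", call. = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic
  # order in which the first factor varies slowest
  grid <- do.call(expand.grid,
                  c(rev(factorLevels),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_along(factorLevels)), drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Exclude zero-yield entries
#'
#' Removes the rows whose recorded yield is exactly 0%. Zero-yield entries
#' lump fundamentally different failure modes under one label and distort
#' regression toward classification, so they are excluded before modeling
#' (in the arylation-style workflow; the step is a pipeline flag, not
#' hard-wired). Row order is preserved; the removed count is reported via
#' `message()`.
#'
#' @param table a reaction table (see [validateReactionTable()])
#' @return the filtered table
#' @export
excludeZeroYield <- function(table) {
  validateReactionTable(table)
  zero <- table$yield == 0
  message(sprintf("excluded %d zero-yield row(s); %d retained",
                  sum(zero), sum(!zero)))
  if (all(zero)) warning("all rows had zero yield: empty table returned",
                         call. = FALSE)
  out <- table[!zero, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert Celsius to Kelvin
#'
#' @param tCelsius temperature(s) in degrees Celsius, each >= -273.15
#' @return temperature(s) in Kelvin (`tCelsius + 273.15`)
#' @export
celsiusToKelvin <- function(tCelsius) {
  if (!is.numeric(tCelsius) || anyNA(tCelsius))
    stop("temperature must be numeric and non-missing", call. = FALSE)
  if (any(tCelsius < -273.15))
    stop("temperature below absolute zero (-273.15 C)", call. = FALSE)
  tCelsius + 273.15
}

# ---- FeatureMatrix ----------------------------------------------------------

#' Model-ready reaction feature matrix
#'
#' Rows are reaction conditions; columns are ordered
#' `[descriptor block | base one-hot | solvent one-hot | concentration |
#' temperature]`. Ligands are encoded by their IR descriptor vector; bases
#' and solvents by one-hot indicators; concentration and temperature enter
#' as raw numeric columns (any scaling is the model's preprocessing).
#' `groups` carries the ligand id of each row for group-aware
#' cross-validation.
#'
#' @slot X numeric matrix, n_rows x p
#' @slot y yields (percent), length n_rows
#' @slot groups ligand id per row
#' @slot descriptorName name of the ligand descriptor used
#'
#' @seealso [assembleFeatureMatrix()]
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(X = "matrix", y = "numeric", groups = "character",
                 descriptorName = "character"))

setValidity("FeatureMatrix", function(object) {
  n <- nrow(object@X)
  if (length(object@y) != n || length(object@groups) != n)
    return("X, y and groups must agree in length")
  if (is.null(colnames(object@X))) return("X must have column names")
  TRUE
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d rows x %d features (%s), %d ligand group(s)\n",
              nrow(object@X), ncol(object@X), object@descriptorName,
              length(unique(object@groups))))
})

#' FeatureMatrix accessors
#' @param x a [FeatureMatrix-class]
#' @return `featureX()` the design matrix; `featureY()` the yields;
#'   `featureGroups()` the per-row ligand ids
#' @export
featureX <- function(x) { stopifnot(is(x, "FeatureMatrix")); x@X }

#' @rdname featureX
#' @export
featureY <- function(x) { stopifnot(is(x, "FeatureMatrix")); x@y }

#' @rdname featureX
#' @export
featureGroups <- function(x) { stopifnot(is(x, "FeatureMatrix")); x@groups }

oneHot <- function(values, prefix) {
  levels <- sort(unique(values))
  m <- outer(values, levels, `==`) * 1
  colnames(m) <- paste0(prefix, "_", levels)
  m
}

#' Assemble the reaction feature matrix
#'
#' Joins the ligand descriptor vectors onto the reaction table and encodes
#' the conditions: descriptor block first, then base and solvent one-hot
#' blocks (vocabularies = sorted unique values in the table; each block
#' sums to 1 per row), then raw numeric `concentration` and
#' `temperature_k` columns when present. Permuting table rows permutes the
#' matrix rows identically.
#'
#' @param table a reaction table (see [validateReactionTable()])
#' @param descriptors a [DescriptorTable-class] covering every ligand in
#'   `table`
#' @return a [FeatureMatrix-class]
#' @export
assembleFeatureMatrix <- function(table, descriptors) {
  validateReactionTable(table)
  stopifnot(is(descriptors, "DescriptorTable"))
  vals <- descriptorValues(descriptors)
  unknown <- setdiff(unique(table$ligand_id), rownames(vals))
  if (length(unknown))
    stop("ligand(s) missing from the descriptor table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ligand <- as.character(table$ligand_id)
  blocks <- list(vals[ligand, , drop = FALSE],
                 oneHot(as.character(table$base_id), "base"),
                 oneHot(as.character(table$solvent_id), "solvent"))
  if (!is.null(table$concentration))
    blocks <- c(blocks, list(matrix(table$concentration,
                                    dimnames = list(NULL, "concentration"))))
  if (!is.null(table$temperature_k))
    blocks <- c(blocks, list(matrix(table$temperature_k,
                                    dimnames = list(NULL, "temperature_k"))))
  X <- do.call(cbind, blocks)
  rownames(X) <- NULL
  new("FeatureMatrix", X = X, y = as.numeric(table$yield), groups = ligand,
      descriptorName = descriptorName(descriptors))
}

#' Read / write the reaction CSV
#'
#' Exchange format: header
#' `ligand_id,base_id,solvent_id,concentration,temperature_c,yield`, with
#' temperature in Celsius (converted to Kelvin on load); `concentration`
#' and `temperature_c` columns are optional.
#'
#' @param path CSV file path
#' @return `readReactionCsv()`: a validated reaction table with
#'   `temperature_k` in Kelvin
#' @export
readReactionCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("ligand_id", "base_id", "solvent_id", "yield"),
                     names(df))
  if (length(missing))
    stop("reaction CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(df$temperature_c)) {
    df$temperature_k <- celsiusToKelvin(df$temperature_c)
    df$temperature_c <- NULL
  }
  validateReactionTable(df)
  df
}

#' @param table a reaction table with `temperature_k` in Kelvin
#' @rdname readReactionCsv
#' @return `writeReactionCsv()`: `path`, invisibly
#' @export
writeReactionCsv <- function(table, path) {
  validateReactionTable(table)
  out <- table
  if (!is.null(out$temperature_k)) {
    out$temperature_c <- out$temperature_k - 273.15
    out$temperature_k <- NULL
  }
  front <- intersect(c("ligand_id", "base_id", "solvent_id", "concentration",
                       "temperature_c", "yield"), names(out))
  write.csv(out[, c(front, setdiff(names(out), front)), drop = FALSE],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
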