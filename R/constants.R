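#' @keywords internal
"_PACKAGE"

## Monoisotopic element masses (CODATA/IUPAC), Da.
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

PROTON_MASS <- 1.00727646677
WATER_MASS <- 2 * .ELEMENT_MASS[["H"]] + .ELEMENT_MASS[["O"]]
NH3_MASS <- .ELEMENT_MASS[["N"]] + 3 * .ELEMENT_MASS[["H"]]

#' Monoisotopic mass of an elemental composition
#'
#' @param counts named numeric vector, element symbol -> atom count.
#' @return mass in Da.
#' @keywords internal
elemental_mass <- function(counts) {
  stopifnot(all(names(counts) %in% names(.ELEMENT_MASS)))
  sum(.ELEMENT_MASS[names(counts)] * counts)
}

## Relative (fractional) mass error of an observed vs theoretical mass.
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical
}

## Evaluate expr with a temporary RNG state seeded from `seed`, restoring
## the caller's stream afterwards.  All stochastic internals go through this
## so that user-level seeds compose predictably.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

## Deterministic small-integer hash of a character key, for per-object seeds.
key_seed <- function(key, base_seed = 0L) {
  bytes <- utf8ToInt(key)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

## For each target mass, indices of peaks within tol*target (relative
## tolerance); returns index of closest such peak or NA.  `masses` sorted.
match_mass <- function(masses, target, tol) {
  if (length(masses) == 0L) return(NA_integer_)
  lo <- findInterval(target * (1 - tol), masses) + 1L
  hi <- findInterval(target * (1 + tol), masses)
  if (hi < lo) return(NA_integer_)
  idx <- lo:hi
  idx[which.min(abs(masses[idx] - target))]
}

safe_log10 <- function(x) log10(pmax(x, .Machine$double.eps))

## Pearson correlation defined as 0 on degenerate input (< 3 points or a
## zero-variance vector): the neutral value under the shifted-(rho+1) terms.
safe_cor <- function(x, y, method = "pearson") {
  if (length(x) < 3L || length(y) < 3L) return(0)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  v <- suppressWarnings(stats::cor(x, y, method = method))
  if (!is.finite(v)) 0 else v
}
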