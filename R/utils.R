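## Internal helpers: classed conditions, seeded evaluation, axis conversion.

#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats approx loess loess.control predict quantile sd setNames
#' @importFrom utils read.table write.table head tail
NULL

## Classed error, so callers can distinguish parse errors from fit failures etc.
bsError <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "bathyspec_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

bsWarning <- function(class, message) {
  warning(structure(
    class = c(class, "bathyspec_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

## Evaluate expr under a fixed RNG state without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    bsError("bs_parameter_error", "a single finite seed is required")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Convert wavelength (nm) to wavenumber (cm^-1)
#'
#' @param nm wavelengths in nanometres (all > 0).
#' @return wavenumbers in cm^-1 (`1e7 / nm`).
#' @export
nmToWavenumber <- function(nm) {
  if (any(!is.finite(nm)) || any(nm <= 0))
    bsError("bs_domain_error", "wavelengths must be finite and positive")
  1e7 / nm
}

#' Convert wavenumber (cm^-1) to wavelength (nm)
#'
#' @param cm1 wavenumbers in cm^-1 (all > 0).
#' @return wavelengths in nanometres.
#' @export
wavenumberToNm <- function(cm1) {
  if (any(!is.finite(cm1)) || any(cm1 <= 0))
    bsError("bs_domain_error", "wavenumbers must be finite and positive")
  1e7 / cm1
}

## Round half away from zero (table rendering convention; rows sum to 100).
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

## Cosine similarity of two vectors.
cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
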