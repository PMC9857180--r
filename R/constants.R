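#' Physical constants and unit helpers
#'
#' `vacuumPermeability()` returns mu0 = 4*pi*1e-7 N/A^2, the single point
#' where the reduced-unit field solutions are tied to SI forces (Br = mu0*M).
#'
#' @return `vacuumPermeability()`: mu0 in N/A^2 (equivalently T*m/A).
#' @examples
#' vacuumPermeability() * 795774.7  # ~1 T remanence for M ~ 796 kA/m
#' @export
vacuumPermeability <- function() 4e-7 * pi

.MU0 <- 4e-7 * pi

## canonical culture-condition labels, in the order used throughout
.CONDITIONS <- c("ST", "ST+Fe", "ST+MF", "ST+MF+Fe")

## classed conditions: validation failures (CLI exit 2) vs singular field
## evaluations such as stripe corners or x = 0 in the seam asymptote (exit 3)
.stopValidation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("mgValidationError", "error", "condition")))
}

.stopSingular <- function(msg) {
  stop(errorCondition(msg, class = c("mgSingularError", "error", "condition")))
}

## run code with a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    .stopValidation("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
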