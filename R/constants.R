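#' Physical constants
#'
#' CODATA values used throughout the package: the vacuum permeability
#' `mu0` (T m/A) and the Boltzmann constant `kB` (J/K).
#'
#' @return Named list with elements `mu0` and `kB`.
#' @examples
#' physical_constants()$mu0
#' @export
physical_constants <- function() {
  list(mu0 = 4e-7 * pi, kB = 1.380649e-23)
}

.mu0 <- 4e-7 * pi
.kB <- 1.380649e-23
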