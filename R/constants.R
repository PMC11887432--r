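# Physical constants (CODATA 2018) and species bookkeeping shared across
# modules. Internal units: nm for length, kBT for energy, e for charge,
# mol/L for reservoir concentrations.

#' Physical constants used by the package
#'
#' A named list with Avogadro's number (`N_A`, 1/mol), Boltzmann's constant
#' (`k_B`, J/K), the elementary charge (`e`, C), and the vacuum permittivity
#' (`eps0`, F/m).
#'
#' @export
pt_constants <- list(
  N_A  = 6.02214076e23,
  k_B  = 1.380649e-23,
  e    = 1.602176634e-19,
  eps0 = 8.8541878128e-12
)

# particles per nm^3 at the reference concentration c0 = 1 mol/L
.NA_C0_NM3 <- pt_constants$N_A / 1e24

# species codes shared with src/simcore.cpp
.SPECIES <- c(core = 0L, site = 1L, Na = 2L, Cl = 3L, H = 4L, OH = 5L)

.species_name <- function(code) names(.SPECIES)[match(code, .SPECIES)]

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (strict_upper && x >= upper)
    stop(sprintf("'%s' must be < %g", name, upper), call. = FALSE)
  if (!strict_upper && x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
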