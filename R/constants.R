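#' Physical constants and the thermal voltage
#'
#' Returns the thermodynamic constants used throughout the model: the gas
#' constant \eqn{R}, the absolute temperature \eqn{T}, the Faraday constant
#' \eqn{F}, and the derived thermal voltage \eqn{V_{ref} = RT/F} that scales
#' all Goldman-Hodgkin-Katz exponentials.
#'
#' @param temperature Absolute temperature in K (default 298.15).
#' @return A named list with elements `R` (J mol^-1 K^-1), `T` (K),
#'   `F` (C mol^-1) and `Vref` (V).
#' @examples
#' pc <- physicalConstants()
#' pc$Vref            # ~0.0257 V at 25 C
#' @export
physicalConstants <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  R <- 8.314462618
  F <- 96485.33212
  list(R = R, T = temperature, F = F, Vref = R * temperature / F)
}

# RT in Pa per (mol L^-1): osmotic pressure of a 1 M ideal solute.
# Concentrations are carried in M internally; the factor 1000 converts to
# mol m^-3 where pressure or flux arithmetic needs it.
.RT_Pa_per_M <- function(constants) constants$R * constants$T * 1000
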