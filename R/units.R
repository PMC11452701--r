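#' Unit conversion constants
#'
#' The package computes internally in SI (Pa, m, s, m^3/s) and converts at the
#' I/O boundary, where pressures are mmHg, velocities cm/s, cardiac output
#' L/min and pulse wave velocity m/s.
#'
#' @name units
#' @keywords internal
NULL

#' @rdname units
#' @export
MMHG_PA <- 133.322387415

#' @rdname units
#' @export
L_PER_MIN_M3_PER_S <- 1e-3 / 60

#' Convert mmHg to Pa
#' @param x pressure in mmHg
#' @return pressure in Pa
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' Convert Pa to mmHg
#' @param x pressure in Pa
#' @return pressure in mmHg
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' Convert L/min to m^3/s
#' @param x flow in L/min
#' @return flow in m^3/s
#' @export
lmin_to_m3s <- function(x) x * L_PER_MIN_M3_PER_S

#' Convert m^3/s to L/min
#' @param x flow in m^3/s
#' @return flow in L/min
#' @export
m3s_to_lmin <- function(x) x / L_PER_MIN_M3_PER_S
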