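# Centralized unit conversions. Convention throughout the package:
# all arithmetic is done in SI (m, s, Pa, kg/m^3, Pa.s); every user-facing
# interface speaks mm, s, cP and g/mL, the units practitioners of capillary
# "dip-and-test" strips quote.

MM_PER_M <- 1000

#' @noRd
mm_to_m <- function(x) x / MM_PER_M

#' @noRd
m_to_mm <- function(x) x * MM_PER_M

#' Convert a density from g/mL to kg/m^3
#' @noRd
gml_to_kgm3 <- function(x) x * 1000

#' Convert a dynamic viscosity from centipoise to Pa.s
#' @noRd
cp_to_pas <- function(x) x * 1e-3

#' @noRd
pas_to_cp <- function(x) x * 1e3
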