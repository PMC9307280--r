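#' Physical constants and unit conversions
#'
#' Interfaces use clinical units (mm, mmHg, mL/min for reported flows,
#' mmHg.s/mL for resistances); the solver works in SI internally with
#' 1 mmHg = 133.322 Pa.
#'
#' @name units
#' @keywords internal
NULL

## 1 mmHg in Pa
MMHG_PA <- 133.322

## blood density [kg m^-3] and viscosity [Pa s]
BLOOD_RHO <- 1060
BLOOD_MU <- 0.0047

## Poisson ratio of the arterial wall
WALL_SIGMA <- 0.5

## reference (diastolic-load) pressure [mmHg]
P0_MMHG <- 85

## cardiac period [s]
CARDIAC_PERIOD <- 1.0

## 1 mmHg.s/mL in Pa.s/m^3
RES_SI <- MMHG_PA / 1e-6

## 1 mL/mmHg in m^3/Pa
CAP_SI <- 1e-6 / MMHG_PA

#' @keywords internal
mmHg_to_Pa <- function(p) p * MMHG_PA
#' @keywords internal
Pa_to_mmHg <- function(p) p / MMHG_PA
#' @keywords internal
mlmin_to_m3s <- function(q) q * 1e-6 / 60
#' @keywords internal
m3s_to_mlmin <- function(q) q * 60 / 1e-6
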