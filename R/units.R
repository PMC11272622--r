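# All internal quantities are SI (Pa, m, N). mmHg appears only at interfaces.
MMHG_PA <- 133.322

#' Convert between pascal and millimetres of mercury
#'
#' The package computes in SI units; clinical compression values are reported
#' in mmHg (1 mmHg = 133.322 Pa).
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' pa_to_mmhg(2500)   # 18.75 mmHg
#' mmhg_to_pa(18.75)
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' @rdname pa_to_mmhg
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA
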