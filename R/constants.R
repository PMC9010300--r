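#' Gyromagnetic frequency ratio between carbon-13 and proton
#'
#' Single source of truth for unit conversions between ppm and rad/s: the
#' carbon-13 Larmor frequency expressed as a fraction of the proton Larmor
#' frequency at the same static field.
#'
#' @format A length-one numeric, `0.251450`.
#' @export
GAMMA_C_OVER_H <- 0.251450

# Maximum relative snap error tolerated silently when rounding a requested
# CPMG frequency to an integer pulse count (see .snap_ncpmg()).
.SNAP_TOL <- 0.02
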