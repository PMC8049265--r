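#' ADC unit scales
#'
#' ADC maps are stored at several conventional scales: physical mm^2/s
#' (floating point, order 1e-3 for brain tissue), or integer storage at
#' 1e-3, 1e-5 or 1e-6 mm^2/s per unit. Internally every volume is held in
#' canonical mm^2/s; reporting uses `report_scale` (default 1e-5 mm^2/s,
#' the scale at which whole-lesion glioma ADC statistics are conventionally
#' tabulated, e.g. a mean ADC of 1.3757e-3 mm^2/s prints as 137.57).
#'
#' @param unit_scale One of `"mm2/s"`, `"1e-3"`, `"1e-5"`, `"1e-6"`, or a
#'   positive number giving mm^2/s per stored unit.
#' @return The multiplicative factor converting stored values to mm^2/s.
#' @export
#' @examples
#' unit_scale_factor("1e-6") # 1376 stored -> 1.376e-3 mm^2/s
unit_scale_factor <- function(unit_scale) {
  if (is.numeric(unit_scale)) {
    if (length(unit_scale) != 1L || !is.finite(unit_scale) || unit_scale <= 0) {
      abort("`unit_scale` must be a single positive number or a known scale name.",
            class = "adchist_validation_error")
    }
    return(as.numeric(unit_scale))
  }
  switch(as.character(unit_scale),
    "mm2/s" = 1,
    "1"     = 1,
    "1e-3"  = 1e-3,
    "1e-5"  = 1e-5,
    "1e-6"  = 1e-6,
    abort(sprintf("Unknown unit scale '%s'.", unit_scale),
          class = "adchist_validation_error")
  )
}

#' Default reporting scale for ADC values
#'
#' @return mm^2/s per reported unit (1e-5).
#' @export
default_report_scale <- function() 1e-5

# canonical mm^2/s -> report units
to_report_units <- function(x, report_scale = default_report_scale()) {
  x / report_scale
}
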