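# Dose accumulation and adiabatic heating bounds.
#
# A Gray is one joule per kilogram, so with no heat exchange and no phase
# change the temperature rise of the absorbing liquid is bounded by
# dose / specific heat. Specific heats are standard room-temperature values;
# both are configuration, not physics the method estimates.

.solvent_specific_heat <- c(water = 4184, ethanol = 2440)  # J kg^-1 K^-1

#' Solvent thermal properties
#'
#' @param name `"water"` or `"ethanol"`, or a custom name with
#'   `specific_heat` supplied.
#' @param specific_heat J kg^-1 K^-1 at room temperature; defaults come from
#'   standard tables (water 4184, ethanol 2440).
#' @return Object of class `solvent_properties`.
#' @export
solvent_properties <- function(name, specific_heat = NULL) {
  if (is.null(specific_heat)) {
    if (!name %in% names(.solvent_specific_heat))
      stop_bub("unknown solvent '%s'; supply specific_heat explicitly", name)
    specific_heat <- .solvent_specific_heat[[name]]
  }
  assert_scalar_pos(specific_heat, "specific_heat")
  structure(list(name = name, specific_heat = specific_heat),
            class = "solvent_properties")
}

#' Accumulated surface dose
#'
#' `D = dose_rate * (t - t_ron)`: the cumulative dose after `t - t_ron`
#' seconds of irradiation at a constant dose rate (36.8 Gy/s measured at the
#' beamline by default).
#'
#' @param t Time, s (may be a vector).
#' @param dose_rate Gy/s.
#' @param t_ron Radiation-on time, s.
#' @return Dose in Gy.
#' @export
cumulative_dose <- function(t, dose_rate = 36.8, t_ron = 0) {
  assert_scalar_pos(dose_rate, "dose_rate")
  if (any(t < t_ron)) stop_bub("t must not precede radiation-on time")
  dose_rate * (t - t_ron)
}

#' Dose accumulated at bubble onset
#'
#' @param onset An `onset_estimate` (or numeric t_bo, s).
#' @param dose_rate Gy/s.
#' @param t_ron Radiation-on time, s.
#' @return Dose at onset, Gy (`dose_rate * t_bbo`).
#' @export
dose_at_onset <- function(onset, dose_rate = 36.8, t_ron = 0) {
  t_bo <- if (inherits(onset, "onset_estimate")) onset$t_bo else onset
  if (is.na(t_bo)) return(NA_real_)
  cumulative_dose(t_bo, dose_rate, t_ron)
}

#' Adiabatic upper-bound temperature rise
#'
#' `delta_T = dose / specific_heat`, assuming all absorbed energy stays in
#' the solvent (no heat exchange, no phase change) - the maximum possible
#' temperature change for the given dose.
#'
#' @param dose_gy Absorbed dose, Gy (J/kg); may be a vector.
#' @param solvent A [solvent_properties()] or a solvent name.
#' @return Temperature rise in degrees Celsius.
#' @export
temperature_bound <- function(dose_gy, solvent) {
  if (is.character(solvent)) solvent <- solvent_properties(solvent)
  stopifnot(inherits(solvent, "solvent_properties"))
  if (any(dose_gy < 0)) stop_bub("dose must be non-negative")
  dose_gy / solvent$specific_heat
}
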