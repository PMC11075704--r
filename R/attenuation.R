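# Linear attenuation of the embedding liquid.
#
# The volumetric inversion needs the linear attenuation coefficient mu_liq of
# the liquid that the gas displaces (70% ethanol in water for
# ethanol-dehydrated, wet-embedded tissue) at the working beam energy
# (82 keV mean). mu_liq is derived from NIST XCOM mass attenuation
# coefficients of H, C and O by the elemental mixture rule, log-log
# interpolated in energy. All defaults are overridable through
# `attenuation_model()` / the run configuration.

# NIST XCOM mass attenuation coefficients mu/rho (cm^2/g), total with coherent
# scattering, for the elements of water and ethanol. Cross-checked against the
# tabulated water compound value (0.1837 cm^2/g at 80 keV).
.xcom_energies_kev <- c(60, 80, 100, 150)
.xcom_mu_rho <- rbind(
  H = c(0.3254, 0.3091, 0.2944, 0.2651),
  C = c(0.1753, 0.1610, 0.1514, 0.1347),
  O = c(0.1907, 0.1678, 0.1551, 0.1361)
)

# Mass fractions: water H2O, ethanol C2H6O (atomic masses 1.008, 12.011, 15.999).
.mass_frac <- list(
  water   = c(H = 2 * 1.008, C = 0, O = 15.999) / (2 * 1.008 + 15.999),
  ethanol = c(H = 6 * 1.008, C = 2 * 12.011, O = 15.999) /
    (6 * 1.008 + 2 * 12.011 + 15.999)
)

# Density of 70 vol% ethanol/water at room temperature (CRC tables), g/cm^3.
.density_70etoh <- 0.868

#' Elemental mass attenuation coefficient
#'
#' Total mass attenuation coefficient (with coherent scattering) of H, C or O,
#' log-log interpolated between NIST XCOM tabulation energies.
#'
#' @param element One of `"H"`, `"C"`, `"O"`.
#' @param energy_kev Photon energy in keV, within 60-150 keV.
#' @return mu/rho in cm^2/g.
#' @export
mass_attenuation <- function(element, energy_kev) {
  element <- match.arg(element, rownames(.xcom_mu_rho))
  if (energy_kev < min(.xcom_energies_kev) || energy_kev > max(.xcom_energies_kev))
    stop_bub("energy %.1f keV outside tabulated range 60-150 keV", energy_kev)
  exp(approx(log(.xcom_energies_kev), log(.xcom_mu_rho[element, ]),
             xout = log(energy_kev))$y)
}

#' Linear attenuation coefficient of an ethanol/water mixture
#'
#' Mixture-rule mu (mm^-1) for an ethanol/water solution at a given energy.
#' The default arguments describe the embedding liquid assumed throughout the
#' package: 70% ethanol by volume at 82 keV mean beam energy.
#'
#' @param energy_kev Photon energy, keV.
#' @param ethanol_vol_frac Ethanol volume fraction of the mixture.
#' @param density_g_cm3 Mixture mass density, g/cm^3. Default is the tabulated
#'   room-temperature density of 70 vol% ethanol.
#' @return Linear attenuation coefficient in mm^-1.
#' @examples
#' mu_liquid()            # ~0.0158 mm^-1
#' mu_liquid(82, 0)       # pure water (pass density = 0.998)
#' @export
mu_liquid <- function(energy_kev = 82, ethanol_vol_frac = 0.70,
                      density_g_cm3 = .density_70etoh) {
  assert_scalar_pos(density_g_cm3, "density_g_cm3")
  if (ethanol_vol_frac < 0 || ethanol_vol_frac > 1)
    stop_bub("ethanol_vol_frac must lie in [0, 1]")
  rho_e <- 0.789; rho_w <- 0.998
  m_e <- ethanol_vol_frac * rho_e
  m_w <- (1 - ethanol_vol_frac) * rho_w
  w_e <- m_e / (m_e + m_w)
  frac <- w_e * .mass_frac$ethanol + (1 - w_e) * .mass_frac$water
  mu_rho <- sum(vapply(names(frac), function(el) {
    frac[[el]] * if (frac[[el]] > 0) mass_attenuation(el, energy_kev) else 0
  }, numeric(1)))
  # cm^2/g * g/cm^3 = cm^-1 -> mm^-1
  mu_rho * density_g_cm3 / 10
}

#' Attenuation model for Beer-Lambert inversion
#'
#' Bundles the liquid's linear attenuation coefficient with the beam energy it
#' refers to. `gas_volume()` divides excess optical depth by `mu_liq` to get
#' the gas path length.
#'
#' @param mu_liq Linear attenuation coefficient of the displaced liquid,
#'   mm^-1. Defaults to [mu_liquid()] at 82 keV for 70 vol% ethanol.
#' @param energy_kev Beam energy the coefficient refers to (metadata).
#' @return An object of class `attenuation_model`.
#' @export
attenuation_model <- function(mu_liq = mu_liquid(), energy_kev = 82) {
  assert_scalar_pos(mu_liq, "mu_liq")
  structure(list(mu_liq = mu_liq, energy_kev = energy_kev),
            class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat(sprintf("<attenuation_model> mu_liq = %.5f mm^-1 at %.0f keV\n",
              x$mu_liq, x$energy_kev))
  invisible(x)
}
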