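# Phantom specification objects.
#
# The phantom emulates the acquisition this package analyzes: a parallel-beam
# phase-contrast cineradiograph sequence (25 um pixels, 3 frames/s, ~50 mm x
# 4 mm field of view) of a liquid-filled container with an agar/tissue
# attenuation context, in which bubbles nucleate sequentially and grow under
# one of three microstructure regimes, plus micro-gas-chromatograph cycles
# with N2/O2/EtOH/H2O peaks whose solvent fractions shift at bubble onset.

#' Phantom specification
#'
#' Describes the synthetic imaging experiment: geometry, microstructure,
#' attenuation background, noise and acquisition parameters. Defaults follow
#' the study conditions the analysis assumes (25 um isotropic pixels, 3
#' frames per second, 70 mm beam path through the liquid).
#'
#' @param fov_mm Field of view `c(width, height)` in mm.
#' @param pixel_size_um Isotropic pixel size, um.
#' @param frame_rate Frames per second.
#' @param container_thickness_mm Beam-path length through the liquid, mm.
#'   The container slices are ~70 mm across; this is an assumption of the
#'   forward model, overridable here and in run configurations.
#' @param microstructure One of `"none"` (homogeneous liquid),
#'   `"agar_gaps"` (unconstrained voids), `"vessel"` (one horizontal tubular
#'   lumen), `"alveolar"` (hexagonally packed spherical compartments).
#' @param vessel_diameter_um Lumen diameter for `"vessel"`, um.
#' @param alveolus_radius_um Compartment radius for `"alveolar"`, um.
#' @param mu_liq Linear attenuation of the liquid, mm^-1.
#' @param bg_texture_tau Amplitude (optical-depth units) of the smooth
#'   agar/tissue context texture added to the homogeneous background.
#' @param noise_sigma_rel Relative Gaussian intensity noise per pixel.
#' @param photon_scale Optional photon-count scale; if given, Poisson-like
#'   noise with sd `sqrt(I * photon_scale)/photon_scale` replaces the relative
#'   Gaussian model.
#' @param fringe_strength Amplitude of the propagation-fringe surrogate (a
#'   discrete Laplacian of the gas path length added to the intensity);
#'   0 disables it. The analysis performs no phase retrieval, so fringes exist
#'   only to probe volumetry robustness.
#' @param seed Integer seed making rendering reproducible.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(fov_mm = c(50, 4),
                         pixel_size_um = 25,
                         frame_rate = 3,
                         container_thickness_mm = 70,
                         microstructure = c("none", "agar_gaps", "vessel", "alveolar"),
                         vessel_diameter_um = 100,
                         alveolus_radius_um = 125,
                         mu_liq = mu_liquid(),
                         bg_texture_tau = 0.05,
                         noise_sigma_rel = 0.02,
                         photon_scale = NULL,
                         fringe_strength = 0,
                         seed = 1L) {
  microstructure <- match.arg(microstructure)
  if (length(fov_mm) != 2L || any(fov_mm <= 0))
    stop_bub("fov_mm must be two positive numbers (width, height)")
  assert_scalar_pos(pixel_size_um, "pixel_size_um")
  assert_scalar_pos(frame_rate, "frame_rate")
  assert_scalar_pos(container_thickness_mm, "container_thickness_mm")
  assert_scalar_pos(vessel_diameter_um, "vessel_diameter_um")
  assert_scalar_pos(alveolus_radius_um, "alveolus_radius_um")
  assert_scalar_pos(mu_liq, "mu_liq")
  if (noise_sigma_rel < 0) stop_bub("noise_sigma_rel must be >= 0")
  if (fringe_strength < 0) stop_bub("fringe_strength must be >= 0")
  if (bg_texture_tau < 0) stop_bub("bg_texture_tau must be >= 0")
  structure(list(
    fov_mm = as.numeric(fov_mm),
    pixel_size_um = pixel_size_um,
    frame_rate = frame_rate,
    container_thickness_mm = container_thickness_mm,
    microstructure = microstructure,
    vessel_diameter_um = vessel_diameter_um,
    alveolus_radius_um = alveolus_radius_um,
    mu_liq = mu_liq,
    bg_texture_tau = bg_texture_tau,
    noise_sigma_rel = noise_sigma_rel,
    photon_scale = photon_scale,
    fringe_strength = fringe_strength,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %.1f x %.1f mm FOV, %.0f um px, %.1f fps, %s microstructure, noise %.1f%%\n",
    x$fov_mm[1], x$fov_mm[2], x$pixel_size_um, x$frame_rate,
    x$microstructure, 100 * x$noise_sigma_rel))
  invisible(x)
}

#' Bubble seed
#'
#' One nucleation event and its growth law. Growth laws mirror the three
#' constrained-growth regimes the shape analysis distinguishes:
#' * `"diffusion"`: a free sphere whose radius grows as the square root of
#'   elapsed time (projected area grows linearly in time after onset);
#' * `"vessel"`: bidirectional elongation of a capsule of fixed radius inside
#'   a tubular lumen (circularity decreases continuously);
#' * `"alveolar"`: sequential filling of adjacent spherical compartments with
#'   dwell times (stepped area plateaus).
#'
#' @param nucleation_time Seconds since radiation-on.
#' @param site `c(x, y)` position in mm (origin top-left, y downward).
#' @param law `"diffusion"`, `"vessel"` or `"alveolar"`.
#' @param rate Law rate constant: diffusion `r(t) = rate * sqrt(t)` (mm);
#'   vessel half-length growth rate (mm/s); alveolar dwell time per
#'   compartment (s).
#' @param radius_mm Fixed radius: capsule radius for `"vessel"`, compartment
#'   radius for `"alveolar"`; ignored for `"diffusion"`.
#' @param n_compartments Number of compartments available (`"alveolar"`).
#' @param rise_velocity_mm_s Upward drift speed; bubbles migrate toward the
#'   top edge and exit the field of view.
#' @param exit_time Optional scripted time (s) at which the bubble leaves the
#'   field of view; its volume is frozen into the exited ledger.
#' @return Object of class `bubble_seed`.
#' @export
bubble_seed <- function(nucleation_time, site,
                        law = c("diffusion", "vessel", "alveolar"),
                        rate = 0.02, radius_mm = 0.05, n_compartments = 3L,
                        rise_velocity_mm_s = 0, exit_time = NA_real_) {
  law <- match.arg(law)
  if (nucleation_time < 0) stop_bub("nucleation_time must be >= 0")
  assert_scalar_pos(rate, "rate")
  assert_scalar_pos(radius_mm, "radius_mm")
  if (length(site) != 2L) stop_bub("site must be c(x, y) in mm")
  structure(list(
    nucleation_time = nucleation_time, site = as.numeric(site), law = law,
    rate = rate, radius_mm = radius_mm, n_compartments = as.integer(n_compartments),
    rise_velocity_mm_s = rise_velocity_mm_s, exit_time = exit_time
  ), class = "bubble_seed")
}

#' Gas injection schedule for chromatogram synthesis
#'
#' Per-cycle injected amounts (arbitrary units) of N2, O2, EtOH and H2O over a
#' sequence of elution rounds, with a solvent-fraction shift at bubble onset:
#' after onset the ethanol share of the solvent vapor rises by
#' `etoh_shift` at the expense of water, while the air species stay constant.
#'
#' @param n_cycles Number of elution rounds.
#' @param cycle_period_s Duration of one elution round, s (2.4 min).
#' @param onset_time_s Bubble onset time, s.
#' @param solvent_amount Total solvent vapor amount per cycle (a.u.).
#' @param air_amount Total air (N2+O2) amount per cycle (a.u.).
#' @param etoh_frac_pre Pre-onset ethanol fraction of the solvent vapor.
#' @param etoh_shift Post-onset increase of the ethanol fraction.
#' @param amount_noise_rel Independent relative noise on each species amount
#'   per cycle (injection/partitioning variability).
#' @return Object of class `gas_schedule`: a data frame of per-cycle amounts
#'   with the schedule parameters as attributes.
#' @export
gas_schedule <- function(n_cycles = 12L, cycle_period_s = 144,
                         onset_time_s = 800, solvent_amount = 100,
                         air_amount = 60, etoh_frac_pre = 0.40,
                         etoh_shift = 0.15, amount_noise_rel = 0.01) {
  assert_scalar_pos(cycle_period_s, "cycle_period_s")
  if (n_cycles < 1L) stop_bub("n_cycles must be >= 1")
  if (etoh_frac_pre < 0 || etoh_frac_pre + etoh_shift > 1)
    stop_bub("ethanol fractions must stay within [0, 1]")
  cycle_time <- (seq_len(n_cycles) - 0.5) * cycle_period_s
  post <- cycle_time > onset_time_s
  fe <- ifelse(post, etoh_frac_pre + etoh_shift, etoh_frac_pre)
  sched <- data.frame(
    cycle = seq_len(n_cycles),
    cycle_time_s = cycle_time,
    n2 = 0.78 * air_amount,
    o2 = 0.22 * air_amount,
    etoh = fe * solvent_amount,
    h2o = (1 - fe) * solvent_amount
  )
  structure(sched,
            cycle_period_s = cycle_period_s, onset_time_s = onset_time_s,
            amount_noise_rel = amount_noise_rel, etoh_shift = etoh_shift,
            class = c("gas_schedule", "data.frame"))
}
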