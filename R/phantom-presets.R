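# Named phantom presets: the study conditions exercised by the validation
# suite. Volume-series presets emulate the macroscopic cumulative growth of
# degassed / non-degassed samples; scenario presets emulate the three
# constrained-growth regimes at single-bubble level.

#' Simulate a cumulative bubble-volume series
#'
#' Draws a power-law cumulative volume curve
#' `V_C(t) = k * (t - t_bo)^alpha` for `t > t_bo` sampled at the
#' cineradiography frame rate, with multiplicative measurement noise and a
#' small additive volumetry noise floor. Presets:
#' * `"degassed"`: the highly degassed condition - consistent exponent
#'   `alpha = 3.0`; the prefactor default accumulates ~1.3e3 mm^3 of gas over
#'   the first 10 min, and places the default onset-detection rule within a
#'   few seconds of the true onset.
#' * `"non_degassed"`: sample-dependent kinetics - `alpha` drawn uniformly
#'   from \[2.4, 3.0\] per series (a spread of at least 0.4 across samples).
#'
#' @param preset `"degassed"` or `"non_degassed"`.
#' @param duration_s Series length, s (t = 0 at radiation-on).
#' @param frame_rate Frames per second.
#' @param onset_time_s True bubble onset time, s.
#' @param noise_rel Multiplicative measurement noise (sd, relative).
#' @param noise_abs_mm3 Additive volumetry noise floor (sd, mm^3).
#' @param alpha,k Override the preset growth exponent / prefactor
#'   (mm^3 s^-alpha).
#' @param seed Integer seed.
#' @return A [volume_series()] with attributes `true_onset_s`, `alpha_true`
#'   and `k_true`.
#' @export
simulate_volume_series <- function(preset = c("degassed", "non_degassed"),
                                   duration_s = 700, frame_rate = 3,
                                   onset_time_s = 60, noise_rel = 0.02,
                                   noise_abs_mm3 = 1e-4,
                                   alpha = NULL, k = NULL, seed = 1L) {
  preset <- match.arg(preset)
  local_seed(seed, {
    if (is.null(alpha))
      alpha <- if (preset == "degassed") 3.0 else stats::runif(1, 2.4, 3.0)
    if (is.null(k)) k <- 6e-6
    times <- seq(1 / frame_rate, duration_s, by = 1 / frame_rate)
    tabo <- pmax(times - onset_time_s, 0)
    v_true <- k * tabo^alpha
    v_obs <- v_true * (1 + stats::rnorm(length(times), sd = noise_rel)) +
      stats::rnorm(length(times), sd = noise_abs_mm3)
    v_obs <- pmax(v_obs, 0)
    vs <- volume_series(times, v_obs)
    attr(vs, "true_onset_s") <- onset_time_s
    attr(vs, "alpha_true") <- alpha
    attr(vs, "k_true") <- k
    vs
  })
}

#' Simulate excess-depth maps for one constrained-growth scenario
#'
#' Generates a short single-bubble sequence of excess optical-depth maps for
#' one of the three growth regimes, with per-pixel Gaussian noise. Seed-level
#' variation jitters nucleation time, growth rate and site. These are the
#' inputs the segmentation/tracking/classification chain is validated on.
#'
#' @param scenario `"diffusion"`, `"vessel"` or `"alveolar"`.
#' @param seed Integer seed.
#' @param duration_s Sequence length, s.
#' @param frame_rate Frames per second.
#' @param noise_dtau Additive per-pixel noise sd on the excess depth map.
#' @param pixel_size_um Pixel size, um.
#' @param mu_liq Liquid attenuation used to convert gas path to excess depth.
#' @return List with `dtau` (list of matrices), `times`, `pixel_size_um`,
#'   `evolution` (ground truth) and `noise_dtau`.
#' @export
simulate_scenario <- function(scenario = c("diffusion", "vessel", "alveolar"),
                              seed = 1L, duration_s = 30, frame_rate = 3,
                              noise_dtau = 5e-4, pixel_size_um = 25,
                              mu_liq = mu_liquid()) {
  scenario <- match.arg(scenario)
  local_seed(seed, {
    jit <- function(x, f = 0.2) x * stats::runif(1, 1 - f, 1 + f)
    if (scenario == "diffusion") {
      fov <- c(3, 3)
      sd_ <- bubble_seed(nucleation_time = stats::runif(1, 0.5, 2),
                         site = c(jit(1.5, 0.1), jit(1.5, 0.1)),
                         law = "diffusion", rate = jit(0.15))
    } else if (scenario == "vessel") {
      fov <- c(6, 1)
      sd_ <- bubble_seed(nucleation_time = stats::runif(1, 0.5, 2),
                         site = c(jit(3, 0.1), 0.5),
                         law = "vessel", rate = jit(0.01), radius_mm = 0.05)
    } else {
      fov <- c(3, 1.5)
      sd_ <- bubble_seed(nucleation_time = stats::runif(1, 0.5, 2),
                         site = c(1, 0.75),
                         law = "alveolar", rate = jit(8), radius_mm = 0.125,
                         n_compartments = 3L)
    }
    spec <- phantom_spec(fov_mm = fov, pixel_size_um = pixel_size_um,
                         frame_rate = frame_rate, microstructure = "none",
                         mu_liq = mu_liq, noise_sigma_rel = 0,
                         bg_texture_tau = 0, seed = seed)
    grid <- pixel_grid(spec)
    times <- seq(1 / frame_rate, duration_s, by = 1 / frame_rate)
    evo <- evolve_bubbles(list(sd_), times, phantom = NULL)
    dtau <- lapply(evo$frames, function(shapes) {
      m <- mu_liq * gas_path_map(shapes, grid)
      if (noise_dtau > 0)
        m <- m + matrix(stats::rnorm(length(m), sd = noise_dtau), nrow(m))
      m
    })
    list(dtau = dtau, times = times, pixel_size_um = pixel_size_um,
         evolution = evo, noise_dtau = noise_dtau)
  })
}

#' Segment, track and measure a simulated scenario
#'
#' Runs the measurement chain on a [simulate_scenario()] result: Gaussian
#' smoothing for detection, flooring at 3 times the robust noise level of
#' the smoothed maps (estimated from the first, bubble-free frame),
#' segmentation, and overlap tracking. Returns the longest track - the
#' scenario's bubble.
#'
#' @param sim A [simulate_scenario()] result.
#' @param smooth_sigma Detection smoothing, pixels.
#' @param min_size_px Minimum component size.
#' @return List: `track` (data frame), `tracks` (all), `floor`.
#' @export
measure_scenario <- function(sim, smooth_sigma = 1, min_size_px = 9L) {
  det <- lapply(sim$dtau, gauss_blur, sigma = smooth_sigma)
  floor_ <- 3 * stats::mad(det[[1]])
  segs <- lapply(det, function(m) {
    segment_frame(pmax(m - 0, 0), sim$pixel_size_um,
                  min_size_px = min_size_px, threshold = floor_)
  })
  trk <- track_bubbles(segs, sim$times, pixel_size_um = sim$pixel_size_um)
  ns <- vapply(trk$tracks, nrow, integer(1))
  list(track = trk$tracks[[which.max(ns)]], tracks = trk, floor = floor_)
}
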