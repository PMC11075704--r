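# Forward rendering: radiograph stacks and chromatograms with ground truth.

#' Render a cineradiograph stack from phantom and bubble geometry
#'
#' Forward model: transmitted intensity
#' `I = flat(x, y, t) * exp(-(tau_bg - mu_liq * t_gas)) + dark + noise`,
#' where `t_gas` is the beam-path length through gas. An optional
#' edge-enhancement surrogate (`fringe_strength` times the discrete Laplacian
#' of `t_gas`) mimics propagation fringes without any coherent-optics model.
#' Negative intensities after noise are clipped at zero and counted.
#'
#' @param phantom A [build_phantom()] result.
#' @param evo A [evolve_bubbles()] result on the same phantom.
#' @param n_flats,n_darks Number of flat/dark frames to synthesize.
#' @param flat_drift Relative amplitude of a slow illumination drift across
#'   the sequence (a horizontal gradient ramping over time); the recorded
#'   flats sample the same drift range so the dynamic flat-field method can
#'   model it. 0 keeps the illumination static.
#' @return Object of class `radiograph_stack` (see [read_stack()]): frames,
#'   times, pixel size, flats, darks and metadata (clip count, frame rate).
#' @export
render_stack <- function(phantom, evo, n_flats = 10L, n_darks = 5L,
                         flat_drift = 0) {
  stopifnot(inherits(phantom, "phantom"), inherits(evo, "bubble_evolution"))
  spec <- phantom$spec
  grid <- phantom$grid
  local_seed(spec$seed, {
    w2 <- max(grid$x) / 2; h2 <- max(grid$y) / 2
    gx <- (grid$x - w2) / w2
    gy <- (grid$y - h2) / h2
    flat0 <- outer(1 - 0.05 * gy^2, 1 - 0.15 * gx^2)
    gradx <- outer(rep(1, grid$ny), gx)

    noisify <- function(img) {
      if (!is.null(spec$photon_scale)) {
        sdm <- sqrt(pmax(img, 0) * spec$photon_scale) / spec$photon_scale
        img + matrix(stats::rnorm(length(img), sd = 1), nrow(img)) * sdm
      } else if (spec$noise_sigma_rel > 0) {
        img * (1 + matrix(stats::rnorm(length(img), sd = spec$noise_sigma_rel),
                          nrow(img)))
      } else img
    }

    dark_level <- 0.01
    flat_at <- function(a) flat0 * (1 + flat_drift * a * gradx)
    # recorded flats carry the dark offset, as on a real detector
    flats <- lapply(seq(-1, 1, length.out = n_flats),
                    function(a) noisify(flat_at(a)) + dark_level)
    dark_noise <- 0.05 * spec$noise_sigma_rel
    darks <- lapply(seq_len(n_darks), function(i) {
      m <- matrix(dark_level, grid$ny, grid$nx)
      if (dark_noise > 0)
        m <- m + matrix(stats::rnorm(grid$ny * grid$nx, sd = dark_noise), grid$ny)
      m
    })

    n_clip <- 0L
    tt <- evo$times
    ramp <- if (length(tt) > 1L) 2 * (tt - tt[1]) / (tt[length(tt)] - tt[1]) - 1
            else rep(0, length(tt))
    frames <- vector("list", length(tt))
    for (fi in seq_along(tt)) {
      tg <- gas_path_map(evo$frames[[fi]], grid)
      tau <- phantom$tau_bg - spec$mu_liq * tg
      img <- flat_at(ramp[fi]) * exp(-tau)
      if (spec$fringe_strength > 0)
        img <- img + spec$fringe_strength * laplacian(tg)
      img <- noisify(img) + dark_level
      neg <- img < 0
      n_clip <- n_clip + sum(neg)
      img[neg] <- 0
      frames[[fi]] <- img
    }

    structure(list(frames = frames, times = tt,
                   pixel_size_um = spec$pixel_size_um,
                   flats = flats, darks = darks,
                   meta = list(frame_rate = spec$frame_rate,
                               clip_count = n_clip,
                               mu_liq = spec$mu_liq)),
              class = "radiograph_stack")
  })
}

#' Synthesize micro-gas-chromatograms from a gas schedule
#'
#' Each elution cycle yields one trace per detection module with Gaussian
#' peaks at fixed species retention times (area proportional to injected
#' amount), a slowly drifting baseline, and additive noise. Module MS5A
#' carries N2 and O2; module PDMS10 carries EtOH, H2O and a combined N2+O2
#' peak.
#'
#' @param schedule A [gas_schedule()].
#' @param reference Reference retention-time table as from
#'   [gc_reference_default()].
#' @param seed Integer seed.
#' @param rt_max,rt_step Retention-time axis extent and sampling, s.
#' @param peak_sigma_s Chromatographic peak width (Gaussian sigma), s.
#' @param baseline_level,noise_abs Baseline magnitude and additive noise sd,
#'   detector units.
#' @return Object of class `chromatogram_set`: long data frame with columns
#'   `module`, `cycle`, `cycle_time_s`, `rt_s`, `signal`, plus a `truth`
#'   attribute holding the noisy per-cycle injected amounts.
#' @export
render_chromatograms <- function(schedule, reference = gc_reference_default(),
                                 seed = 1L, rt_max = 90, rt_step = 0.25,
                                 peak_sigma_s = 1.2, baseline_level = 2,
                                 noise_abs = 0.05) {
  stopifnot(inherits(schedule, "gas_schedule"))
  rt <- seq(0, rt_max, by = rt_step)
  noise_rel <- attr(schedule, "amount_noise_rel")
  local_seed(seed, {
    amounts <- as.matrix(schedule[, c("n2", "o2", "etoh", "h2o")])
    amounts <- amounts * matrix(1 + stats::rnorm(length(amounts), sd = noise_rel),
                                nrow(amounts))
    traces <- list()
    for (ci in seq_len(nrow(schedule))) {
      species_amt <- c(N2 = amounts[ci, "n2"], O2 = amounts[ci, "o2"],
                       EtOH = amounts[ci, "etoh"], H2O = amounts[ci, "h2o"],
                       `N2+O2` = amounts[ci, "n2"] + amounts[ci, "o2"])
      for (mod in unique(reference$module)) {
        ref <- reference[reference$module == mod, ]
        # baseline wander is incoherent between elution rounds
        sig <- baseline_level *
          (1 + 0.1 * sin(2 * pi * rt / rt_max + stats::runif(1, 0, 2 * pi))) +
          0.002 * rt
        for (i in seq_len(nrow(ref))) {
          amt <- species_amt[[ref$species[i]]]
          h <- amt / (peak_sigma_s * sqrt(2 * pi))
          sig <- sig + h * exp(-(rt - ref$rt_s[i])^2 / (2 * peak_sigma_s^2))
        }
        sig <- sig + stats::rnorm(length(rt), sd = noise_abs)
        traces[[length(traces) + 1L]] <- data.frame(
          module = mod, cycle = schedule$cycle[ci],
          cycle_time_s = schedule$cycle_time_s[ci], rt_s = rt, signal = sig)
      }
    }
    out <- do.call(rbind, traces)
    truth <- data.frame(cycle = schedule$cycle,
                        cycle_time_s = schedule$cycle_time_s, amounts)
    structure(out, truth = truth, onset_time_s = attr(schedule, "onset_time_s"),
              cycle_period_s = attr(schedule, "cycle_period_s"),
              class = c("chromatogram_set", "data.frame"))
  })
}

#' Default reference retention times
#'
#' Retention times are instrument calibration data, not physical constants;
#' this table is shared between the phantom renderer and the peak assignment
#' so that synthetic runs are internally consistent. Override per run through
#' the configuration.
#'
#' @return Data frame with columns `module`, `species`, `rt_s`.
#' @export
gc_reference_default <- function() {
  data.frame(
    module = c("MS5A", "MS5A", "PDMS10", "PDMS10", "PDMS10"),
    species = c("N2", "O2", "N2+O2", "EtOH", "H2O"),
    rt_s = c(30, 45, 20, 50, 70)
  )
}

# ---- on-disk phantom run ----------------------------------------------------

# Intensities are written as 16-bit TIFF after division by this full-scale
# value; read_stack() multiplies it back using meta.json.
.tiff_full_scale <- 1.5

#' Simulate a phantom run to disk
#'
#' Renders a radiograph stack (multi-page 16-bit TIFF plus flats, darks and a
#' timestamps CSV), chromatogram CSVs and ground-truth CSVs under `out_dir`,
#' the same layout [read_stack()] and the `analyze` pipeline consume.
#'
#' @param spec A [phantom_spec()].
#' @param seeds List of [bubble_seed()]; default one diffusion-law bubble.
#' @param duration_s Length of the cineradiograph sequence, s.
#' @param out_dir Output directory (created if missing).
#' @param schedule Optional [gas_schedule()]; when supplied chromatograms.csv
#'   is written as well.
#' @param flat_drift Passed to [render_stack()].
#' @return Invisibly, a list with the stack, evolution and file paths.
#' @export
simulate_phantom_run <- function(spec, seeds = NULL, duration_s = 20,
                                 out_dir, schedule = NULL, flat_drift = 0) {
  ph <- build_phantom(spec)
  if (is.null(seeds)) {
    seeds <- list(bubble_seed(nucleation_time = 2,
                              site = c(spec$fov_mm[1] / 2, spec$fov_mm[2] / 2),
                              law = "diffusion", rate = 0.05))
  }
  times <- seq(1 / spec$frame_rate, duration_s, by = 1 / spec$frame_rate)
  evo <- evolve_bubbles(seeds, times, ph)
  stack <- render_stack(ph, evo, flat_drift = flat_drift)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_stack(stack, out_dir)
  utils::write.csv(evo$ledger, file.path(out_dir, "ground_truth_bubbles.csv"),
                   row.names = FALSE)
  utils::write.csv(evo$totals, file.path(out_dir, "ground_truth_volumes.csv"),
                   row.names = FALSE)
  if (!is.null(evo$exits) && nrow(evo$exits))
    utils::write.csv(evo$exits, file.path(out_dir, "ground_truth_exits.csv"),
                     row.names = FALSE)
  if (!is.null(schedule)) {
    chrom <- render_chromatograms(schedule, seed = spec$seed)
    utils::write.csv(chrom, file.path(out_dir, "chromatograms.csv"),
                     row.names = FALSE)
  }
  invisible(list(stack = stack, evolution = evo, phantom = ph, paths = paths))
}

#' Write a radiograph stack to disk
#'
#' Frames go to `stack.tif` (multi-page, 16-bit unsigned, frame order = time
#' order), flats and darks to `flats.tif` / `darks.tif`, frame times to
#' `timestamps.csv` (`frame_index`, `time_s`) and scaling/pixel metadata to
#' `meta.json`.
#'
#' @param stack A `radiograph_stack`.
#' @param out_dir Target directory.
#' @return Named list of file paths.
#' @export
write_stack <- function(stack, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clamp <- function(m) pmin(pmax(m / .tiff_full_scale, 0), 1)
  p <- list(
    stack = file.path(out_dir, "stack.tif"),
    flats = file.path(out_dir, "flats.tif"),
    darks = file.path(out_dir, "darks.tif"),
    timestamps = file.path(out_dir, "timestamps.csv"),
    meta = file.path(out_dir, "meta.json")
  )
  tiff::writeTIFF(lapply(stack$frames, clamp), p$stack, bits.per.sample = 16L)
  tiff::writeTIFF(lapply(stack$flats, clamp), p$flats, bits.per.sample = 16L)
  tiff::writeTIFF(lapply(stack$darks, clamp), p$darks, bits.per.sample = 16L)
  utils::write.csv(data.frame(frame_index = seq_along(stack$times) - 1L,
                              time_s = stack$times),
                   p$timestamps, row.names = FALSE)
  jsonlite::write_json(list(full_scale = .tiff_full_scale,
                            pixel_size_um = stack$pixel_size_um,
                            frame_rate = stack$meta$frame_rate),
                       p$meta, auto_unbox = TRUE, digits = NA)
  p
}
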