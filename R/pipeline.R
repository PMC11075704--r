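# End-to-end orchestration: simulate/read -> correct -> segment -> volumetry
# -> kinetics -> GC -> dosimetry -> report.

#' Load and validate a run configuration
#'
#' A configuration supplies exactly one input source - a phantom
#' specification (`phantom`) or recorded inputs (`inputs` with `stack_dir`
#' and optional `chromatograms_csv`) - plus analysis parameters. Any omitted
#' parameter falls back to the package default. Referenced files must exist
#' at validation time.
#'
#' @param config Path to a JSON file or a named list.
#' @return Object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_bub("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  has_phantom <- !is.null(config$phantom)
  has_inputs <- !is.null(config$inputs)
  if (has_phantom == has_inputs)
    stop_bub("exactly one of `phantom` or `inputs` must be supplied")
  if (has_inputs) {
    if (is.null(config$inputs$stack_dir))
      stop_bub("inputs$stack_dir is required")
    if (!dir.exists(config$inputs$stack_dir))
      stop_bub("stack directory not found: %s", config$inputs$stack_dir)
    cc <- config$inputs$chromatograms_csv
    if (!is.null(cc) && !file.exists(cc))
      stop_bub("chromatogram file not found: %s", cc)
  }
  defaults <- list(
    mu_liq = mu_liquid(), energy_kev = 82,
    onset_threshold_mm3 = sphere_volume_mm3(100), onset_persistence = 3L,
    fit_duration_s = 600, correction_method = "static",
    smooth_sigma_px = 1.5, noise_floor_k_sigma = 3,
    context_frames = NULL, min_size_px = 25L, top_margin_px = 10L,
    dose_rate_gy_s = 36.8, seed = 1L, out_dir = NULL
  )
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  structure(config, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one sample and assembles a reproducible report:
#' onset table (t_bo, t_bbo, dose at onset), growth fit, per-track
#' classifications, volume series, GC window summary (when chromatograms are
#' supplied), and a provenance manifest (config hash, seed, package
#' version). All tables are written as CSV under `out_dir` when set.
#'
#' @param config A [run_config()] (or path/list coercible to one).
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  logmsg <- character(0)
  note <- function(...) logmsg <<- c(logmsg, sprintf(...))
  note("mu_liq = %.5f mm^-1; onset threshold = %.3g mm^3 x %d frames; floor = %g sigma",
       config$mu_liq, config$onset_threshold_mm3, config$onset_persistence,
       config$noise_floor_k_sigma)

  truth <- NULL
  if (!is.null(config$phantom)) {
    ph_args <- config$phantom
    seeds <- NULL
    if (!is.null(ph_args$seeds)) {
      sl <- ph_args$seeds
      # JSON arrays of seed objects may arrive simplified to a data frame
      if (is.data.frame(sl))
        sl <- lapply(seq_len(nrow(sl)), function(i) as.list(sl[i, , drop = FALSE]))
      seeds <- lapply(sl, function(s) {
        s <- lapply(s, function(x) if (is.list(x)) unlist(x) else x)
        s$site <- as.numeric(s$site)
        do.call(bubble_seed, s)
      })
      ph_args$seeds <- NULL
    }
    duration <- ph_args$duration_s %||% 20
    ph_args$duration_s <- NULL
    spec <- do.call(phantom_spec, c(ph_args, list(seed = config$seed)))
    sim_dir <- file.path(config$out_dir %||% tempdir(), "sim")
    sim <- simulate_phantom_run(spec, seeds = seeds, duration_s = duration,
                                out_dir = sim_dir)
    stack <- sim$stack
    truth <- sim$evolution
    note("simulated phantom run: %d frames", length(stack$frames))
  } else {
    stack <- read_stack(config$inputs$stack_dir)
  }

  tstack <- flat_field_correct(stack, method = config$correction_method)
  ctx_frames <- config$context_frames %||% seq_len(min(9L, length(stack$frames)))
  ctx <- build_context(tstack, window = ctx_frames)
  nf <- estimate_noise_floor(tstack, ctx, window = ctx_frames,
                             smooth_sigma = config$smooth_sigma_px,
                             k_sigma = config$noise_floor_k_sigma)
  note("noise floor = %.3g (sigma = %.3g)", nf$floor, nf$sigma)

  model <- attenuation_model(config$mu_liq, config$energy_kev)
  # detection maps (smoothed, floored) drive segmentation and tracking;
  # volumes integrate the raw signed excess depth over the detected apertures
  det_list <- lapply(tstack$frames, function(T) {
    excess_depth(T, ctx, noise_floor = nf$floor,
                 smooth_sigma = config$smooth_sigma_px,
                 from_transmission = TRUE)$dtau
  })
  raw_list <- lapply(tstack$frames, function(T) {
    excess_depth(T, ctx, noise_floor = 0, smooth_sigma = 0,
                 from_transmission = TRUE, clip_negative = FALSE)$dtau
  })

  segs <- lapply(det_list, segment_frame,
                 pixel_size_um = stack$pixel_size_um,
                 min_size_px = config$min_size_px)
  vols <- lapply(seq_along(segs), function(i) {
    masked_gas_volume(raw_list[[i]], segs[[i]]$labels, model,
                      stack$pixel_size_um)
  })
  vs <- volume_series(tstack$times,
                      vapply(vols, `[[`, numeric(1), "volume_mm3"))
  onset <- detect_onset(vs, config$onset_threshold_mm3,
                        config$onset_persistence)

  tracks <- track_bubbles(segs, tstack$times,
                          pixel_size_um = stack$pixel_size_um,
                          top_margin_px = config$top_margin_px)
  exited <- which(tracks$status == "exited")
  exits <- if (length(exited)) {
    data.frame(
      time = tracks$exit_time[exited],
      volume_mm3 = vapply(exited, function(i) {
        last <- tracks$exit_measurement[[i]]
        fi <- which(tstack$times == tracks$tracks[[i]]$time[nrow(tracks$tracks[[i]])])
        pv <- vols[[fi]]$per_label
        v <- pv[as.character(last$label)]
        if (is.na(v)) 0 else unname(v)
      }, numeric(1)))
  } else NULL
  vs <- accumulate_volume(vs, exits, onset)

  fit <- NULL
  if (onset$found) {
    fit <- tryCatch(fit_power_law(vs, onset,
                                  fit_duration = config$fit_duration_s),
                    error = function(e) {
                      note("power-law fit skipped: %s", conditionMessage(e))
                      NULL
                    })
  }

  cls <- do.call(rbind, lapply(seq_along(tracks$tracks), function(i) {
    tr <- tracks$tracks[[i]]
    if (nrow(tr) < 10L) return(NULL)
    c1 <- classify_growth(tr)
    data.frame(track = i, status = tracks$status[i], n_frames = nrow(tr),
               class = c1$class, circ_slope = c1$circ_slope,
               n_steps = c1$n_steps)
  }))

  gc_summary <- NULL
  conc <- NULL
  chrom_path <- config$inputs$chromatograms_csv %||%
    (if (!is.null(config$phantom)) {
      p <- file.path(config$out_dir %||% tempdir(), "sim", "chromatograms.csv")
      if (file.exists(p)) p else NULL
    })
  if (!is.null(chrom_path) && onset$found) {
    chrom <- utils::read.csv(chrom_path)
    pt <- analyze_chromatograms(chrom)
    conc <- relative_concentrations(pt)
    gc_summary <- onset_window_summary(conc, onset$t_bo)
  }

  onset_table <- data.frame(
    t_bo_s = onset$t_bo, t_bbo_s = onset$t_bbo,
    dose_at_onset_gy = dose_at_onset(onset, config$dose_rate_gy_s),
    dT_bound_water_C = if (onset$found)
      temperature_bound(dose_at_onset(onset, config$dose_rate_gy_s), "water")
      else NA_real_,
    dT_bound_ethanol_C = if (onset$found)
      temperature_bound(dose_at_onset(onset, config$dose_rate_gy_s), "ethanol")
      else NA_real_)

  fit_table <- if (!is.null(fit)) {
    data.frame(alpha = fit$alpha, alpha_se = fit$alpha_se, k = fit$k,
               t_bo_used = fit$t_bo_used, n = fit$n, method = fit$method)
  } else data.frame()

  cfg_plain <- unclass(config)
  report <- structure(list(
    onset = onset_table, growth_fit = fit_table,
    classifications = cls %||% data.frame(),
    volumes = as.data.frame(vs), concentrations = conc,
    gc_summary = gc_summary, log = logmsg,
    truth = truth,
    provenance = list(config_hash = rlang::hash(cfg_plain),
                      seed = config$seed,
                      version = as.character(utils::packageVersion("bubblometry")))
  ), class = "run_report")
  report$report_hash <- rlang::hash(report[c("onset", "growth_fit",
                                             "classifications", "volumes",
                                             "gc_summary")])

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  onset:\n")
  print(x$onset)
  if (nrow(x$growth_fit)) {
    cat("  growth fit:\n"); print(x$growth_fit)
  }
  if (!is.null(x$classifications) && nrow(x$classifications)) {
    cat("  classifications:\n"); print(x$classifications)
  }
  invisible(x)
}

#' Write report tables and manifest
#'
#' @param report A `run_report`.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df))
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  wr(report$onset, "onset")
  wr(report$growth_fit, "growth_fit")
  wr(report$classifications, "classifications")
  wr(report$volumes, "volumes")
  wr(report$concentrations, "concentrations")
  wr(report$gc_summary, "gc_summary")
  manifest <- c(report$provenance,
                list(report_hash = report$report_hash, log = report$log))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the pipeline on a downloaded data deposit
#'
#' The deposited experiment archives (X-ray imaging, gas chromatography,
#' analysis tables) are optional replication inputs that the user must
#' download manually - nothing is fetched automatically. Because the deposit
#' layout is not standardized, a mapping file (JSON) must translate it into
#' this package's inputs: per sample a `stack_dir` (with stack.tif, flats,
#' timestamps) and optionally a `chromatograms_csv`.
#'
#' @param deposit_dir Directory where the deposit was extracted.
#' @param mapping_file JSON file: a named list of samples, each with
#'   `stack_dir` (relative to `deposit_dir`) and optional
#'   `chromatograms_csv`.
#' @param out_dir Output directory for per-sample reports.
#' @param ... Further `run_config` fields applied to every sample.
#' @return Named list of `run_report` objects (per-sample failures are
#'   recorded as error messages, not propagated).
#' @export
replicate_from_deposit <- function(deposit_dir, mapping_file = NULL,
                                   out_dir = NULL, ...) {
  if (!dir.exists(deposit_dir))
    stop_bub(paste0("deposit directory not found: %s\nexpected the extracted ",
                    "archives (X-ray imaging, gas chromatography, analysis ",
                    "tables) downloaded from the public data repository"),
             deposit_dir)
  if (is.null(mapping_file))
    stop_bub(paste0("a mapping file is required: the deposit layout is not ",
                    "standardized; supply a JSON file mapping each sample to ",
                    "a stack_dir and optional chromatograms_csv"))
  if (!file.exists(mapping_file))
    stop_bub("mapping file not found: %s", mapping_file)
  mapping <- jsonlite::read_json(mapping_file, simplifyVector = TRUE)
  if (!length(mapping)) stop_bub("mapping file lists no samples")
  reports <- list()
  for (nm in names(mapping)) {
    entry <- mapping[[nm]]
    cfg <- list(inputs = list(
      stack_dir = file.path(deposit_dir, entry$stack_dir),
      chromatograms_csv = if (!is.null(entry$chromatograms_csv))
        file.path(deposit_dir, entry$chromatograms_csv)),
      out_dir = if (!is.null(out_dir)) file.path(out_dir, nm), ...)
    reports[[nm]] <- tryCatch(run_pipeline(run_config(cfg)),
                              error = function(e) conditionMessage(e))
  }
  reports
}
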