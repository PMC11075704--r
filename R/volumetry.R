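# Beer-Lambert gas volumetry, onset detection and volume bookkeeping.

#' Gas volume from an excess-depth map
#'
#' Direct inversion of the Beer-Lambert law: the drop in optical depth where
#' gas displaces liquid equals `mu_liq` times the gas path length, so
#' `t_gas = dtau / mu_liq` per pixel and the in-field gas volume is the sum
#' of path lengths times the pixel area.
#'
#' @param dtau Excess-depth matrix (NA at masked pixels, treated as 0).
#' @param model An [attenuation_model()].
#' @param pixel_size_um Pixel size, um.
#' @return List: `volume_mm3`, `thickness_mm` (gas path-length map).
#' @export
gas_volume <- function(dtau, model, pixel_size_um) {
  stopifnot(inherits(model, "attenuation_model"))
  if (any(dtau < 0, na.rm = TRUE)) stop_bub("excess depth must be non-negative")
  thick <- dtau / model$mu_liq
  thick[is.na(thick)] <- 0
  ps_mm <- pixel_size_um / 1000
  list(volume_mm3 = sum(thick) * ps_mm^2, thickness_mm = thick)
}

#' Aperture-integrated gas volume
#'
#' Integrates the raw (unfloored, signed) excess depth over the segmented
#' bubble support dilated by a few pixels. Detection on a smoothed, floored
#' map combined with integration of the raw map over the dilated aperture
#' recovers the faint silhouette rim that flooring removes, while zero-mean
#' noise cancels inside the aperture instead of accumulating over the whole
#' field of view.
#'
#' @param dtau_raw Signed excess-depth map (no floor, negatives kept).
#' @param labels Integer label matrix from [segment_frame()] on the
#'   detection map.
#' @param model An [attenuation_model()].
#' @param pixel_size_um Pixel size, um.
#' @param dilate_px Aperture dilation radius, pixels.
#' @return List: `volume_mm3` (total), `per_label` (named vector of
#'   per-component volumes, overlap-free).
#' @export
masked_gas_volume <- function(dtau_raw, labels, model, pixel_size_um,
                              dilate_px = 3L) {
  stopifnot(inherits(model, "attenuation_model"))
  if (!any(labels > 0))
    return(list(volume_mm3 = 0, per_label = numeric(0)))
  brush <- EBImage::makeBrush(2L * dilate_px + 1L, shape = "disc")
  grown <- as.matrix(EBImage::dilate(labels, brush))
  dtau_raw[is.na(dtau_raw)] <- 0
  ps_mm <- pixel_size_um / 1000
  ids <- sort(unique(grown[grown > 0]))
  per <- vapply(ids, function(i) {
    sum(dtau_raw[grown == i]) / model$mu_liq * ps_mm^2
  }, numeric(1))
  names(per) <- ids
  list(volume_mm3 = sum(per), per_label = per)
}

#' Volume series container
#'
#' @param times Frame times, s.
#' @param V Instantaneous in-field gas volume per frame, mm^3.
#' @param V_C Optional cumulative volume (defaults to `V` until
#'   [accumulate_volume()] adds exited bubbles).
#' @param t_ron Radiation-on time, s.
#' @return Data frame of class `volume_series` with columns `time`, `V_mm3`,
#'   `V_C_mm3`.
#' @export
volume_series <- function(times, V, V_C = NULL, t_ron = 0) {
  if (any(diff(times) <= 0)) stop_bub("times must be strictly increasing")
  if (length(V) != length(times)) stop_bub("V and times lengths differ")
  if (any(V < -sqrt(.Machine$double.eps))) stop_bub("V must be non-negative")
  structure(data.frame(time = times, V_mm3 = pmax(V, 0),
                       V_C_mm3 = if (is.null(V_C)) pmax(V, 0) else V_C),
            t_ron = t_ron, class = c("volume_series", "data.frame"))
}

#' Volume of a sphere of given diameter (onset threshold helper)
#' @param diameter_um Sphere diameter, um.
#' @return Volume in mm^3.
#' @export
sphere_volume_mm3 <- function(diameter_um = 100) {
  r_mm <- diameter_um / 2000
  4 / 3 * pi * r_mm^3
}

#' Detect bubble onset
#'
#' Automated surrogate for selecting the first frame with visible bubbles:
#' the earliest time at which the instantaneous volume exceeds
#' `threshold_volume` for at least `persistence` consecutive frames. The
#' default threshold is the volume of a 100 um-diameter sphere (a bubble at
#' the resolution limit) and the default persistence is 3 frames (1 s at 3
#' frames per second).
#'
#' @param vs A [volume_series()].
#' @param threshold_volume mm^3.
#' @param persistence Consecutive frames required.
#' @return Object of class `onset_estimate`: `found`, `t_bo`, `t_bbo`
#'   (= t_bo - t_ron), plus the rule parameters. When the threshold is never
#'   sustained, `found = FALSE` and times are NA (no exception).
#' @export
detect_onset <- function(vs, threshold_volume = sphere_volume_mm3(100),
                         persistence = 3L) {
  stopifnot(inherits(vs, "volume_series"))
  idx <- first_sustained(vs$V_mm3 > threshold_volume, persistence)
  t_ron <- attr(vs, "t_ron") %||% 0
  if (is.na(idx)) {
    return(structure(list(found = FALSE, t_bo = NA_real_, t_bbo = NA_real_,
                          t_ron = t_ron, threshold_volume = threshold_volume,
                          persistence = persistence),
                     class = "onset_estimate"))
  }
  t_bo <- vs$time[idx]
  structure(list(found = TRUE, t_bo = t_bo, t_bbo = t_bo - t_ron,
                 t_ron = t_ron, threshold_volume = threshold_volume,
                 persistence = persistence),
            class = "onset_estimate")
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (x$found)
    cat(sprintf("<onset_estimate> t_bo = %.2f s (t_bbo = %.2f s)\n",
                x$t_bo, x$t_bbo))
  else cat("<onset_estimate> no onset detected\n")
  invisible(x)
}

#' Time after bubble onset
#' @param times Times, s.
#' @param onset An `onset_estimate` or a numeric onset time.
#' @return `times - t_bo`.
#' @export
t_abo <- function(times, onset) {
  t_bo <- if (inherits(onset, "onset_estimate")) onset$t_bo else onset
  times - t_bo
}

#' Cumulative volume including exited bubbles
#'
#' The cumulative volume adds, to the instantaneous in-field volume, the
#' frozen volume of every bubble that has left the field of view up to that
#' time. With an onset supplied, the cumulative series is defined as zero
#' before onset.
#'
#' @param vs A [volume_series()].
#' @param exits Data frame with columns `time` and `volume_mm3` (one row per
#'   exited bubble); an empty or NULL ledger leaves `V_C = V`.
#' @param onset Optional `onset_estimate` or numeric time. When supplied,
#'   both series are defined as zero before onset: no bubbles exist yet, so
#'   pre-onset measurements are noise by definition.
#' @return The series with `V_C_mm3` filled in.
#' @export
accumulate_volume <- function(vs, exits = NULL, onset = NULL) {
  stopifnot(inherits(vs, "volume_series"))
  vc <- vs$V_mm3
  if (!is.null(exits) && nrow(exits)) {
    if (any(exits$time < min(vs$time) | exits$time > max(vs$time)))
      stop_bub("exit times outside the series range")
    vc <- vc + vapply(vs$time, function(t) {
      sum(exits$volume_mm3[exits$time <= t])
    }, numeric(1))
  }
  if (!is.null(onset)) {
    t_bo <- if (inherits(onset, "onset_estimate")) onset$t_bo else onset
    if (!is.na(t_bo)) {
      vc[vs$time < t_bo] <- 0
      vs$V_mm3[vs$time < t_bo] <- 0
    }
  }
  vs$V_C_mm3 <- vc
  vs
}

#' Excess cumulative volume between two samples
#'
#' Re-bases two cumulative series to their own onsets, resamples them onto a
#' common time-after-onset grid, and returns the difference (first minus
#' second; order the arguments as non-degassed minus degassed to reproduce
#' the positive excess of non-degassed samples).
#'
#' @param vs1,vs2 [volume_series()] objects with `V_C_mm3` filled.
#' @param onset1,onset2 Their onsets (`onset_estimate` or numeric).
#' @param min_overlap_s Minimum common coverage, s.
#' @return Data frame: `t_abo`, `delta_mm3`, `V_C1_mm3`, `V_C2_mm3`.
#' @export
excess_volume <- function(vs1, vs2, onset1, onset2, min_overlap_s = 60) {
  tb1 <- if (inherits(onset1, "onset_estimate")) onset1$t_bo else onset1
  tb2 <- if (inherits(onset2, "onset_estimate")) onset2$t_bo else onset2
  if (is.na(tb1) || is.na(tb2)) stop_bub("both series need a detected onset")
  a1 <- vs1$time - tb1
  a2 <- vs2$time - tb2
  lo <- max(min(a1), min(a2), 0)
  hi <- min(max(a1), max(a2))
  if (hi - lo < min_overlap_s)
    stop_bub("post-onset overlap %.1f s is shorter than %.1f s", hi - lo,
             min_overlap_s)
  dt <- stats::median(diff(vs1$time))
  grid <- seq(lo, hi, by = dt)
  y1 <- approx(a1, vs1$V_C_mm3, xout = grid)$y
  y2 <- approx(a2, vs2$V_C_mm3, xout = grid)$y
  data.frame(t_abo = grid, delta_mm3 = y1 - y2, V_C1_mm3 = y1, V_C2_mm3 = y2)
}

#' Per-frame volume series from segmented stacks
#'
#' Convenience wrapper: sums `dtau / mu_liq * pixel_area` over each frame of
#' a list of excess-depth maps.
#'
#' @param dtau_list List of excess-depth matrices.
#' @param times Frame times, s.
#' @param model An [attenuation_model()].
#' @param pixel_size_um Pixel size, um.
#' @return A [volume_series()].
#' @export
volume_series_from_maps <- function(dtau_list, times, model, pixel_size_um) {
  V <- vapply(dtau_list, function(m) gas_volume(m, model, pixel_size_um)$volume_mm3,
              numeric(1))
  volume_series(times, V)
}
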