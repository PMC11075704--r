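# Micro-gas-chromatogram analysis: baseline correction, peak integration and
# onset-aligned relative-concentration summaries.
#
# Four detection modules (MS5A, PDMS5, PDMS10, PPU) elute once per ~2.4 min
# cycle. Species are quantified from MS5A (N2, O2) and PDMS10 (EtOH, H2O and
# a combined N2+O2 peak); the other modules are ingested but not quantified
# by default.

#' Baseline-correct a chromatogram trace
#'
#' Morphological-opening baseline: a rolling minimum followed by a rolling
#' maximum over `window` points (which removes any peak narrower than the
#' window while reproducing slow drifts, including linear ramps, exactly),
#' smoothed by a rolling mean; iterated. The estimate is subtracted from the
#' signal.
#'
#' @param signal Detector trace.
#' @param window Window width in samples; should exceed the widest peak
#'   support and must not exceed the trace length.
#' @param n_iter Iterations.
#' @return List: `corrected`, `baseline`.
#' @export
correct_baseline <- function(signal, window = 81L, n_iter = 2L) {
  n <- length(signal)
  if (window <= 0) stop_bub("window must be positive")
  if (window > n)
    stop_bub("baseline window (%d) exceeds trace length (%d)", window, n)
  roll <- function(x, f) {
    half <- window %/% 2L
    xp <- c(rep(x[1], half), x, rep(x[n], half))
    vapply(seq_len(n), function(i) f(xp[i:(i + 2L * half)]), numeric(1))
  }
  base <- signal
  for (i in seq_len(n_iter)) base <- roll(roll(roll(base, min), max), mean)
  list(corrected = signal - base, baseline = base)
}

#' Detect and integrate peaks in a corrected trace
#'
#' Local maxima above `k_sigma` times the trace noise (robustly estimated
#' from first differences) are matched to the nearest reference retention
#' time within `tolerance_s`; the area is the trapezoidal integral over the
#' contiguous above-baseline support around the apex, taken above the chord
#' joining the support endpoints (a local linear baseline that absorbs any
#' residual drift the global correction missed). When two maxima match one
#' reference the larger area is kept and flagged ambiguous.
#'
#' @param rt_s Retention-time axis, strictly increasing, s.
#' @param signal Baseline-corrected signal.
#' @param reference Data frame with `species`, `rt_s` for this module.
#' @param tolerance_s Assignment tolerance, s.
#' @param k_sigma Detection threshold in noise sigmas.
#' @param min_rel_height Candidate maxima must also reach this fraction of
#'   the tallest peak in the trace; rejects residual-baseline bumps that
#'   clear the noise threshold but would otherwise steal watershed bounds or
#'   reference assignments from genuine peaks.
#' @return Data frame (`peak_table`): `species` (`"unassigned"` for unmatched
#'   peaks), `rt_apex_s`, `area`, `ambiguous`.
#' @export
integrate_peaks <- function(rt_s, signal, reference, tolerance_s = 5,
                            k_sigma = 5, min_rel_height = 0.05) {
  if (any(diff(rt_s) <= 0)) stop_bub("retention times must strictly increase")
  sigma <- stats::mad(diff(signal)) / sqrt(2)
  floor_level <- max(3 * sigma, .Machine$double.eps)
  pk <- pracma::findpeaks(signal, minpeakheight = max(k_sigma * sigma, 0),
                          minpeakdistance = 3L)
  empty <- data.frame(species = character(0), rt_apex_s = numeric(0),
                      area = numeric(0), ambiguous = logical(0))
  if (is.null(pk)) return(empty)
  pk <- pk[pk[, 1] >= min_rel_height * max(pk[, 1]), , drop = FALSE]
  apexes <- sort(pk[, 2])
  # each support expands to the floor crossing but never past the midpoint
  # toward an adjacent apex (watershed bound), so neighbouring peaks whose
  # valley rides above the floor still integrate separately
  peaks <- do.call(rbind, lapply(seq_along(apexes), function(i) {
    apex <- apexes[i]
    lo_lim <- if (i > 1L) floor((apex + apexes[i - 1L]) / 2) + 1L else 1L
    hi_lim <- if (i < length(apexes)) floor((apex + apexes[i + 1L]) / 2)
              else length(signal)
    lo <- apex; while (lo > lo_lim && signal[lo - 1L] > floor_level) lo <- lo - 1L
    hi <- apex; while (hi < hi_lim && signal[hi + 1L] > floor_level) hi <- hi + 1L
    chord <- (signal[lo] + signal[hi]) / 2 * (rt_s[hi] - rt_s[lo])
    data.frame(rt_apex_s = rt_s[apex],
               area = max(pracma::trapz(rt_s[lo:hi], signal[lo:hi]) - chord, 0),
               lo = lo, hi = hi)
  }))

  peaks$species <- "unassigned"
  peaks$ambiguous <- FALSE
  for (i in seq_len(nrow(reference))) {
    d <- abs(peaks$rt_apex_s - reference$rt_s[i])
    cand <- which(d <= tolerance_s)
    if (!length(cand)) next
    if (length(cand) > 1L) {
      keep <- cand[which.max(peaks$area[cand])]
      peaks$ambiguous[keep] <- TRUE
    } else keep <- cand
    peaks$species[keep] <- reference$species[i]
  }
  peaks[, c("species", "rt_apex_s", "area", "ambiguous")]
}

#' Peak tables for every module and cycle of a chromatogram set
#'
#' Runs baseline correction and peak integration on each (module, cycle)
#' trace of a long chromatogram table.
#'
#' @param chrom A `chromatogram_set` (long data frame with `module`, `cycle`,
#'   `cycle_time_s`, `rt_s`, `signal`).
#' @param reference Reference retention times ([gc_reference_default()]).
#'   Modules absent from the reference are skipped unless
#'   `report_unreferenced = TRUE`, in which case their peaks are reported
#'   unassigned.
#' @param baseline_window Samples, for [correct_baseline()].
#' @param tolerance_s,k_sigma Passed to [integrate_peaks()].
#' @param report_unreferenced Also report peaks of modules without reference
#'   entries.
#' @return Data frame: `module`, `cycle`, `cycle_time_s`, `species`,
#'   `rt_apex_s`, `area`, `ambiguous`.
#' @export
analyze_chromatograms <- function(chrom, reference = gc_reference_default(),
                                  baseline_window = 81L, tolerance_s = 5,
                                  k_sigma = 5, report_unreferenced = FALSE) {
  mods <- unique(chrom$module)
  if (!report_unreferenced) mods <- intersect(mods, unique(reference$module))
  out <- list()
  for (mod in mods) {
    ref <- reference[reference$module == mod, , drop = FALSE]
    for (cy in unique(chrom$cycle[chrom$module == mod])) {
      tr <- chrom[chrom$module == mod & chrom$cycle == cy, ]
      corr <- correct_baseline(tr$signal, window = baseline_window)$corrected
      pt <- integrate_peaks(tr$rt_s, corr, ref, tolerance_s, k_sigma)
      if (nrow(pt))
        out[[length(out) + 1L]] <- cbind(module = mod, cycle = cy,
                                         cycle_time_s = tr$cycle_time_s[1], pt)
    }
  }
  if (!length(out))
    return(data.frame(module = character(0), cycle = integer(0),
                      cycle_time_s = numeric(0), species = character(0),
                      rt_apex_s = numeric(0), area = numeric(0),
                      ambiguous = logical(0)))
  do.call(rbind, out)
}

#' Relative concentrations per module and cycle
#'
#' Normalizes assigned peak areas within each (module, cycle): the fraction
#' of each species is its area over the summed assigned area of that
#' module's cycle (0-1 scale). Cycles whose assigned area is zero are
#' flagged and get NA fractions.
#'
#' @param peak_tables Output of [analyze_chromatograms()].
#' @return Data frame of class `concentration_series`: `module`, `species`,
#'   `cycle`, `cycle_time_s`, `fraction`, `flagged`.
#' @export
relative_concentrations <- function(peak_tables) {
  pt <- peak_tables[peak_tables$species != "unassigned", , drop = FALSE]
  out <- list()
  for (mod in unique(pt$module)) {
    for (cy in unique(pt$cycle[pt$module == mod])) {
      rows <- pt[pt$module == mod & pt$cycle == cy, ]
      total <- sum(rows$area)
      flagged <- !is.finite(total) || total <= 0
      out[[length(out) + 1L]] <- data.frame(
        module = mod, species = rows$species, cycle = cy,
        cycle_time_s = rows$cycle_time_s,
        fraction = if (flagged) NA_real_ else rows$area / total,
        flagged = flagged)
    }
  }
  structure(do.call(rbind, out),
            class = c("concentration_series", "data.frame"))
}

#' Onset-aligned window summary of relative concentrations
#'
#' Reports each species' relative concentration at fixed offsets around the
#' bubble onset (6 min and 3 min before; 5 min and 10 min after, by
#' default), using the nearest elution cycle within half a cycle period (the
#' 2.4 min cycle is the series' native resolution - no interpolation).
#' A species is classified `increasing` if its post-onset mean exceeds the
#' pre-onset mean by more than the cycle-to-cycle noise sigma (estimated
#' from the pre-onset cycles), `decreasing` below `-sigma`, else
#' `unchanged`.
#'
#' @param conc A `concentration_series`.
#' @param t_bo Bubble onset time, s.
#' @param offsets_s Offsets relative to onset, s.
#' @param cycle_period_s Elution cycle period, s.
#' @param pre_window_s,post_window_s Extent of the pre-/post-onset means, s.
#' @return Data frame: one row per module/species with `value_at_<offset>`
#'   columns (NA when the offset is outside coverage), `pre_mean`,
#'   `post_mean`, `diff`, `sigma`, `classification`.
#' @export
onset_window_summary <- function(conc, t_bo,
                                 offsets_s = c(-360, -180, 300, 600),
                                 cycle_period_s = 144,
                                 pre_window_s = 600, post_window_s = 600) {
  stopifnot(inherits(conc, "concentration_series"))
  out <- list()
  for (mod in unique(conc$module)) {
    for (sp in unique(conc$species[conc$module == mod])) {
      s <- conc[conc$module == mod & conc$species == sp & !conc$flagged, ]
      s <- s[order(s$cycle_time_s), ]
      vals <- vapply(offsets_s, function(off) {
        target <- t_bo + off
        i <- which.min(abs(s$cycle_time_s - target))
        if (!length(i) || abs(s$cycle_time_s[i] - target) > cycle_period_s / 2)
          NA_real_ else s$fraction[i]
      }, numeric(1))
      pre_all <- s$fraction[s$cycle_time_s < t_bo]
      pre <- s$fraction[s$cycle_time_s < t_bo &
                          s$cycle_time_s >= t_bo - pre_window_s]
      post <- s$fraction[s$cycle_time_s > t_bo &
                           s$cycle_time_s <= t_bo + post_window_s]
      sigma <- if (length(pre_all) >= 2L) stats::sd(pre_all) else NA_real_
      dmean <- mean(post) - mean(pre)
      cls <- if (!is.finite(sigma) || !is.finite(dmean)) NA_character_
      else if (dmean > sigma) "increasing"
      else if (dmean < -sigma) "decreasing"
      else "unchanged"
      row <- data.frame(module = mod, species = sp,
                        pre_mean = mean(pre), post_mean = mean(post),
                        diff = dmean, sigma = sigma, classification = cls)
      for (j in seq_along(offsets_s))
        row[[sprintf("value_at_%+ds", offsets_s[j])]] <- vals[j]
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
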