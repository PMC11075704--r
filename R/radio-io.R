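# Radiograph stack I/O, flat-field correction and context subtraction.
#
# The chain radiograph -> transmission -> optical depth -> excess depth is the
# inverse of the rendering model: T = (I - dark)/(flat - dark), tau = -ln T,
# and the gas signal is the drop of tau below the pre-onset agar/tissue
# context, Delta-tau = tau_ref - tau.

#' Read a radiograph stack from disk
#'
#' Expects the layout written by [write_stack()] / [simulate_phantom_run()]:
#' a multi-page `stack.tif`, `flats.tif`, optional `darks.tif`, a
#' `timestamps.csv` with one row per frame, and optional `meta.json` with the
#' intensity full scale and pixel size.
#'
#' @param path Directory containing the stack files.
#' @param pixel_size_um Pixel size override if no `meta.json` is present.
#' @return A `radiograph_stack` object.
#' @export
read_stack <- function(path, pixel_size_um = NULL) {
  f_stack <- file.path(path, "stack.tif")
  f_flats <- file.path(path, "flats.tif")
  f_times <- file.path(path, "timestamps.csv")
  for (f in c(f_stack, f_flats, f_times))
    if (!file.exists(f)) stop_bub("missing input file: %s", f)
  meta_file <- file.path(path, "meta.json")
  meta <- if (file.exists(meta_file)) jsonlite::read_json(meta_file) else list()
  scale <- meta$full_scale %||% 1
  ps <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(ps)) stop_bub("pixel size not given and absent from meta.json")

  as_frames <- function(x) if (is.list(x)) x else list(x)
  frames <- lapply(as_frames(tiff::readTIFF(f_stack, all = TRUE)),
                   function(m) m * scale)
  flats <- lapply(as_frames(tiff::readTIFF(f_flats, all = TRUE)),
                  function(m) m * scale)
  darks <- if (file.exists(file.path(path, "darks.tif"))) {
    lapply(as_frames(tiff::readTIFF(file.path(path, "darks.tif"), all = TRUE)),
           function(m) m * scale)
  } else list()

  ts <- utils::read.csv(f_times)
  if (nrow(ts) != length(frames))
    stop_bub(paste0("timestamps.csv has %d rows but stack.tif has %d frames; ",
                    "first unmatched frame index: %d"),
             nrow(ts), length(frames), min(nrow(ts), length(frames)))
  if (any(diff(ts$time_s) <= 0)) stop_bub("frame times must strictly increase")
  dims <- vapply(c(frames, flats, darks), dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_bub("all frames, flats and darks must share one shape")
  structure(list(frames = frames, times = ts$time_s,
                 pixel_size_um = as.numeric(ps), flats = flats, darks = darks,
                 meta = list(frame_rate = meta$frame_rate %||% NA_real_)),
            class = "radiograph_stack")
}

#' @export
print.radiograph_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<radiograph_stack> %d frames of %d x %d px, %.0f um px, t = %.2f..%.2f s\n",
              length(x$frames), d[1], d[2], x$pixel_size_um,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Flat-field correction
#'
#' Converts detector counts to transmission. The static method divides by the
#' mean flat after mean-dark subtraction. The dynamic method tracks slow
#' illumination drifts: on a bubble-free border region it first removes the
#' static sample attenuation (the per-pixel time-median of the
#' frame-to-mean-flat ratio), then fits the remaining per-frame variation as
#' the best non-negative combination of the recorded flats' illumination
#' patterns (equivalently, non-negative loadings on their principal
#' components), and divides each frame by its fitted flat.
#'
#' @param stack A `radiograph_stack` with at least one flat; darks are
#'   assumed zero if absent.
#' @param method `"static"` (default) or `"dynamic"`.
#' @param border_px Width of the left/right border strips used to fit the
#'   dynamic illumination (bubbles nucleate away from the lateral edges;
#'   the sample there must be static over the sequence).
#' @return Object of class `transmission_stack`: `frames` (transmission
#'   matrices), `times`, `pixel_size_um`, `mask` (TRUE where flat - dark <= 0,
#'   i.e. uninformative pixels).
#' @export
flat_field_correct <- function(stack, method = c("static", "dynamic"),
                               border_px = 8L) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "radiograph_stack"))
  if (length(stack$flats) < 1L) stop_bub("at least one flat field is required")
  dark <- if (length(stack$darks)) Reduce(`+`, stack$darks) / length(stack$darks)
          else 0
  mean_flat <- Reduce(`+`, stack$flats) / length(stack$flats)
  denom0 <- mean_flat - dark
  mask <- denom0 <= 0
  if (all(mask)) stop_bub("flat - dark is non-positive everywhere")

  if (method == "static") {
    frames <- lapply(stack$frames, function(I) {
      T <- (I - dark) / denom0
      T[mask] <- NA_real_
      T
    })
  } else {
    d <- dim(stack$frames[[1]])
    cols <- unique(c(seq_len(min(border_px, d[2])),
                     seq.int(max(1L, d[2] - border_px + 1L), d[2])))
    sel <- as.numeric(matrix(seq_len(prod(d)), d[1], d[2])[, cols])
    sel <- sel[!mask[sel]]
    mf <- as.numeric(denom0)
    # illumination patterns of the recorded flats, relative to the mean flat
    A <- vapply(stack$flats, function(f) (as.numeric(f - dark) / mf)[sel],
                numeric(length(sel)))
    A_full <- vapply(stack$flats, function(f) as.numeric(f - dark) / mf,
                     numeric(prod(d)))
    # static sample factor on the border: per-pixel median ratio over time
    R <- vapply(stack$frames, function(I) (as.numeric(I - dark) / mf)[sel],
                numeric(length(sel)))
    s_px <- apply(R, 1L, stats::median)
    ok <- s_px > 0
    frames <- lapply(seq_along(stack$frames), function(fi) {
      y <- R[ok, fi] / s_px[ok]
      cf <- pracma::lsqnonneg(A[ok, , drop = FALSE], y)$x
      flat_i <- matrix(mf * as.numeric(A_full %*% cf), d[1], d[2])
      bad <- mask | flat_i <= 0
      T <- (stack$frames[[fi]] - dark) / flat_i
      T[bad] <- NA_real_
      T
    })
  }
  structure(list(frames = frames, times = stack$times,
                 pixel_size_um = stack$pixel_size_um, mask = mask,
                 method = method),
            class = "transmission_stack")
}

#' Build the agar/tissue context map
#'
#' The reference optical depth of everything that is not gas: per-pixel
#' median of `-ln T` over a pre-onset window. Masked pixels propagate.
#'
#' @param tstack A `transmission_stack`.
#' @param window Frame indices to use; must contain at least 5 frames.
#' @param onset_time Optional declared/detected onset (s); an error is raised
#'   if the window reaches it.
#' @return Object of class `context_map`: `tau_ref` matrix, `n_frames_used`,
#'   `mask`, `method`.
#' @export
build_context <- function(tstack, window = NULL, onset_time = NULL) {
  stopifnot(inherits(tstack, "transmission_stack"))
  if (is.null(window)) window <- seq_along(tstack$frames)
  if (length(window) < 5L)
    stop_bub("context window must contain at least 5 frames (got %d)",
             length(window))
  if (!is.null(onset_time) && any(tstack$times[window] >= onset_time))
    stop_bub("context window overlaps bubble onset at %.1f s", onset_time)
  taus <- vapply(tstack$frames[window],
                 function(T) as.numeric(-log(pmax(T, .Machine$double.eps))),
                 numeric(length(tstack$frames[[1]])))
  tau_ref <- matrix(apply(taus, 1L, stats::median), nrow(tstack$frames[[1]]))
  tau_ref[tau_ref < 0] <- 0
  tau_ref[tstack$mask] <- NA_real_
  structure(list(tau_ref = tau_ref, n_frames_used = length(window),
                 mask = tstack$mask, method = "static_median"),
            class = "context_map")
}

#' Excess optical depth of gas
#'
#' `Delta-tau = tau_ref - tau`, positive where gas displaces liquid. Values
#' below the noise floor are set to zero; negative excursions (denser than
#' the reference) are clipped to zero and counted.
#'
#' @param tau Optical-depth frame (matrix, `-ln T`), or a transmission frame
#'   via `from_transmission = TRUE`.
#' @param context A `context_map`.
#' @param noise_floor Threshold below which excess depth is zeroed (same
#'   units as tau). See [estimate_noise_floor()].
#' @param smooth_sigma Gaussian pre-smoothing of the excess map, pixels;
#'   0 disables.
#' @param from_transmission Interpret `tau` as transmission and take `-ln`.
#' @param clip_negative Clip negative excursions to zero (the default rule:
#'   bubbles only reduce optical depth). Aperture volume integration uses
#'   `clip_negative = FALSE` so that zero-mean noise cancels within the
#'   integration mask.
#' @return List: `dtau` matrix (NA at masked pixels), `n_clipped_negative`.
#' @export
excess_depth <- function(tau, context, noise_floor = 0, smooth_sigma = 0,
                         from_transmission = FALSE, clip_negative = TRUE) {
  stopifnot(inherits(context, "context_map"))
  if (from_transmission) tau <- -log(pmax(tau, .Machine$double.eps))
  if (!all(dim(tau) == dim(context$tau_ref)))
    stop_bub("frame and context shapes differ")
  dtau <- context$tau_ref - tau
  na_mask <- context$mask | is.na(dtau)
  dtau[na_mask] <- 0
  if (smooth_sigma > 0) dtau <- gauss_blur(dtau, smooth_sigma)
  n_neg <- sum(dtau < 0)
  if (clip_negative) {
    dtau[dtau < 0] <- 0
    dtau[dtau < noise_floor] <- 0
  } else {
    dtau[abs(dtau) < noise_floor] <- 0
  }
  dtau[na_mask] <- NA_real_
  list(dtau = dtau, n_clipped_negative = n_neg)
}

#' Estimate the excess-depth noise floor
#'
#' Robust per-pixel noise of the context-subtracted optical depth, estimated
#' from pre-onset frames: the median absolute deviation (scaled to sigma) of
#' the smoothed residuals `tau_ref - tau`, pooled over pixels and frames.
#' The default floor is `k_sigma` times this sigma.
#'
#' @param tstack A `transmission_stack`.
#' @param context A `context_map` built from pre-onset frames.
#' @param window Pre-onset frame indices to pool (default: all frames).
#' @param smooth_sigma Same smoothing that will be applied in
#'   [excess_depth()].
#' @param k_sigma Multiplier for the returned floor.
#' @return List: `sigma`, `floor`.
#' @export
estimate_noise_floor <- function(tstack, context, window = NULL,
                                 smooth_sigma = 0, k_sigma = 3) {
  if (is.null(window)) window <- seq_along(tstack$frames)
  res <- unlist(lapply(tstack$frames[window], function(T) {
    d <- context$tau_ref + log(pmax(T, .Machine$double.eps))
    d[context$mask] <- NA_real_
    if (smooth_sigma > 0) d <- gauss_blur(d, smooth_sigma)
    as.numeric(d)
  }))
  sigma <- stats::mad(res, na.rm = TRUE)
  list(sigma = sigma, floor = k_sigma * sigma)
}

#' Write excess-depth maps as 32-bit float TIFF
#'
#' @param dtau_list List of excess-depth matrices.
#' @param path Output file (`.tif`).
#' @param diagnostics Optional list written alongside as JSON
#'   (`<path>.diagnostics.json`).
#' @return `path`, invisibly.
#' @export
write_depth_maps <- function(dtau_list, path, diagnostics = NULL) {
  tiff::writeTIFF(lapply(dtau_list, function(m) {
    m[is.na(m)] <- 0
    m
  }), path, bits.per.sample = 32L, reduce = FALSE)
  if (!is.null(diagnostics))
    jsonlite::write_json(diagnostics, paste0(path, ".diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
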