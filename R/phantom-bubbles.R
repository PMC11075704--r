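# Bubble evolution: geometry per frame plus the ground-truth ledger.
#
# Three growth laws produce the silhouettes the shape analysis is calibrated
# against: square-root radial growth of a free sphere (projected area linear
# in time after nucleation), bidirectional capsule elongation at fixed radius
# inside a vessel, and sequential filling of tangent spherical compartments
# with dwell times (stepped plateaus).

# ---- analytic silhouette / volume formulas ----------------------------------

sphere_metrics <- function(r) {
  list(area = pi * r^2, perim = 2 * pi * r, vol = 4 / 3 * pi * r^3)
}

# Stadium silhouette of a capsule: straight length L (total), cap radius r.
capsule_metrics <- function(r, L) {
  list(area = pi * r^2 + 2 * r * L,
       perim = 2 * pi * r + 2 * L,
       vol = 4 / 3 * pi * r^3 + pi * r^2 * L)
}

# Union of k tangent spheres of radius r.
alveolar_metrics <- function(r, k) {
  list(area = k * pi * r^2, perim = k * 2 * pi * r, vol = k * 4 / 3 * pi * r^3)
}

# ---- per-time shape of one seed ---------------------------------------------

seed_shape <- function(seed, t, phantom = NULL) {
  dt <- t - seed$nucleation_time
  if (dt <= 0) return(NULL)
  cy <- seed$site[2] - seed$rise_velocity_mm_s * dt
  if (seed$law == "diffusion") {
    r <- seed$rate * sqrt(dt)
    m <- sphere_metrics(r)
    shp <- list(id = NA_integer_, type = "sphere",
                cx = seed$site[1], cy = cy, r = r)
  } else if (seed$law == "vessel") {
    r <- seed$radius_mm
    half <- seed$rate * dt
    clipped <- FALSE
    if (!is.null(phantom)) {
      half_max <- max(0, min(seed$site[1], phantom$spec$fov_mm[1] - seed$site[1]) - r)
      if (half > half_max) { half <- half_max; clipped <- TRUE }
    }
    m <- capsule_metrics(r, 2 * half)
    shp <- list(id = NA_integer_, type = "capsule", cx = seed$site[1], cy = cy,
                r = r, half_len = half, clipped = clipped)
  } else { # alveolar
    r <- seed$radius_mm
    k_want <- 1L + floor(dt / seed$rate)
    centers <- alveolar_chain(seed, phantom)
    k <- min(k_want, nrow(centers), seed$n_compartments)
    m <- alveolar_metrics(r, k)
    shp <- list(id = NA_integer_, type = "spheres",
                centers = centers[seq_len(k), , drop = FALSE], r = r,
                clipped = k_want > k)
  }
  shp$metrics <- m
  shp
}

# Compartment chain for an alveolar seed: nearest phantom compartments to the
# nucleation site, or a horizontal chain of tangent compartments if no
# phantom is supplied.
alveolar_chain <- function(seed, phantom) {
  if (!is.null(phantom) && !is.null(phantom$compartments)) {
    cc <- phantom$compartments
    ord <- order((cc$x - seed$site[1])^2 + (cc$y - seed$site[2])^2)
    cc[ord, c("x", "y"), drop = FALSE]
  } else {
    data.frame(x = seed$site[1] + 2 * seed$radius_mm * (seq_len(seed$n_compartments) - 1L),
               y = seed$site[2])
  }
}

# ---- evolution --------------------------------------------------------------

#' Evolve bubbles and build the ground-truth ledger
#'
#' Evaluates each seed's growth law at every sampled time, applies scripted
#' exits and upward migration, and records the exact per-bubble silhouette
#' area/perimeter and 3D gas volume.
#'
#' @param seeds List of [bubble_seed()] objects.
#' @param times Strictly increasing frame times, s (t = 0 at radiation-on).
#' @param phantom Optional [build_phantom()] result used to confine growth
#'   (vessel extent, alveolar compartment positions). Bubbles escaping their
#'   confinement are clipped and counted in the `clips` attribute.
#' @return Object of class `bubble_evolution`: `times`, `frames` (per-frame
#'   shape lists), `ledger` (per frame per bubble), `totals` (per-frame true
#'   instantaneous `V_mm3` and cumulative `V_C_mm3`), `exits` (id, time,
#'   frozen volume), `onset_time` (earliest nucleation), `clips`.
#' @export
evolve_bubbles <- function(seeds, times, phantom = NULL) {
  if (inherits(seeds, "bubble_seed")) seeds <- list(seeds)
  stopifnot(all(vapply(seeds, inherits, logical(1), "bubble_seed")))
  if (any(diff(times) <= 0)) stop_bub("times must be strictly increasing")
  fov <- if (!is.null(phantom)) phantom$spec$fov_mm else NULL

  n_clip <- 0L
  exits <- data.frame(id = integer(0), time = numeric(0), volume_mm3 = numeric(0))
  exited_at <- rep(NA_real_, length(seeds))
  frozen_vol <- rep(NA_real_, length(seeds))
  frames <- vector("list", length(times))
  rows <- list()

  for (fi in seq_along(times)) {
    t <- times[fi]
    shapes <- list()
    for (si in seq_along(seeds)) {
      sd <- seeds[[si]]
      if (!is.na(exited_at[si])) next
      exit_now <- FALSE
      if (!is.na(sd$exit_time) && t >= sd$exit_time) exit_now <- TRUE
      shp <- seed_shape(sd, t, phantom)
      if (is.null(shp)) next
      # migration out of the top edge counts as an exit once fully out
      top_extent <- shape_top_extent(shp)
      if (!exit_now && !is.null(fov) && sd$rise_velocity_mm_s > 0 &&
          top_extent < 0) exit_now <- TRUE
      if (exit_now) {
        t_exit <- if (!is.na(sd$exit_time)) min(t, sd$exit_time) else t
        shp_exit <- seed_shape(sd, t_exit, phantom)
        exited_at[si] <- t_exit
        frozen_vol[si] <- shp_exit$metrics$vol
        exits <- rbind(exits, data.frame(id = si, time = t_exit,
                                         volume_mm3 = shp_exit$metrics$vol))
        next
      }
      if (isTRUE(shp$clipped)) n_clip <- n_clip + 1L
      shp$id <- si
      shapes[[length(shapes) + 1L]] <- shp
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fi, time = t, id = si, status = "active",
        area_mm2 = shp$metrics$area, perimeter_mm = shp$metrics$perim,
        volume_mm3 = shp$metrics$vol)
    }
    frames[[fi]] <- shapes
  }

  ledger <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), time = numeric(0), id = integer(0),
               status = character(0), area_mm2 = numeric(0),
               perimeter_mm = numeric(0), volume_mm3 = numeric(0))
  V <- vapply(seq_along(times), function(fi) {
    sum(ledger$volume_mm3[ledger$frame == fi])
  }, numeric(1))
  V_exited <- vapply(times, function(t) {
    sum(exits$volume_mm3[exits$time <= t])
  }, numeric(1))
  totals <- data.frame(frame = seq_along(times), time = times,
                       V_mm3 = V, V_C_mm3 = V + V_exited)
  onset <- min(vapply(seeds, function(s) s$nucleation_time, numeric(1)))
  structure(list(times = times, frames = frames, ledger = ledger,
                 totals = totals, exits = exits, onset_time = onset,
                 clips = n_clip, phantom = phantom),
            class = "bubble_evolution")
}

shape_top_extent <- function(shp) {
  switch(shp$type,
         sphere = shp$cy + shp$r,
         capsule = shp$cy + shp$r,
         spheres = max(shp$centers$y) + shp$r)
}

#' @export
print.bubble_evolution <- function(x, ...) {
  cat(sprintf("<bubble_evolution> %d frames, %d bubbles, %d exits, onset %.1f s\n",
              length(x$times), length(unique(x$ledger$id)), nrow(x$exits),
              x$onset_time))
  invisible(x)
}

# ---- rasterization ----------------------------------------------------------

# Beam-path length of gas (mm) through all shapes, on the phantom pixel grid.
# Shapes are treated as lying at mid-container depth with an orthographic
# parallel-beam projection, so depth does not alter the chord lengths.
gas_path_map <- function(shapes, grid) {
  tg <- matrix(0, grid$ny, grid$nx)
  for (shp in shapes) {
    if (shp$type == "sphere") {
      tg <- tg + sphere_chords(grid, shp$cx, shp$cy, shp$r)
    } else if (shp$type == "capsule") {
      tg <- tg + capsule_chords(grid, shp$cx, shp$cy, shp$r, shp$half_len)
    } else {
      for (i in seq_len(nrow(shp$centers)))
        tg <- tg + sphere_chords(grid, shp$centers$x[i], shp$centers$y[i], shp$r)
    }
  }
  tg
}

sphere_chords <- function(grid, cx, cy, r) {
  m <- matrix(0, grid$ny, grid$nx)
  jx <- which(abs(grid$x - cx) <= r)
  jy <- which(abs(grid$y - cy) <= r)
  if (!length(jx) || !length(jy)) return(m)
  d2 <- outer((grid$y[jy] - cy)^2, (grid$x[jx] - cx)^2, `+`)
  ch <- 2 * sqrt(pmax(r^2 - d2, 0))
  m[jy, jx] <- ch
  m
}

capsule_chords <- function(grid, cx, cy, r, half_len) {
  m <- matrix(0, grid$ny, grid$nx)
  jy <- which(abs(grid$y - cy) <= r)
  if (!length(jy)) return(m)
  dy2 <- (grid$y[jy] - cy)^2
  # cylindrical barrel
  jx <- which(abs(grid$x - cx) <= half_len)
  if (length(jx)) m[jy, jx] <- matrix(2 * sqrt(pmax(r^2 - dy2, 0)),
                                      length(jy), length(jx))
  # hemispherical caps (spherical chords beyond the barrel ends)
  for (sgn in c(-1, 1)) {
    ccx <- cx + sgn * half_len
    jxc <- which(abs(grid$x - ccx) <= r &
                   sgn * (grid$x - cx) > half_len - 1e-12)
    if (!length(jxc)) next
    d2 <- outer(dy2, (grid$x[jxc] - ccx)^2, `+`)
    m[jy, jxc] <- pmax(m[jy, jxc], 2 * sqrt(pmax(r^2 - d2, 0)))
  }
  m
}
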