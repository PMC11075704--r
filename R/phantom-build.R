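# Static phantom construction: background optical depth and microstructure.

pixel_grid <- function(spec) {
  ps_mm <- spec$pixel_size_um / 1000
  nx <- round(spec$fov_mm[1] / ps_mm)
  ny <- round(spec$fov_mm[2] / ps_mm)
  list(nx = nx, ny = ny, ps_mm = ps_mm,
       x = (seq_len(nx) - 0.5) * ps_mm,   # columns, mm
       y = (seq_len(ny) - 0.5) * ps_mm)   # rows, mm (0 at top edge)
}

# Smooth random context texture: a few broad Gaussian bumps, deterministic in
# the spec seed. Emulates the slowly varying agar/tissue absorption profile
# that context subtraction must remove.
context_texture <- function(grid, amplitude, seed) {
  if (amplitude <= 0) return(matrix(0, grid$ny, grid$nx))
  local_seed(seed + 104729L, {
    n_bump <- 8L
    cx <- stats::runif(n_bump, 0, max(grid$x))
    cy <- stats::runif(n_bump, 0, max(grid$y))
    w  <- stats::runif(n_bump, 0.2, 0.6) * max(grid$y)
    a  <- stats::runif(n_bump, -1, 1)
    tex <- matrix(0, grid$ny, grid$nx)
    for (i in seq_len(n_bump)) {
      gx <- exp(-((grid$x - cx[i])^2) / (2 * w[i]^2))
      gy <- exp(-((grid$y - cy[i])^2) / (2 * w[i]^2))
      tex <- tex + a[i] * outer(gy, gx)
    }
    tex <- tex - min(tex)
    if (max(tex) > 0) tex <- tex / max(tex)
    amplitude * tex
  })
}

#' Build the static phantom
#'
#' Produces the background optical-depth map (homogeneous liquid absorption
#' plus a smooth agar/tissue context texture) and the microstructure mask
#' marking void spaces where bubbles may grow.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom` with elements `tau_bg` (ny x nx matrix,
#'   optical depth), `mask` (logical matrix of allowed void space),
#'   `compartments` (data frame of alveolar compartment centers, or NULL),
#'   `grid`, and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- pixel_grid(spec)
  tau_bg <- matrix(spec$mu_liq * spec$container_thickness_mm,
                   grid$ny, grid$nx) +
    context_texture(grid, spec$bg_texture_tau, spec$seed)

  compartments <- NULL
  if (spec$microstructure %in% c("none", "agar_gaps")) {
    mask <- matrix(TRUE, grid$ny, grid$nx)
  } else if (spec$microstructure == "vessel") {
    d_mm <- spec$vessel_diameter_um / 1000
    if (d_mm > spec$fov_mm[2])
      stop_bub("vessel diameter %.0f um exceeds field-of-view height %.1f mm",
               spec$vessel_diameter_um, spec$fov_mm[2])
    yc <- spec$fov_mm[2] / 2
    rows <- abs(grid$y - yc) < d_mm / 2
    mask <- matrix(FALSE, grid$ny, grid$nx)
    mask[rows, ] <- TRUE
  } else { # alveolar
    r_mm <- spec$alveolus_radius_um / 1000
    if (2 * r_mm > min(spec$fov_mm))
      stop_bub("alveolus diameter %.0f um exceeds field of view",
               2 * spec$alveolus_radius_um)
    compartments <- hex_pack(spec$fov_mm, r_mm)
    if (nrow(compartments) == 0L)
      stop_bub("no alveolar compartment fits the field of view")
    mask <- matrix(FALSE, grid$ny, grid$nx)
    for (i in seq_len(nrow(compartments))) {
      dx2 <- outer(rep(1, grid$ny), (grid$x - compartments$x[i])^2)
      dy2 <- outer((grid$y - compartments$y[i])^2, rep(1, grid$nx))
      mask <- mask | (dx2 + dy2 <= r_mm^2)
    }
  }
  structure(list(tau_bg = tau_bg, mask = mask, compartments = compartments,
                 grid = grid, spec = spec),
            class = "phantom")
}

# Hexagonal packing of equal circles of radius r inside a w x h rectangle;
# returns centers (mm) of circles fully inside.
hex_pack <- function(fov_mm, r_mm) {
  w <- fov_mm[1]; h <- fov_mm[2]
  dy <- r_mm * sqrt(3)
  rows_y <- seq(r_mm, h - r_mm, by = dy)
  out <- list()
  for (i in seq_along(rows_y)) {
    off <- if (i %% 2 == 0) r_mm else 0
    xs <- seq(r_mm + off, w - r_mm, by = 2 * r_mm)
    if (length(xs)) out[[i]] <- data.frame(x = xs, y = rows_y[i])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(x = numeric(0), y = numeric(0))
  res$compartment <- seq_len(nrow(res))
  res
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, tau_bg %.3f-%.3f, %s mask (%.1f%% void)\n",
              x$grid$ny, x$grid$nx, min(x$tau_bg), max(x$tau_bg),
              x$spec$microstructure, 100 * mean(x$mask)))
  invisible(x)
}
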