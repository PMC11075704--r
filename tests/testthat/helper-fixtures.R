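# Fixtures are generated in code; matrices follow the package convention:
# rows = y (0 at top), columns = x.

# Binary/valued disk on an n x n grid (value in excess-depth units).
raster_disk <- function(cx, cy, r, n = 80, value = 0.03) {
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix(as.numeric((g$col - cx)^2 + (g$row - cy)^2 <= r^2) * value, n, n)
}

# Axis-aligned ellipse with semi-axes a (x) and b (y).
raster_ellipse <- function(cx, cy, a, b, n, value = 0.03) {
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix(as.numeric(((g$col - cx) / a)^2 + ((g$row - cy) / b)^2 <= 1) * value,
         n, n)
}

# Numerical perimeter of an ellipse via the arc-length integral (independent
# oracle for the circularity calibration).
ellipse_perimeter <- function(a, b) {
  4 * stats::integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

# Small rendered phantom with one diffusion bubble; returns everything the
# correction chain needs.
render_small_run <- function(seed = 1L, noise = 0, fov = c(4, 4),
                             nucleation = 6, rate = 0.2, duration = 18,
                             texture = 0.05, flat_drift = 0, ...) {
  spec <- phantom_spec(fov_mm = fov, noise_sigma_rel = noise,
                       bg_texture_tau = texture, seed = seed, ...)
  ph <- build_phantom(spec)
  seeds <- list(bubble_seed(nucleation, site = fov / 2, law = "diffusion",
                            rate = rate))
  times <- seq(1 / spec$frame_rate, duration, by = 1 / spec$frame_rate)
  evo <- evolve_bubbles(seeds, times, ph)
  stack <- render_stack(ph, evo, flat_drift = flat_drift)
  list(spec = spec, phantom = ph, evo = evo, stack = stack, times = times)
}
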