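test_that("stack write/read round trip preserves shape, times and frame count", {
  r <- render_small_run(seed = 4, noise = 0.02, fov = c(2, 2), duration = 4)
  dir <- withr::local_tempdir()
  write_stack(r$stack, dir)
  back <- read_stack(dir)
  expect_length(back$frames, length(r$stack$frames))
  expect_equal(back$times, r$stack$times)
  expect_equal(back$pixel_size_um, 25)
  # 16-bit quantization only
  expect_lt(max(abs(back$frames[[1]] - r$stack$frames[[1]])), 1.5 / 65535 * 2)
})

test_that("a 60 s sequence at 3 frames per second holds 180 frames", {
  spec <- phantom_spec(fov_mm = c(0.5, 0.5), noise_sigma_rel = 0,
                       bg_texture_tau = 0)
  ph <- build_phantom(spec)
  evo <- evolve_bubbles(list(bubble_seed(100, c(0.2, 0.2), "diffusion")),
                        times = seq(1 / 3, 60, by = 1 / 3))
  stack <- render_stack(ph, evo, n_flats = 2L, n_darks = 1L)
  expect_length(stack$frames, 180L)
})

test_that("timestamp/frame mismatches and missing files raise named errors", {
  r <- render_small_run(seed = 4, fov = c(1, 1), duration = 3)
  dir <- withr::local_tempdir()
  write_stack(r$stack, dir)
  ts <- read.csv(file.path(dir, "timestamps.csv"))
  write.csv(ts[-3, ], file.path(dir, "timestamps.csv"), row.names = FALSE)
  expect_error(read_stack(dir), "timestamps")
  file.remove(file.path(dir, "flats.tif"))
  expect_error(read_stack(dir), "flats.tif")
})

test_that("flat-field identity: I = flat, dark = 0 gives T = 1", {
  flat <- matrix(runif(400, 0.5, 1), 20, 20)
  stack <- structure(list(frames = list(flat), times = 1,
                          pixel_size_um = 25, flats = list(flat),
                          darks = list(), meta = list()),
                     class = "radiograph_stack")
  ts <- flat_field_correct(stack)
  expect_equal(ts$frames[[1]], matrix(1, 20, 20), tolerance = 1e-12)
})

test_that("noiseless chain reproduces tau and mu*t_gas to machine precision", {
  r <- render_small_run(seed = 5, noise = 0, duration = 18)
  ts <- flat_field_correct(r$stack)
  expect_equal(-log(ts$frames[[1]]), r$phantom$tau_bg, tolerance = 1e-12)
  ctx <- build_context(ts, window = 1:15, onset_time = 6)
  fi <- 45
  ed <- excess_depth(ts$frames[[fi]], ctx, from_transmission = TRUE)
  tg <- bubblometry:::gas_path_map(r$evo$frames[[fi]], r$phantom$grid)
  expect_equal(ed$dtau, r$spec$mu_liq * tg, tolerance = 1e-10)
  expect_false(any(is.na(ed$dtau)))
})

test_that("dynamic flat fitting beats the static method under drift", {
  r <- render_small_run(seed = 6, noise = 0.01, fov = c(2, 2), duration = 6,
                        nucleation = 100, flat_drift = 0.05)
  t_static <- flat_field_correct(r$stack, "static")
  t_dynamic <- flat_field_correct(r$stack, "dynamic")
  # truth: all frames are bubble-free, so T_true = exp(-tau_bg)
  T_true <- exp(-r$phantom$tau_bg)
  res <- function(ts) sum(vapply(ts$frames, function(T)
    sum((T - T_true)^2), numeric(1)))
  expect_lt(res(t_dynamic), res(t_static))
})

test_that("context map is the per-pixel median and stays within frame range", {
  r <- render_small_run(seed = 7, noise = 0.02, fov = c(1, 1), duration = 5,
                        nucleation = 100)
  ts <- flat_field_correct(r$stack)
  ctx <- build_context(ts, window = 1:11)
  taus <- simplify2array(lapply(ts$frames[1:11], function(T) -log(T)))
  expect_equal(ctx$tau_ref, apply(taus, c(1, 2), median), tolerance = 1e-12)
  expect_true(all(ctx$tau_ref >= apply(taus, c(1, 2), min) - 1e-12))
  expect_true(all(ctx$tau_ref <= apply(taus, c(1, 2), max) + 1e-12))
  expect_error(build_context(ts, window = 1:3), "at least 5")
  expect_error(build_context(ts, window = 1:11, onset_time = 2), "overlaps")
})

test_that("context recovery error shrinks like sigma over sqrt(n)", {
  r <- render_small_run(seed = 8, noise = 0.02, fov = c(1, 1), duration = 7,
                        nucleation = 100, texture = 0.05)
  ts <- flat_field_correct(r$stack)
  ctx <- build_context(ts, window = seq_along(ts$frames))
  err <- ctx$tau_ref - r$phantom$tau_bg
  # tau noise ~ sigma_rel per pixel; median of n frames ~ 1.25 sigma/sqrt(n)
  n <- length(ts$frames)
  expect_lt(stats::quantile(abs(err), 0.99), 3 * 1.25 * 0.02 / sqrt(n) * 2.6)
})

test_that("excess depth follows the product rule and clips negatives", {
  ctx <- structure(list(tau_ref = matrix(1.2, 10, 10),
                        mask = matrix(FALSE, 10, 10),
                        method = "static_median"),
                   class = "context_map")
  # frame identical to context: zero excess
  ed0 <- excess_depth(matrix(1.2, 10, 10), ctx)
  expect_true(all(ed0$dtau == 0))
  # a 2 mm gas path at mu = 0.018/mm: peak excess 0.036
  tau <- matrix(1.2, 10, 10); tau[5, 5] <- 1.2 - 0.018 * 2
  ed1 <- excess_depth(tau, ctx)
  expect_equal(max(ed1$dtau), 0.036)
  # denser-than-reference excursions are clipped and counted
  tau2 <- matrix(1.2, 10, 10); tau2[2, 2] <- 1.5
  ed2 <- excess_depth(tau2, ctx)
  expect_equal(ed2$n_clipped_negative, 1L)
  expect_true(all(ed2$dtau >= 0))
})

test_that("masked pixels propagate through the chain without NaN", {
  r <- render_small_run(seed = 9, noise = 0.01, fov = c(1, 1), duration = 5)
  stack <- r$stack
  stack$flats <- lapply(stack$flats, function(f) { f[3, 4] <- 0; f })
  ts <- flat_field_correct(stack)
  expect_true(ts$mask[3, 4])
  ctx <- build_context(ts, window = 1:9)
  ed <- excess_depth(ts$frames[[2]], ctx, from_transmission = TRUE)
  expect_true(is.na(ed$dtau[3, 4]))
  expect_false(any(is.nan(ed$dtau)))
  v <- gas_volume(ed$dtau, attenuation_model(), 25)
  expect_true(is.finite(v$volume_mm3))
})
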