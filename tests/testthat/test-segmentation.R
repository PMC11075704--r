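test_that("a rasterized disk measures circularity 1 and exact pixel area", {
  m <- raster_disk(110, 110, 100, n = 220)
  seg <- segment_frame(m, pixel_size_um = 25)
  expect_equal(nrow(seg$measurements), 1L)
  expect_equal(seg$measurements$circularity, 1, tolerance = 0.02)
  expect_equal(seg$measurements$area_um2, sum(m > 0) * 25^2)
})

test_that("ellipse circularity matches the elliptic-integral oracle", {
  a <- 200; b <- 100
  m <- raster_ellipse(256, 256, a, b, n = 512)
  seg <- segment_frame(m, pixel_size_um = 1)
  oracle <- 4 * pi * (pi * a * b) / ellipse_perimeter(a, b)^2
  expect_equal(oracle, 0.8412, tolerance = 1e-4)
  expect_equal(seg$measurements$circularity, oracle, tolerance = 0.02)
})

test_that("circularity decreases with aspect ratio and stays below 1.05", {
  shapes <- list(raster_disk(150, 150, 100, n = 300),
                 raster_ellipse(210, 210, 200, 100, n = 420),
                 raster_ellipse(210, 210, 200, 50, n = 420))
  circs <- vapply(shapes, function(m)
    segment_frame(m, 1)$measurements$circularity, numeric(1))
  expect_true(all(diff(circs) < 0))
  expect_true(all(circs <= 1.05))
})

test_that("empty frames and sub-threshold specks yield no components", {
  expect_equal(nrow(segment_frame(matrix(0, 30, 30), 25)$measurements), 0L)
  speck <- matrix(0, 30, 30); speck[4, 4] <- 0.05
  expect_equal(nrow(segment_frame(speck, 25, min_size_px = 9)$measurements), 0L)
  expect_error(segment_frame(matrix(-1, 3, 3), 25), "non-negative")
})

test_that("holes are filled before measurement", {
  m <- raster_disk(40, 40, 20, n = 80)
  m[38:42, 38:42] <- 0
  seg <- segment_frame(m, 1)
  expect_equal(seg$measurements$n_px, sum(raster_disk(40, 40, 20, n = 80) > 0))
})

test_that("a single growing disk yields one continuous track", {
  frames <- lapply(seq(6, 20, 2), function(r) raster_disk(40, 40, r))
  segs <- lapply(frames, segment_frame, pixel_size_um = 25)
  trk <- track_bubbles(segs, seq_along(frames), pixel_size_um = 25)
  expect_length(trk$tracks, 1L)
  expect_equal(trk$status, "active")
  expect_equal(nrow(trk$tracks[[1]]), length(frames))
})

test_that("a disk leaving through the top edge is marked exited", {
  frames <- lapply(seq(40, -12, by = -8), function(cy) raster_disk(40, cy, 8))
  segs <- lapply(frames, segment_frame, pixel_size_um = 25)
  trk <- track_bubbles(segs, seq_along(frames), pixel_size_um = 25)
  expect_equal(trk$status, "exited")
  last_seen <- max(trk$tracks[[1]]$time)
  expect_equal(trk$exit_time, last_seen + 1)  # one frame period later
  expect_equal(trk$exit_measurement[[1]]$label,
               utils::tail(trk$tracks[[1]]$label, 1))
})

test_that("a disk vanishing away from the top edge is flagged lost", {
  frames <- c(lapply(1:3, function(i) raster_disk(40, 60, 8)),
              list(matrix(0, 80, 80)))
  segs <- lapply(frames, segment_frame, pixel_size_um = 25)
  trk <- track_bubbles(segs, seq_along(frames), pixel_size_um = 25)
  expect_equal(trk$status, "lost")
})

test_that("two disks growing into contact merge into a successor track", {
  frames <- lapply(seq(10, 17, 1), function(r)
    raster_disk(25, 40, r) + raster_disk(56, 40, r))
  segs <- lapply(frames, segment_frame, pixel_size_um = 25)
  trk <- track_bubbles(segs, seq_along(frames), pixel_size_um = 25)
  expect_equal(sort(trk$status), c("active", "merged", "merged"))
  succ <- which(trk$status == "active")
  parents <- which(trk$status == "merged")
  expect_equal(unique(trk$merged_into[parents]), succ)
  a_succ <- trk$tracks[[succ]]$area_um2[1]
  a_par <- sum(vapply(parents, function(i)
    utils::tail(trk$tracks[[i]]$area_um2, 1), numeric(1)))
  expect_equal(a_succ / a_par, 1, tolerance = 0.2)
})

test_that("per-frame track areas add up to the segmented total", {
  sim <- simulate_scenario("diffusion", seed = 2)
  ms <- measure_scenario(sim)
  seg_total <- vapply(seq_along(sim$times), function(fi) {
    sum(unlist(lapply(ms$tracks$tracks, function(tr)
      tr$area_um2[tr$time == sim$times[fi]])))
  }, numeric(1))
  # recompute directly
  det <- lapply(sim$dtau, bubblometry:::gauss_blur, sigma = 1)
  direct <- vapply(det, function(m) {
    s <- segment_frame(pmax(m, 0), sim$pixel_size_um, threshold = ms$floor)
    sum(s$measurements$area_um2)
  }, numeric(1))
  expect_equal(seg_total, direct)
})

test_that("growth-law presets classify into their three regimes", {
  for (s in 1:3) {
    expect_equal(classify_growth(
      measure_scenario(simulate_scenario("diffusion", seed = s))$track)$class,
      "unconstrained")
    expect_equal(classify_growth(
      measure_scenario(simulate_scenario("vessel", seed = s))$track)$class,
      "vessel_confined")
    cl <- classify_growth(
      measure_scenario(simulate_scenario("alveolar", seed = s))$track)
    expect_equal(cl$class, "alveolar_stepped")
    expect_gte(cl$n_steps, 2L)
  }
})

test_that("short tracks are rejected by the classifier", {
  tr <- data.frame(time = 1:5, area_um2 = 1:5, circularity = rep(1, 5))
  expect_error(classify_growth(tr), "at least 10")
})

test_that("area growth exponent recovers closed-form slopes", {
  tt <- seq(1, 30, 0.5)
  lin <- data.frame(time = tt, area_um2 = 7 * tt)
  expect_equal(area_growth_exponent(lin, birth_time = 0)$slope, 1,
               tolerance = 1e-10)
  sq <- data.frame(time = tt, area_um2 = 2 * tt^2)
  expect_equal(area_growth_exponent(sq, birth_time = 0)$slope, 2,
               tolerance = 1e-10)
  # non-positive areas excluded with a warning
  bad <- data.frame(time = tt, area_um2 = c(0, 7 * tt[-1]))
  expect_warning(res <- area_growth_exponent(bad, birth_time = 0), "excluded")
  expect_equal(res$n, length(tt) - 1L)
})

test_that("diffusion preset: area slope 1 implies radius slope one half", {
  slopes <- vapply(1:5, function(s) {
    sim <- simulate_scenario("diffusion", seed = s)
    tr <- measure_scenario(sim)$track
    t0 <- sim$evolution$onset_time
    unname(coef(lm(log(sqrt(tr$area_um2 / pi)) ~ log(tr$time - t0)))[2])
  }, numeric(1))
  expect_true(all(abs(slopes - 0.5) <= 0.03))
})
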