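test_that("background map is a homogeneous slab without texture", {
  spec <- phantom_spec(fov_mm = c(2, 1), bg_texture_tau = 0)
  ph <- build_phantom(spec)
  expect_equal(max(ph$tau_bg), min(ph$tau_bg))
  expect_equal(ph$tau_bg[1, 1], spec$mu_liq * spec$container_thickness_mm)
  expect_true(all(ph$mask))
})

test_that("vessel mask is a 4-pixel tube for a 100 um lumen at 25 um pixels", {
  ph <- build_phantom(phantom_spec(fov_mm = c(4, 2), microstructure = "vessel",
                                   vessel_diameter_um = 100))
  rows <- which(apply(ph$mask, 1, any))
  expect_length(rows, 4L)
  expect_true(all(diff(rows) == 1L))
  expect_true(all(ph$mask[rows, ]))
})

test_that("alveolar compartments match the analytic disk area", {
  ph <- build_phantom(phantom_spec(fov_mm = c(3, 1.5),
                                   microstructure = "alveolar",
                                   alveolus_radius_um = 125))
  n <- nrow(ph$compartments)
  expect_gt(n, 0)
  px_per_comp <- sum(ph$mask) / n
  r_px <- 125 / 25
  expect_equal(px_per_comp, pi * r_px^2, tolerance = 0.05)
})

test_that("geometry exceeding the field of view is rejected", {
  expect_error(build_phantom(phantom_spec(fov_mm = c(4, 0.05),
                                          microstructure = "vessel",
                                          vessel_diameter_um = 100)),
               "exceeds")
  expect_error(build_phantom(phantom_spec(fov_mm = c(0.2, 0.2),
                                          microstructure = "alveolar",
                                          alveolus_radius_um = 125)),
               "exceeds")
})

test_that("diffusion-law area doubles between t_abo and 2 t_abo", {
  sd_ <- bubble_seed(0, c(1, 1), "diffusion", rate = 0.1)
  evo <- evolve_bubbles(list(sd_), times = c(5, 10))
  a <- evo$ledger$area_mm2
  expect_equal(a[2] / a[1], 2, tolerance = 1e-12)
})

test_that("vessel-law silhouette matches the closed-form stadium", {
  # elongation L = 2r: circularity 4 pi (pi r^2 + 4 r^2) / (2 pi r + 4 r)^2
  r <- 0.05
  sd_ <- bubble_seed(0, c(1, 0.5), "vessel", rate = r / 2, radius_mm = r)
  evo <- evolve_bubbles(list(sd_), times = 2)  # half = r, L = 2r
  led <- evo$ledger
  circ <- 4 * pi * led$area_mm2 / led$perimeter_mm^2
  expect_equal(led$area_mm2, pi * r^2 + 4 * r^2, tolerance = 1e-12)
  expect_equal(circ, 4 * pi * (pi + 4) / (2 * pi + 4)^2, tolerance = 1e-12)
  expect_equal(circ, 0.849, tolerance = 1e-3)
})

test_that("alveolar-law area has plateaus separated by compartment jumps", {
  sd_ <- bubble_seed(0, c(0.5, 0.75), "alveolar", rate = 5, radius_mm = 0.125,
                     n_compartments = 3L)
  evo <- evolve_bubbles(list(sd_), times = seq(0.5, 16, by = 0.5))
  a <- evo$ledger$area_mm2
  jumps <- which(diff(a) > 1e-9)
  expect_length(jumps, 2L)                      # 3 compartments, 2 fills
  comp_area <- pi * 0.125^2
  expect_equal(unname(diff(a)[jumps]), rep(comp_area, 2), tolerance = 1e-9)
  expect_equal(length(unique(round(a, 9))), 3L) # piecewise-constant plateaus
})

test_that("rendered intensity is exact Beer-Lambert without noise or bubbles", {
  spec <- phantom_spec(fov_mm = c(1, 1), noise_sigma_rel = 0,
                       bg_texture_tau = 0.05, seed = 2)
  ph <- build_phantom(spec)
  evo <- evolve_bubbles(list(bubble_seed(100, c(0.5, 0.5), "diffusion")),
                        times = c(1, 2))
  stack <- render_stack(ph, evo)
  dark <- Reduce(`+`, stack$darks) / length(stack$darks)
  flat <- Reduce(`+`, stack$flats) / length(stack$flats)
  T <- (stack$frames[[1]] - dark) / (flat - dark)
  expect_equal(-log(T), ph$tau_bg, tolerance = 1e-12)
})

test_that("gas path length through a sphere equals its chord", {
  spec <- phantom_spec(fov_mm = c(4, 4), noise_sigma_rel = 0,
                       bg_texture_tau = 0)
  grid <- bubblometry:::pixel_grid(spec)
  shp <- list(type = "sphere", cx = 2, cy = 2, r = 1)
  tg <- bubblometry:::gas_path_map(list(shp), grid)
  expect_equal(max(tg), 2, tolerance = 1e-3)    # centre chord = diameter
  expect_equal(sum(tg) * grid$ps_mm^2, 4 / 3 * pi, tolerance = 1e-3)
})

test_that("identical seeds render bit-identical stacks and chromatograms", {
  r1 <- render_small_run(seed = 9, noise = 0.02, duration = 3)
  r2 <- render_small_run(seed = 9, noise = 0.02, duration = 3)
  expect_identical(r1$stack$frames, r2$stack$frames)
  expect_identical(r1$stack$flats, r2$stack$flats)
  c1 <- render_chromatograms(gas_schedule(n_cycles = 3), seed = 4)
  c2 <- render_chromatograms(gas_schedule(n_cycles = 3), seed = 4)
  expect_identical(c1$signal, c2$signal)
})

test_that("rendered transmission stays within noise bounds", {
  r <- render_small_run(seed = 3, noise = 0.02, duration = 5, texture = 0)
  flat <- Reduce(`+`, r$stack$flats) / length(r$stack$flats)
  for (f in r$stack$frames) {
    T <- f / flat
    expect_true(all(T >= 0))
    expect_true(all(T <= 1 + 5 * 0.02 + 0.02)) # 5 sigma + dark offset
  }
})

test_that("ledger volumes are non-decreasing and additive, with exits frozen", {
  seeds <- list(
    bubble_seed(1, c(1, 1), "diffusion", rate = 0.05, exit_time = 8),
    bubble_seed(2, c(2.5, 1), "diffusion", rate = 0.04))
  evo <- evolve_bubbles(seeds, times = seq(0.5, 12, 0.5))
  tot <- evo$totals
  expect_true(all(diff(tot$V_C_mm3) >= -1e-12))
  expect_equal(nrow(evo$exits), 1L)
  expect_equal(evo$exits$time, 8)
  # after the exit, V_C - V equals the frozen volume
  post <- tot$time >= 8
  expect_equal(tot$V_C_mm3[post] - tot$V_mm3[post],
               rep(evo$exits$volume_mm3, sum(post)), tolerance = 1e-12)
  # per-frame totals equal the sum of per-bubble ledger rows
  for (fi in c(3, 10, 20)) {
    expect_equal(tot$V_mm3[fi],
                 sum(evo$ledger$volume_mm3[evo$ledger$frame == fi]))
  }
})

test_that("noiseless diffusion ledger has unit log-area slope", {
  sd_ <- bubble_seed(2, c(1, 1), "diffusion", rate = 0.1)
  evo <- evolve_bubbles(list(sd_), times = seq(2.5, 30, 0.5))
  led <- evo$ledger
  fit <- lm(log(led$area_mm2) ~ log(led$time - 2))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.02)
})

test_that("chromatograms carry the scheduled peaks per module", {
  # single species injected: one assigned peak in its module
  sch <- gas_schedule(n_cycles = 2, solvent_amount = 0, air_amount = 80,
                      amount_noise_rel = 0)
  # zero out O2 by overriding: amounts are columns of the schedule
  sch$o2 <- 0
  ch <- render_chromatograms(sch, seed = 1, noise_abs = 0.01)
  pt <- analyze_chromatograms(ch)
  ms <- pt[pt$module == "MS5A" & pt$species != "unassigned" & pt$cycle == 1, ]
  expect_equal(ms$species, "N2")
  # equal N2 and O2 amounts: equal MS5A areas within noise
  sch2 <- gas_schedule(n_cycles = 2, amount_noise_rel = 0)
  sch2$n2 <- 40; sch2$o2 <- 40
  ch2 <- render_chromatograms(sch2, seed = 2, noise_abs = 0.01)
  pt2 <- analyze_chromatograms(ch2)
  a <- pt2[pt2$module == "MS5A" & pt2$cycle == 1, ]
  expect_equal(a$area[a$species == "N2"], a$area[a$species == "O2"],
               tolerance = 0.05)
})

test_that("solvent-fraction shift at onset raises the EtOH share", {
  sch <- gas_schedule(onset_time_s = 500, etoh_frac_pre = 0.4,
                      etoh_shift = 0.15)
  pre <- sch$etoh[sch$cycle_time_s < 500] / (sch$etoh + sch$h2o)[sch$cycle_time_s < 500]
  post <- sch$etoh[sch$cycle_time_s > 500] / (sch$etoh + sch$h2o)[sch$cycle_time_s > 500]
  expect_true(all(post > pre))
  expect_equal(unique(post) - unique(pre), 0.15)
})
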