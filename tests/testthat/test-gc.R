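test_that("baseline correction recovers a flat-baseline Gaussian peak", {
  rt <- seq(0, 90, 0.25)
  peak <- 8 * exp(-(rt - 45)^2 / (2 * 1.5^2))
  sig <- 3 + peak
  cb <- correct_baseline(sig, window = 81)
  off_peak <- abs(rt - 45) > 10
  expect_lt(abs(median(cb$corrected[off_peak])), 0.05)
  expect_true(all(cb$corrected >= -3 * 0.05))
  expect_error(correct_baseline(sig, window = 10000), "exceeds")
  expect_equal(correct_baseline(rep(0, 100), window = 21)$corrected,
               rep(0, 100))
})

test_that("peak areas survive linear baseline drift within 2%", {
  rt <- seq(0, 90, 0.25)
  peak <- 8 * exp(-(rt - 45)^2 / (2 * 1.5^2))
  ref <- data.frame(species = "EtOH", rt_s = 45)
  area_flat <- integrate_peaks(rt, correct_baseline(2 + peak, 81)$corrected,
                               ref)$area
  area_drift <- integrate_peaks(
    rt, correct_baseline(2 + 0.005 * rt + peak, 81)$corrected, ref)$area
  expect_equal(area_drift / area_flat, 1, tolerance = 0.02)
})

test_that("a Gaussian integrates to h*sigma*sqrt(2*pi) within 1%", {
  rt <- seq(0, 90, 0.25)
  h <- 5; sp <- 1.5
  sig <- h * exp(-(rt - 40)^2 / (2 * sp^2))
  p <- integrate_peaks(rt, sig, data.frame(species = "N2", rt_s = 40))
  expect_equal(p$area, h * sp * sqrt(2 * pi), tolerance = 0.01)
})

test_that("assignment respects the retention-time tolerance", {
  rt <- seq(0, 90, 0.25)
  sig <- 5 * exp(-(rt - 60)^2 / (2 * 1.5^2))
  ref <- data.frame(species = c("N2", "O2"), rt_s = c(30, 45))
  p <- integrate_peaks(rt, sig, ref, tolerance_s = 5)
  expect_equal(p$species, "unassigned")
  # jitter within half the tolerance does not change the assignment
  for (j in c(-2, 0, 2)) {
    sj <- 5 * exp(-(rt - (45 + j))^2 / (2 * 1.5^2))
    expect_equal(integrate_peaks(rt, sj, ref, tolerance_s = 5)$species, "O2")
  }
})

test_that("two maxima on one reference keep the larger area, flagged", {
  rt <- seq(0, 90, 0.25)
  sig <- 6 * exp(-(rt - 44)^2 / (2 * 1^2)) + 3 * exp(-(rt - 47)^2 / (2 * 1^2))
  p <- integrate_peaks(rt, sig, data.frame(species = "O2", rt_s = 45),
                       tolerance_s = 5)
  assigned <- p[p$species == "O2", ]
  expect_equal(nrow(assigned), 1L)
  expect_true(assigned$ambiguous)
  expect_equal(assigned$rt_apex_s, 44, tolerance = 0.3)
})

test_that("adjacent peaks split at the watershed when the valley stays high", {
  rt <- seq(0, 90, 0.25)
  sig <- 5 * exp(-(rt - 30)^2 / (2 * 2^2)) + 5 * exp(-(rt - 40)^2 / (2 * 2^2))
  ref <- data.frame(species = c("N2", "O2"), rt_s = c(30, 40))
  p <- integrate_peaks(rt, sig, ref)
  expect_setequal(p$species[p$species != "unassigned"], c("N2", "O2"))
  areas <- p$area[match(c("N2", "O2"), p$species)]
  expect_equal(areas[1], areas[2], tolerance = 0.02)
})

test_that("relative concentrations normalize to 1 within each module cycle", {
  sch <- gas_schedule(n_cycles = 6)
  ch <- render_chromatograms(sch, seed = 8)
  conc <- relative_concentrations(analyze_chromatograms(ch))
  sums <- aggregate(fraction ~ module + cycle, conc, sum)
  expect_true(all(abs(sums$fraction - 1) < 1e-6))
  # single species: fraction 1; two equal species: 0.5 each
  pt <- data.frame(module = "PDMS10", cycle = 1L, cycle_time_s = 72,
                   species = "EtOH", rt_apex_s = 50, area = 3,
                   ambiguous = FALSE)
  expect_equal(relative_concentrations(pt)$fraction, 1)
  pt2 <- rbind(pt, transform(pt, species = "H2O", rt_apex_s = 70))
  expect_equal(relative_concentrations(pt2)$fraction, c(0.5, 0.5))
})

test_that("a 2:1 EtOH:H2O schedule yields fractions 0.667/0.333", {
  sch <- gas_schedule(n_cycles = 4, air_amount = 0, etoh_frac_pre = 2 / 3,
                      etoh_shift = 0, amount_noise_rel = 0)
  ch <- render_chromatograms(sch, seed = 2, noise_abs = 0.02)
  conc <- relative_concentrations(analyze_chromatograms(ch))
  et <- conc$fraction[conc$species == "EtOH"]
  h2o <- conc$fraction[conc$species == "H2O"]
  expect_true(all(abs(et - 2 / 3) < 0.01))
  expect_true(all(abs(h2o - 1 / 3) < 0.01))
})

test_that("window summary reads constant series as unchanged everywhere", {
  cycles <- 1:12
  conc <- structure(
    data.frame(module = "MS5A", species = "N2", cycle = cycles,
               cycle_time_s = (cycles - 0.5) * 144,
               fraction = 0.78, flagged = FALSE),
    class = c("concentration_series", "data.frame"))
  ws <- onset_window_summary(conc, t_bo = 800)
  vals <- unlist(ws[grep("value_at", names(ws))])
  expect_true(all(vals == 0.78))
  expect_equal(ws$classification, "unchanged")
})

test_that("window summary marks missing cycles without failing", {
  cycles <- setdiff(1:12, 5)  # drop the cycle nearest t_bo - 180 s
  conc <- structure(
    data.frame(module = "MS5A", species = "N2", cycle = cycles,
               cycle_time_s = (cycles - 0.5) * 144,
               fraction = 0.78, flagged = FALSE),
    class = c("concentration_series", "data.frame"))
  ws <- onset_window_summary(conc, t_bo = 800)
  expect_true(is.na(ws[["value_at_-180s"]]))
  expect_false(anyNA(ws[["value_at_-360s"]]))
  expect_equal(ws$classification, "unchanged")
})

test_that("retention-time jitter within half tolerance keeps assignments stable", {
  sch <- gas_schedule(n_cycles = 3)
  ch <- render_chromatograms(sch, seed = 5)
  ref <- gc_reference_default()
  ref$rt_s <- ref$rt_s + 2  # miscalibration below tol/2
  pt <- analyze_chromatograms(ch, reference = ref)
  sp <- sort(unique(pt$species[pt$species != "unassigned"]))
  expect_setequal(sp, c("EtOH", "H2O", "N2", "N2+O2", "O2"))
})
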