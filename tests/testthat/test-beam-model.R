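test_that("equivalent square maps circular cones to equal-area squares", {
  expect_equal(round(equivalent_square(4), 2), 3.54)
  expect_equal(equivalent_square(10), 5 * sqrt(pi), tolerance = 1e-12)
  expect_error(equivalent_square(0), "positive")
  expect_error(equivalent_square(-3), "positive")
  # linear in diameter
  for (k in c(0.5, 2, 7.3))
    expect_equal(equivalent_square(k * 12.5), k * equivalent_square(12.5),
                 tolerance = 1e-12)
  # measured-FWHM override takes precedence over the nominal diameter
  expect_equal(equivalent_square(4, fwhm_mm = 4.2), equivalent_square(4.2))
})

test_that("two-term exponential fit recovers noise-free generating curves", {
  s <- fx_fit_s
  fit <- fit_correction_curve(s, k_twoexp(s))
  expect_lt(max(abs(eval_correction(fit, s) / k_twoexp(s) - 1)), 1e-6)
  # extrapolation below the smallest fitted s stays close to the generator
  expect_equal(eval_correction(fit, 2.5), k_twoexp(2.5), tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-9)
  # constant data
  fitc <- fit_correction_curve(s, rep(1, length(s)))
  expect_lt(max(abs(eval_correction(fitc, s) - 1)), 1e-6)
  # curve must be finite and positive over the fitted range
  grid <- seq(min(s), max(s), length.out = 200)
  expect_true(all(is.finite(eval_correction(fit, grid))))
  expect_true(all(eval_correction(fit, grid) > 0))
})

test_that("fit quality on noisy correction factors and input validation", {
  s <- fx_fit_s
  set.seed(0)
  k <- k_twoexp(s) + rnorm(length(s), sd = 0.002)
  fit <- fit_correction_curve(s, k)
  expect_gt(fit$r_squared, 0.99)
  # R^2 agrees with a direct residual computation
  ss_res <- sum((eval_correction(fit, s) - k)^2)
  ss_tot <- sum((k - mean(k))^2)
  expect_equal(fit$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_error(fit_correction_curve(s[1:4], k[1:4]), "at least 5")
  expect_error(fit_correction_curve(c(1, 2, 2, 3, 4), rep(1, 5)), "distinct")
})

test_that("TMR resampling interpolates to 1 mm and normalizes at dmax", {
  # pure normalization: grid already 1 mm, value 2 everywhere -> halved
  t1 <- resample_and_normalize_tmr(0:200, rep(2, 201), 15)
  expect_true(all(abs(t1$values - 1) < 1e-12))
  expect_equal(t1$dmax, 15)
  # linear midpoint before normalization: (10,0.9),(20,0.7) -> 0.8 at 15
  t2 <- resample_and_normalize_tmr(c(10, 20, 30, 200), c(0.9, 0.7, 0.5, 0.1),
                                   dmax_mm = 10)
  expect_equal(tmr_lookup(t2, 15) * 0.9, 0.8, tolerance = 1e-12)
  expect_error(resample_and_normalize_tmr(c(10, 20), c(1, 0.9), 5),
               "outside")
  expect_error(resample_and_normalize_tmr(c(10, 5), c(1, 0.9), 7),
               "increasing")
  # smoothing requires an odd window, and a 3-point window averages neighbours
  expect_error(resample_and_normalize_tmr(0:200, rep(1, 201), 15,
                                          smooth_window = 4), "odd")
  raw <- c(rep(1, 100), 2, rep(1, 100))
  t3 <- resample_and_normalize_tmr(0:200, raw, 15, smooth_window = 3)
  expect_equal(t3$values[101], (1 + 2 + 1) / 3, tolerance = 1e-12)
})

test_that("TMR lookup is exact at nodes, linear between, log-linear beyond", {
  arch <- fx_archive()
  tab <- arch$cones[["10"]]$tmr
  # exhaustive node sweep
  expect_equal(tmr_lookup(tab, tab$depths), tab$values, tolerance = 1e-15)
  expect_equal(tmr_lookup(tab, tab$dmax), 1.0, tolerance = 1e-12)
  # midway between nodes: arithmetic mean of the two node values
  mid <- tab$depths[50] + 0.5
  expect_equal(tmr_lookup(tab, mid),
               (tab$values[50] + tab$values[51]) / 2, tolerance = 1e-12)
  expect_error(tmr_lookup(tab, -1), "non-negative")
  # beyond the last node: log-linear continuation of the last two nodes
  n <- length(tab$depths)
  slope <- log(tab$values[n] / tab$values[n - 1])
  expect_equal(tmr_lookup(tab, 210), tab$values[n] * exp(10 * slope),
               tolerance = 1e-9)
  # shallower than the first node: clamped, with a warning
  expect_warning(v <- tmr_lookup(tab, 0.2), "clamping")
  expect_equal(v, tab$values[1])
})

test_that("TMR to PDD conversion and round-trip identity", {
  flat <- fx_flat_tmr(15)
  expect_equal(tmr_to_pdd(flat, 900, 15), 100, tolerance = 1e-12)
  expect_equal(tmr_to_pdd(flat, 900, 50), 100 * (915 / 950)^2,
               tolerance = 1e-12)
  arch <- fx_archive()
  tab <- arch$cones[["12.5"]]$tmr
  d <- c(20, 57, 113, 190)
  pdd <- tmr_to_pdd(tab, 900, d)
  # PDD strictly below 100*TMR beyond dmax (inverse-square factor < 1)
  expect_true(all(pdd < 100 * tmr_lookup(tab, d)))
  # inverting the inverse-square factor recovers TMR to machine precision
  back <- pdd / 100 * ((900 + d) / (900 + tab$dmax))^2
  expect_equal(back, tmr_lookup(tab, d), tolerance = 1e-15)
})

test_that("OF at TMR max: unity geometry, factor oracle, algebraic identity", {
  # all geometric factors unity (OF measured at dmax, SSD + dmax = SAD)
  ua <- fx_unity_archive(of = 0.5)
  expect_equal(of_at_tmrmax(ua, 10), 0.5, tolerance = 1e-12)
  # factor-by-factor oracle on the synthetic archive
  arch <- fx_archive()
  cn <- arch$cones[["15"]]
  ssd <- cn$of_geometry$ssd_mm; dmeas <- cn$of_geometry$depth_mm
  sad <- arch$calibration$sad_mm
  f_pdd <- tmr_to_pdd(cn$tmr, ssd, cn$tmr$dmax) / tmr_to_pdd(cn$tmr, ssd, dmeas)
  f_isl <- ((ssd + cn$tmr$dmax) / sad)^2
  expect_equal(of_at_tmrmax(arch, 15), cn$of * f_pdd * f_isl,
               tolerance = 1e-12)
  # exact algebraic identity after substituting the PDD definition
  lhs <- of_at_tmrmax(arch, 15) / cn$of
  rhs <- (1 / tmr_lookup(cn$tmr, dmeas)) *
    ((ssd + dmeas) / (ssd + cn$tmr$dmax))^2 *
    ((ssd + cn$tmr$dmax) / sad)^2
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(of_at_tmrmax(arch, 99), "not present")
})

test_that("archive builds from CSVs, validates, and round-trips losslessly", {
  dir <- withr::local_tempdir()
  arch0 <- fx_archive()
  cones <- vapply(arch0$cones, function(cn) cn$diameter_mm, numeric(1))
  expect_length(cones, 7L)
  # write commissioning CSVs for all 7 cones and rebuild
  for (cn in arch0$cones) {
    raw_d <- seq(0, 200, by = 2.5)
    raw_v <- ifelse(raw_d < 15, (raw_d / 15)^2 + 1e-6,
                    exp(-0.0045 * (raw_d - 15)))
    utils::write.csv(data.frame(depth_mm = raw_d, value = raw_v),
                     file.path(dir, sprintf("tmr_%g.csv", cn$diameter_mm)),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(cone_mm = cones,
                              of = vapply(arch0$cones, function(cn) cn$of,
                                          numeric(1))),
                   file.path(dir, "of.csv"), row.names = FALSE)
  utils::write.csv(data.frame(key = c("drref_gy_per_mu", "sad_mm"),
                              value = c(0.01, 1000)),
                   file.path(dir, "cal.csv"), row.names = FALSE)
  utils::write.csv(data.frame(hu = c(-1000, 0, 1000, 3000),
                              red = c(0, 1, 1.6, 2.5)),
                   file.path(dir, "ct.csv"), row.names = FALSE)
  tmr_files <- stats::setNames(
    file.path(dir, sprintf("tmr_%g.csv", cones)), as.character(cones))
  arch <- build_archive("TB1", "6FFF", 15, tmr_files,
                        file.path(dir, "of.csv"), file.path(dir, "cal.csv"),
                        file.path(dir, "ct.csv"))
  expect_length(arch$cones, 7L)
  expect_equal(tmr_lookup(arch$cones[["4"]]$tmr, 15), 1, tolerance = 1e-12)
  # missing cone file is a configuration error naming the cone
  expect_error(build_archive("TB1", "6FFF", 15, tmr_files[-3],
                             file.path(dir, "of.csv"),
                             file.path(dir, "cal.csv"),
                             file.path(dir, "ct.csv")),
               "cone 7.5")
  # save / load / re-save: byte-identical archives
  p1 <- file.path(dir, "a1.json"); p2 <- file.path(dir, "a2.json")
  save_archive(arch, p1)
  arch2 <- load_archive(p1)
  save_archive(arch2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  expect_equal(arch2$cones[["10"]]$tmr$values, arch$cones[["10"]]$tmr$values,
               tolerance = 1e-12)
  expect_equal(arch2$calibration$drref_gy_per_mu,
               arch$calibration$drref_gy_per_mu, tolerance = 0)
  # empty cone list rejected
  expect_error(beam_archive("m", "e",
                            list(drref_gy_per_mu = 0.01, sad_mm = 1000),
                            arch$ct_curve, list()),
               "no cones")
})

test_that("CT calibration curve validates and clamps lookups", {
  expect_error(ct_calibration_curve(c(0, -10), c(1, 1)), "increasing")
  expect_error(ct_calibration_curve(c(-1000, 0), c(0.5, 0.2)),
               "non-decreasing")
  expect_error(ct_calibration_curve(c(-1000, 0), c(0, 2)), "RED ~ 1")
  cur <- ct_calibration_curve(c(-1000, 0, 1000, 3000), c(0, 1, 1.6, 2.5))
  expect_equal(red_from_hu(cur, c(-2000, -1000, -500, 0, 500, 3000, 5000)),
               c(0, 0, 0.5, 1, 1.3, 2.5, 2.5), tolerance = 1e-12)
})
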