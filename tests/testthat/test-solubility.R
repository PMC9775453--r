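# Higuchi-Connors phase-solubility analysis.

test_that("calibration fits and absorbance inversion", {
  conc <- c(0.002, 0.005, 0.01, 0.02)
  cal <- fit_calibration(conc, 2 * conc + 0.1)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.1, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  # hand-computed OLS: (1,1), (2,2), (3,2)
  cal2 <- fit_calibration(c(1, 2, 3), c(1, 2, 2))
  expect_equal(cal2$slope, 0.5, tolerance = 1e-12)
  expect_equal(cal2$intercept, 2 / 3, tolerance = 1e-12)
  expect_equal(cal2$r_squared, 0.75, tolerance = 1e-12)

  expect_error(fit_calibration(c(1, 2), c(1, 2)), "3 distinct")
  # constant response: zero slope is rejected downstream
  flat <- fit_calibration(1:4, rep(2, 4))
  expect_error(absorbance_to_conc(flat, 2.5), "positive")

  # the published calibration line, inverted
  curve <- structure(list(slope = 39.19, intercept = 0.0009,
                          r_squared = 0.99, valid_range = c(0, 0.02)),
                     class = "calibration_curve")
  inv <- absorbance_to_conc(curve, 0.39199)
  expect_equal(inv, (0.39199 - 0.0009) / 39.19, tolerance = 1e-12)
  expect_equal(signif(inv, 3), 0.00998)
  expect_equal(absorbance_to_conc(curve, 0.0009), 0)
  expect_equal(absorbance_to_conc(curve, 0.39199, dilution_factor = 10),
               10 * inv, tolerance = 1e-12)
  expect_error(absorbance_to_conc(curve, -0.5), "negative")
})

test_that("profile classification separates A and B types", {
  # strictly linear: A_L over the full range
  lin <- solubility_dataset(1:8, 0.04 + 0.1 * (1:8))
  cl <- classify_profile(lin)
  expect_identical(cl$profile, "A_L")
  expect_equal(cl$linear_range, c(1L, 8L))

  # rise, plateau (2 levels), decline: B_s with the initial linear run
  bs <- solubility_dataset(1:8, c(0.14, 0.24, 0.34, 0.34, 0.34,
                                  0.30, 0.26, 0.22))
  clb <- classify_profile(bs)
  expect_identical(clb$profile, "B_s")
  expect_equal(clb$linear_range, c(1L, 3L))

  # rise then immediate sharp decline: B_i
  bi <- solubility_dataset(1:6, c(0.14, 0.24, 0.34, 0.20, 0.10, 0.05))
  expect_identical(classify_profile(bi)$profile, "B_i")

  # curved positive / negative quadratic profiles
  x <- 1:10
  ap <- solubility_dataset(x, 0.05 + 0.02 * x + 0.01 * x^2)
  expect_identical(classify_profile(ap)$profile, "A_P")
  an <- solubility_dataset(x, 0.05 + 0.25 * x - 0.012 * x^2)
  expect_identical(classify_profile(an)$profile, "A_N")

  expect_error(classify_profile(solubility_dataset(1:3, 1:3 * 0.1)),
               "4 levels")
})

test_that("Kc and CE match the closed-form worked examples", {
  # printed slopes with S0 = 0.0378 mM
  expect_equal(signif(compute_kc(0.0652, 0.0378), 2), 1800)
  expect_equal(signif(compute_kc(0.1562, 0.0378), 2), 4900)
  expect_equal(signif(compute_kc(0.1148, 0.0378), 2), 3400)
  expect_equal(compute_kc(0.0652, 0.0378), 1845.43, tolerance = 0.005)
  # hand arithmetic: slope 0.5, S0 1 mM -> 0.5 / (0.001 * 0.5) = 1000
  expect_equal(compute_kc(0.5, 1), 1000, tolerance = 1e-9)

  expect_equal(round(compute_ce(0.0652), 1), 7.0)
  expect_equal(round(compute_ce(0.1562), 1), 18.5)
  expect_equal(round(compute_ce(0.1148), 1), 13.0)
  expect_equal(compute_ce(0.5), 100, tolerance = 1e-12)

  expect_error(compute_kc(1.2, 1), "slope")
  expect_error(compute_kc(-0.1, 1), "slope")
  expect_error(compute_kc(0.5, 0), "S0")
  expect_error(compute_ce(1), "slope")
})

test_that("zero-noise generator datasets are recovered exactly", {
  g <- gen_solubility(solubility_gen_spec(profile = "A_L", slope = 0.1562,
                                          s0_mM = 0.0378, noise_rel = 0))
  fit <- suppressWarnings(phase_solubility(g$dataset, s0_mM = 0.0378))
  expect_identical(fit$profile, "A_L")
  expect_equal(fit$slope, 0.1562, tolerance = 1e-12)
  expect_equal(fit$kc, g$truth$kc, tolerance = 1e-9)
  expect_equal(fit$ce, g$truth$ce, tolerance = 1e-9)

  # B_s: only the initial linear run feeds the slope
  gb <- gen_solubility(solubility_gen_spec(profile = "B_s", slope = 0.0652,
                                           s0_mM = 0.0378, noise_rel = 0))
  fb <- suppressWarnings(phase_solubility(gb$dataset, s0_mM = 0.0378))
  expect_identical(fb$profile, "B_s")
  expect_equal(fb$slope, 0.0652, tolerance = 1e-12)
  expect_equal(fb$kc, 1845.43, tolerance = 0.005)

  # slope -> 0 limit: Kc and CE tend to zero
  tiny <- suppressWarnings(phase_solubility(
    gen_solubility(solubility_gen_spec(profile = "A_L", slope = 1e-6,
                                       noise_rel = 0))$dataset, 0.0378))
  expect_lt(tiny$kc, 0.1)
  expect_lt(tiny$ce, 1e-3)
})

test_that("Kc and CE are strictly increasing in the slope", {
  slopes <- seq(0.02, 0.95, by = 0.01)
  expect_true(all(diff(compute_kc(slopes, 0.0378)) > 0))
  expect_true(all(diff(compute_ce(slopes)) > 0))
})

test_that("CE is independent of S0 while Kc scales with 1/S0", {
  for (s0 in c(0.01, 0.0378, 0.5, 2)) {
    g <- gen_solubility(solubility_gen_spec(profile = "A_L", slope = 0.2,
                                            s0_mM = s0, noise_rel = 0))
    fit <- suppressWarnings(phase_solubility(g$dataset, s0_mM = s0))
    expect_equal(fit$ce, compute_ce(0.2), tolerance = 1e-9)
    expect_equal(fit$kc * s0 / 1000, 0.2 / 0.8, tolerance = 1e-9)
  }
})

test_that("unit discipline: co-scaling both axes leaves slope and Kc alone", {
  g <- gen_solubility(solubility_gen_spec(profile = "A_L", slope = 0.31,
                                          noise_rel = 0))
  d <- g$dataset
  ref <- suppressWarnings(phase_solubility(d, s0_mM = 0.0378))
  # express every concentration in a unit twice as large: values halve,
  # the dimensionless slope (and so Kc in M^-1) must not move
  half <- solubility_dataset(d$cd_conc / 2, d$solubility / 2)
  fit <- suppressWarnings(phase_solubility(half, s0_mM = 0.0378 / 2))
  expect_equal(fit$slope, ref$slope, tolerance = 1e-12)
  expect_equal(fit$kc * (0.0378 / 2) / 1000, ref$kc * 0.0378 / 1000,
               tolerance = 1e-9)
})

test_that("the fitted model object behaves like a classic R fit", {
  g <- gen_solubility(solubility_gen_spec(profile = "A_L", slope = 0.1148,
                                          noise_rel = 0.01, seed = 6))
  fit <- phase_solubility(g$dataset, s0_mM = 0.0378)
  expect_s3_class(fit, "phase_solubility")
  expect_named(coef(fit), c("intercept", "slope", "kc", "ce"))
  expect_length(predict(fit, c(1, 5, 10)), 3)
  expect_lt(max(abs(residuals(fit))), 0.05)
  expect_output(print(fit), "Higuchi-Connors")
  sm <- summary(fit)
  expect_true(all(c("kc_Minv", "ce_pct") %in% names(sm)))
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pf))
  unlink(pf)
})

test_that("solubility CSV reading matches the dataset constructor", {
  g <- gen_solubility(solubility_gen_spec(profile = "A_L", noise_rel = 0.02,
                                          seed = 2))
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(cd_conc_mM = g$dataset$cd_conc,
                              solubility_mM = g$dataset$solubility,
                              sd_mM = g$dataset$sd), p, row.names = FALSE)
  back <- read_solubility_csv(p)
  expect_equal(back$cd_conc, g$dataset$cd_conc)
  expect_equal(back$solubility, g$dataset$solubility)
  expect_equal(back$sd, g$dataset$sd)
})
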