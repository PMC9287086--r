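make_xic <- function(rt, intensity) {
  out <- data.frame(rt = rt, intensity = intensity)
  attr(out, "mz") <- 400; attr(out, "tol_ppm") <- 5
  attr(out, "polarity") <- "negative"
  class(out) <- c("xic", "data.frame")
  out
}

test_that("XIC extraction recovers the simulated peak and respects ppm windows", {
  reg <- mini_registry()
  reg_sub <- reg[reg$id %in% c("FTS_6_2", "IS_FTS_6_2"), ]
  st <- simulate_scan_stream(
    reg_sub, conc = c(FTS_6_2 = 500), design = study_design(),
    response = response_model(reg, rf = 1e6),
    noise = noise_model(cv = 0, mz_jitter_ppm = 0, rt_jitter_sd = 0),
    gradient = c(7.5, 9.1), acquisition = acquisition_config(), seed = 2)
  mz <- ion_mz(parse_formula("C8H5F13O3S"), "[M-H]-")
  xic <- extract_xic(st, mz, tol = 5, rt_window = c(7.5, 9.1))
  expect_s3_class(xic, "xic")
  expect_true(all(diff(xic$rt) > 0))
  # apex lands at the registered RT to within half a scan period
  expect_lt(abs(xic$rt[which.max(xic$intensity)] - 8.3), 0.01 / 2 + 1e-9)
  # only MS1 scans of the right polarity contribute sample points
  expect_identical(nrow(xic),
                   sum(vapply(st$scans, function(s)
                     s$ms_level == 1L && s$polarity == "negative", logical(1))))
  expect_error(extract_xic(st, mz, tol = 5, rt_window = c(7.5, 9.1),
                           polarity = "positive"), "no MS1 scans")
})

test_that("a 3 ppm window excludes a coeluting Hydro-EVE-mass centroid", {
  mz_fts <- ion_mz(parse_formula("C8H5F13O3S"), "[M-H]-")
  scans <- lapply(seq(8.0, 8.6, by = 0.01), function(t) {
    list(rt_min = t, polarity = "negative", ms_level = 1L,
         mz = c(426.9657, mz_fts), intensity = c(500, 1000),
         precursor_mz = NULL, trigger_id = NULL)
  })
  st <- structure(list(scans = scans, gradient = c(8, 8.6),
                       acquisition = NULL, seed = 0L), class = "scan_stream")
  xic3 <- extract_xic(st, mz_fts, tol = 3)
  expect_true(all(xic3$intensity == 1000))
  xic5 <- extract_xic(st, mz_fts, tol = 5)
  expect_true(all(xic5$intensity == 1500))
  # zero matching centroids -> all-zero XIC, not an error
  xic0 <- extract_xic(st, 200.0, tol = 5)
  expect_true(all(xic0$intensity == 0))
  # additivity over disjoint m/z windows: the narrow FTS window plus a
  # narrow Hydro-EVE window recover the wide-window trace
  xic_eve <- extract_xic(st, 426.9657, tol = 1)
  expect_equal(xic3$intensity + xic_eve$intensity, xic5$intensity)
  # scan order does not matter once RT is sorted
  st_shuf <- st; st_shuf$scans <- st$scans[rev(seq_along(st$scans))]
  expect_equal(extract_xic(st_shuf, mz_fts, tol = 3), xic3)
})

test_that("peak integration matches closed forms and is linear", {
  # rectangle of height h over k points spaced dt
  h <- 100; k <- 11L; dt <- 0.01
  xic <- make_xic(seq(0, by = dt, length.out = k), rep(h, k))
  pk <- integrate_peak(xic, expected_rt = 0.05, max_shift = 0.1)
  expect_equal(pk$area, h * (k - 1) * dt)
  expect_identical(pk$n_points, k)

  # noiseless Gaussian: area = A * sigma * sqrt(2*pi) within 0.5%
  A <- 1e5; sig <- 0.05
  rt <- seq(2.0, 3.0, by = 0.01)  # >= 10 points across +/- 3 sigma
  xg <- make_xic(rt, A * exp(-(rt - 2.5)^2 / (2 * sig^2)))
  pg <- integrate_peak(xg, expected_rt = 2.5, max_shift = 0.2,
                       boundary_fraction = 0.001)
  expect_equal(pg$area, A * sig * sqrt(2 * pi), tolerance = 0.005)
  expect_equal(pg$apex_rt, 2.5)

  # linearity: doubling intensities doubles the area exactly
  x2 <- make_xic(rt, 2 * xg$intensity)
  expect_identical(integrate_peak(x2, 2.5, 0.2, 0.001)$area, 2 * pg$area)

  # zero apex -> flagged non-detect with area 0
  x0 <- make_xic(rt, rep(0, length(rt)))
  nd <- integrate_peak(x0, 2.5, 0.2)
  expect_false(nd$detected)
  expect_identical(nd$area, 0)
})

test_that("bimodal breakthrough peaks integrate across both modes", {
  rt <- seq(2.0, 3.2, by = 0.005)
  g <- function(mu) exp(-(rt - mu)^2 / (2 * 0.04^2))
  # valley between modes stays far above the 2% boundary
  y <- 1e4 * (0.4 * g(2.5) + 0.6 * g(2.65))
  both <- integrate_peak(make_xic(rt, y), expected_rt = 2.65, max_shift = 0.2)
  one <- integrate_peak(make_xic(rt, 1e4 * 0.6 * g(2.65)),
                        expected_rt = 2.65, max_shift = 0.2)
  expect_gt(both$area, one$area * 1.5)
  expect_lt(both$bounds[1], 2.5)
})

test_that("idotp is the plain cosine of the isotope envelopes", {
  pat <- data.frame(mz = c(426.9674, 427.9707), abundance = c(1, 0.09))
  expect_equal(score_idotp(c(1, 0.09), pat), 1)
  expect_equal(score_idotp(c(0, 1), data.frame(abundance = c(1, 0))), 0)
  # hand arithmetic: (1 + 0.0162) / (sqrt(1.0081) * sqrt(1.0324))
  got <- score_idotp(c(1, 0.18), pat)
  expect_equal(got, (1 + 0.09 * 0.18) / (sqrt(1 + 0.09^2) * sqrt(1 + 0.18^2)),
               tolerance = 1e-12)
  expect_equal(round(got, 3), 0.996)
  flagged <- score_idotp(c(0, 0), pat)
  expect_identical(as.numeric(flagged), 0)
  expect_identical(attr(flagged, "flag"), "no-signal")
  # scale invariance
  expect_equal(score_idotp(c(10, 1.8), pat), got)
})

test_that("dotp matches Skyline-style sqrt-intensity cosine conventions", {
  tmpl <- data.frame(mz = c(79.9569, 98.9553), abundance = c(1, 1))
  obs_full <- data.frame(mz = tmpl$mz, intensity = c(500, 500))
  expect_equal(score_dotp(obs_full, tmpl), 1)
  obs_half <- data.frame(mz = 79.9569, intensity = 500)
  expect_equal(score_dotp(obs_half, tmpl), 1 / sqrt(2), tolerance = 1e-12)
  obs_none <- data.frame(mz = 300.123, intensity = 500)
  expect_equal(score_dotp(obs_none, tmpl), 0)
  # scale invariance and the plain-intensity variant
  obs_skew <- data.frame(mz = tmpl$mz, intensity = c(400, 100))
  expect_equal(score_dotp(obs_skew, tmpl),
               score_dotp(transform(obs_skew, intensity = intensity * 7), tmpl))
  plain <- score_dotp(obs_skew, tmpl, transform = "none")
  expect_equal(plain, 500 / (sqrt(400^2 + 100^2) * sqrt(2)), tolerance = 1e-12)
  expect_gt(score_dotp(obs_skew, tmpl), plain)  # sqrt compresses dynamic range
  expect_error(score_dotp(obs_full, tmpl[0, ]), "non-empty")
})

test_that("calibration fitting matches an independent WLS oracle", {
  # exact line through the origin
  cc <- fit_calibration(c(2, 10, 100), 0.002 * c(2, 10, 100))
  expect_equal(unname(coef(cc)), c(0, 0.002), tolerance = 1e-12)
  expect_equal(cc$r_squared, 1)
  expect_error(fit_calibration(c(10, 10), c(1, 1.1)), "distinct levels")

  set.seed(31)
  lv <- rep(c(2, 5, 10, 50, 100, 500, 1000, 2000), each = 2)
  ratio <- 0.002 * lv * exp(rnorm(length(lv), 0, 0.05))
  for (wname in c("none", "1/x", "1/x^2")) {
    w <- switch(wname, none = rep(1, length(lv)), "1/x" = 1 / lv,
                "1/x^2" = 1 / lv^2)
    got <- fit_calibration(lv, ratio, weighting = wname)
    want <- oracle_wls(lv, ratio, w)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  }
})

test_that("cal_curve behaves like a classed model object", {
  cc <- fit_calibration(c(2, 10, 100, 1000), c(0.01, 0.025, 0.21, 2.05),
                        analyte = "PFOA", is_id = "IS_PFOA")
  expect_s3_class(cc, "cal_curve")
  expect_named(coef(cc), c("intercept", "slope"))
  expect_equal(predict(cc, 50), coef(cc)[["intercept"]] + 50 * coef(cc)[["slope"]])
  expect_length(residuals(cc), 4)
  expect_output(print(cc), "PFOA / IS_PFOA")
  expect_output(summary(cc), "levels: 2, 10, 100, 1000")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(cc))
})

test_that("back-calculation inverts the fit and round-trips noiselessly", {
  cc <- fit_calibration(c(2, 10, 100), 0.1 + 0.002 * c(2, 10, 100))
  expect_equal(back_calculate(cc, 0.1), 0, tolerance = 1e-9)
  for (L in c(2, 10, 100))
    expect_equal(back_calculate(cc, predict(cc, L)), L, tolerance = 1e-9)
  cc0 <- cc; cc0$slope <- 0
  expect_error(back_calculate(cc0, 1), "slope")
  # zero IS area -> dropped pair with warning
  expect_warning(fit_calibration(c(2, 10, 100), c(0.01, Inf, 0.2)), "dropped")
})

test_that("whole-study quantitation is the identity on noiseless data", {
  reg <- mini_registry()
  sim <- simulate_replicate_study(study_design(), reg, response_model(reg),
                                  noise_model(cv = 0), seed = 4)
  q <- quantify_study(sim$areas, reg)
  expect_equal(q$conc$conc_ngL, q$conc$level_ngL, tolerance = 1e-9)
  expect_true(all(vapply(q$curves, `[[`, numeric(1), "r_squared") == 1))
  # end-to-end linearity: doubling concentrations doubles ratios, R^2 stays 1
  d2 <- study_design(levels = study_design()$levels * 2)
  sim2 <- simulate_replicate_study(d2, reg, response_model(reg),
                                   noise_model(cv = 0), seed = 4)
  q2 <- quantify_study(sim2$areas, reg)
  r1 <- q$ratios[q$ratios$compound == "PFOA", ]
  r2 <- q2$ratios[q2$ratios$compound == "PFOA", ]
  expect_equal(r2$ratio, 2 * r1$ratio, tolerance = 1e-9)
  expect_true(all(vapply(q2$curves, `[[`, numeric(1), "r_squared") == 1))
})

test_that("ratio calibration cancels correlated noise in back-calculation", {
  reg <- mini_registry()
  d <- study_design(n_replicates = 40)
  rsd_at <- function(rho, seed) {
    sim <- simulate_replicate_study(d, reg, response_model(reg, rho = rho),
                                    noise_model(cv = 0.1), seed = seed)
    q <- quantify_study(sim$areas, reg)
    x <- q$conc[q$conc$compound == "PFOA" & q$conc$level_ngL == 500 &
                  !q$conc$is_cal_replicate, "conc_ngL"]
    sd(x) / mean(x)
  }
  expect_lt(rsd_at(1, 21), 1e-10)
  r0 <- rsd_at(0, 21)
  expect_gt(r0, 0.08)
  expect_lt(r0, 0.25)
})

test_that("scan-stream quantitation reproduces the area-table route", {
  reg <- mini_registry()
  reg_sub <- reg[reg$id %in% c("FTS_6_2", "IS_FTS_6_2"), ]
  streams <- list(); samples <- data.frame(replicate_id = 1:2,
                                           level_ngL = c(100, 500))
  for (k in 1:2)
    streams[[k]] <- simulate_scan_stream(
      reg_sub, conc = c(FTS_6_2 = samples$level_ngL[k]),
      design = study_design(), response = response_model(reg, rf = 1e6),
      noise = noise_model(cv = 0, mz_jitter_ppm = 0, rt_jitter_sd = 0),
      gradient = c(7.5, 9.1), acquisition = acquisition_config(), seed = k)
  areas <- quantify_scan_streams(streams, samples, reg_sub,
                                 compounds = c("FTS_6_2", "IS_FTS_6_2"))
  # integrated XIC area matches the analytic rf x pg area within 1%
  a100 <- areas$area[areas$compound == "FTS_6_2" & areas$level_ngL == 100]
  expect_equal(a100, 1e6 * pg_on_column(100), tolerance = 0.01)
  # and the area ratio scales with level
  r <- with(areas, tapply(area, level_ngL, function(x) x[1] / x[2]))
  expect_equal(unname(r[2] / r[1]), 5, tolerance = 0.02)
})
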