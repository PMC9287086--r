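test_that("HR_PIR matches its formula against an independent t oracle", {
  # frozen from the density-integration oracle: t(8, 0.995) = 3.3553873
  x9 <- c(-1.2816, -0.8416, -0.5244, -0.2533, 0, 0.2533, 0.5244, 0.8416, 1.2816)
  s <- sd(x9)
  expect_equal(half_range_pir(x9), s * 3.3553873 * sqrt(1 + 1 / 9),
               tolerance = 1e-6)
  # s = 1 fixture: HR_PIR = t(8,.995) * sqrt(10/9) ~ 3.537
  y <- x9 / s
  expect_equal(half_range_pir(y), 3.537, tolerance = 1e-3)
  expect_identical(half_range_pir(rep(5, 9)), 0)
  # homogeneity: scaling replicates scales HR_PIR
  expect_equal(half_range_pir(7 * x9), 7 * half_range_pir(x9), tolerance = 1e-12)
  expect_error(half_range_pir(1), "at least 2")

  for (df in c(2, 5, 9, 17, 30)) {
    x <- seq_len(df + 1)
    expect_equal(half_range_pir(x, alpha = 0.01),
                 sd(x) * oracle_t_quantile(0.995, df) * sqrt(1 + 1 / (df + 1)),
                 tolerance = 1e-6)
  }
})

test_that("DL follows the printed two-tailed rendering, with one-sided switch", {
  # t(7, 0.995) ~ 3.4995; N = 8, s = 1
  x8 <- c(-1.5, -1, -0.5, -0.1, 0.1, 0.5, 1, 1.5)
  x8 <- x8 / sd(x8)
  expect_equal(detection_limit(x8), 3.4995, tolerance = 1e-4)
  expect_identical(detection_limit(rep(2, 8)), 0)
  # algebraic identity with HR_PIR on the same replicate set
  for (df in c(2, 6, 12, 30)) {
    x <- rnorm(df + 1)
    n <- df + 1
    expect_equal(detection_limit(x),
                 half_range_pir(x) / sqrt(1 + 1 / n), tolerance = 1e-12)
    expect_equal(detection_limit(x, sided = "one"),
                 sd(x) * oracle_t_quantile(0.99, df), tolerance = 1e-6)
    expect_equal(detection_limit(x), sd(x) * oracle_t_quantile(0.995, df),
                 tolerance = 1e-6)
  }
  # one-sided quantile is smaller, so the one-sided DL is too
  expect_lt(detection_limit(x8, sided = "one"), detection_limit(x8))
})

test_that("HR_PIR is monotone in s, alpha, and N", {
  base <- c(9, 9.5, 10, 10.5, 11)
  center <- mean(base)
  for (k in c(2, 4)) # larger spread
    expect_gt(half_range_pir(center + k * (base - center)),
              half_range_pir(base))
  expect_gt(half_range_pir(base, alpha = 0.001), half_range_pir(base, alpha = 0.01))
  expect_gt(half_range_pir(base, alpha = 0.01), half_range_pir(base, alpha = 0.05))
  # fewer replicates with the same s: wider t and bigger 1/N penalty
  s_fix <- function(x) (x - mean(x)) / sd(x)
  expect_gt(half_range_pir(s_fix(base[1:3])), half_range_pir(s_fix(base)))
})

test_that("PIR recovery criteria are inclusive at 150/50", {
  p <- pir_recovery(rep(100, 9), actual = 100)
  expect_equal(p$upper, 100); expect_equal(p$lower, 100)
  expect_true(p$pass)
  # boundary case constructed to land exactly on 150 / 50
  x <- rep(100, 9)
  hr <- 0  # s = 0: widen by shifting mean instead
  p_hi <- pir_recovery(rep(150, 9), actual = 100)
  expect_true(p_hi$pass)  # upper exactly 150, lower 150 >= 50
  p_lo <- pir_recovery(rep(50, 9), actual = 100)
  expect_true(p_lo$pass)  # lower exactly 50
  p_fail <- pir_recovery(rep(150.0001, 9), actual = 100)
  expect_false(p_fail$pass)
  expect_identical(p_fail$fail_reason, "upper")
  expect_error(pir_recovery(x, actual = 0), "positive")
})

test_that("PIR recovery arithmetic follows mean +/- HR_PIR over actual", {
  set.seed(77)
  x <- rnorm(9, mean = 120, sd = 10)
  p <- pir_recovery(x, actual = 100)
  hr <- half_range_pir(x)
  expect_equal(p$upper, (mean(x) + hr))
  expect_equal(p$lower, (mean(x) - hr))
  expect_gte(p$upper, p$lower)
})

test_that("IDP and IDA are the mid-level RSD and mean recovery", {
  expect_identical(idp(rep(500, 8)), 0)
  expect_equal(idp(c(450, 500, 550)), 10)
  expect_equal(idp(3 * c(450, 500, 550)), 10)  # scale invariant
  expect_error(idp(c(-1, 1)), "zero mean")
  expect_equal(ida(rep(500, 8), 500), 100)
  expect_equal(ida(c(540, 560), 500), 110)
  expect_error(ida(c(1, 2), 0), "positive")
})

test_that("MRL is the lowest level passing both criteria, per brute force", {
  set.seed(13)
  mk <- function(actual, spread, n = 9) actual + rnorm(n, 0, spread)
  sets <- list(`2` = mk(2, 3), `5` = mk(5, 4), `10` = mk(10, 0.3),
               `50` = mk(50, 1), `100` = mk(100, 2))
  m <- determine_mrl(sets)
  expect_true(m$defined)
  expect_identical(m$mrl, oracle_mrl(sets))
  expect_identical(m$mrl, 10)
  low <- m$per_level[m$per_level$level_ngL < 10, ]
  expect_true(all(!low$pass))
  expect_true(all(nzchar(low$fail_reason)))

  # all levels failing -> undefined, flagged
  bad <- list(`2` = mk(2, 50), `5` = mk(5, 60))
  mb <- determine_mrl(bad)
  expect_false(mb$defined)
  expect_true(is.na(mb$mrl))

  # a level with too few replicates is excluded with a warning
  sets$`2` <- sets$`2`[1:5]
  expect_warning(m2 <- determine_mrl(sets), "excluded")
  expect_false(2 %in% m2$per_level$level_ngL)
})

test_that("added noise never lowers the MRL on matched seeds", {
  reg <- mini_registry()
  d <- study_design()
  mrl_of <- function(cv, floor, seed) {
    sim <- simulate_replicate_study(d, reg, response_model(reg),
                                    noise_model(cv = cv, area_floor = floor),
                                    seed = seed)
    rep <- build_validation_report(quantify_study(sim$areas, reg), reg, d)
    rep$mrl_ngL[rep$compound == "PFOA"]
  }
  for (seed in 1:8) {
    quiet <- mrl_of(0.02, 0, seed)
    noisy <- mrl_of(0.25, 3, seed)
    expect_gte(noisy, quiet)
  }
})

test_that("pg-on-column conversion reproduces printed report rows", {
  d <- study_design()
  # 4:2 FTS row: MRL 10 ng/L -> 0.9 pg; DL 2.44 ng/L -> 0.220 pg
  expect_equal(pg_on_column(10, d), 0.9)
  expect_equal(round(pg_on_column(2.44, d), 3), 0.220)
  # PFBA row: MRL 50 -> 4.5 pg; DL 19.08 -> 1.717 pg (3 dp)
  expect_equal(pg_on_column(50, d), 4.5)
  expect_equal(round(pg_on_column(19.08, d), 3), 1.717)
})

test_that("validation reports carry one row per analyte with coherent units", {
  reg <- mini_registry()
  d <- study_design()
  sim <- simulate_replicate_study(d, reg, response_model(reg),
                                  noise_model(cv = 0.05), seed = 6)
  rep <- build_validation_report(quantify_study(sim$areas, reg), reg, d)
  expect_s3_class(rep, "validation_report")
  expect_identical(nrow(rep), sum(reg$role == "analyte"))
  expect_false(any(rep$compound %in% reg$id[reg$role == "internal_standard"]))
  ok <- rep$mrl_defined
  expect_equal(rep$mrl_pg_on_column[ok], rep$mrl_ngL[ok] * 0.09)
  expect_equal(rep$dl_pg_on_column[ok], rep$dl_ngL[ok] * 0.09)
  # round-trips through its CSV dialect
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(rep, path)
  back <- read_validation_report(path)
  expect_equal(back$dl_ngL, rep$dl_ngL)
  expect_identical(back$compound, rep$compound)

  # missing mid-level data -> blank IDP/IDA with a warning
  q <- quantify_study(sim$areas, reg)
  q$conc <- q$conc[q$conc$level_ngL != 500, ]
  w <- capture_warnings(rep2 <- build_validation_report(q, reg, d))
  expect_true(all(grepl("mid-level", w)))
  expect_length(w, nrow(rep2))
  expect_true(all(is.na(rep2$idp_pct)))

  # optional trimming reduces every replicate set to exactly seven
  rep3 <- build_validation_report(quantify_study(sim$areas, reg), reg, d,
                                  trim_to = 7)
  expect_true(all(vapply(attr(rep3, "per_level"),
                         function(pl) all(pl$n == 7), logical(1))))
})
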