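# Fasting and dynamic OGTT indices against hand-computed oracles.

test_that("trapezoid AUC matches closed forms and brute-force panel sums", {
  expect_equal(auc_trapezoid(rep(3, 5), OGTT_TIMES), 360)
  expect_equal(auc_trapezoid(OGTT_TIMES, OGTT_TIMES), 7200)

  # study-sample V1 mean glucose curve, panels summed by hand:
  # 30*(76.8+125.1)/2 + 30*(125.1+118.5)/2 + 30*(118.5+102.8)/2
  #   + 30*(102.8+97.1)/2 = 13000.5
  g <- v1_mean_curves()$glucose
  expect_equal(auc_trapezoid(g, OGTT_TIMES), 13000.5)

  # windows restricted to the grid
  expect_equal(auc_trapezoid(g, OGTT_TIMES, 60, 120),
               30 * (g[3] + g[4]) / 2 + 30 * (g[4] + g[5]) / 2)
  expect_error(auc_trapezoid(g, OGTT_TIMES, 15, 120), "grid")
  expect_error(auc_trapezoid(g, c(0, 30, 30, 90, 120)), "increasing")
})

test_that("trapezoid AUC equals brute-force summation on random curves", {
  set.seed(101)
  for (k in 1:1000) {
    vals <- stats::runif(5, 1, 200)
    brute <- sum(vapply(1:4, function(j)
      (OGTT_TIMES[j + 1] - OGTT_TIMES[j]) * (vals[j] + vals[j + 1]) / 2,
      numeric(1)))
    expect_equal(auc_trapezoid(vals, OGTT_TIMES), brute, tolerance = 1e-10)
  }
})

test_that("HOMA-IR reproduces its normalization point and hand values", {
  expect_equal(homa_ir(90.08, 4.5), 1, tolerance = 1e-4)
  # V1 means: (76.8 / 18.016) * exp(1.84) / 22.5 = 1.19295
  expect_equal(homa_ir(76.8, exp(1.84)), 1.19295, tolerance = 1e-5)
  expect_error(homa_ir(76.8, 0), "positive")
  # monotone increasing in both arguments
  expect_true(homa_ir(80, 10) > homa_ir(76, 10))
  expect_true(homa_ir(80, 11) > homa_ir(80, 10))
})

test_that("QUICKI uses natural logs and matches the printed magnitude", {
  expect_equal(quicki(exp(1), exp(1)), 0.5)
  # V1 means: 1 / (ln 76.8 + 1.84) = 0.161781; printed summary 0.17 +/- 0.03
  q <- quicki(76.8, exp(1.84))
  expect_equal(q, 0.1617808, tolerance = 1e-6)
  expect_true(abs(q - 0.17) < 0.03)
  expect_error(quicki(1, 1), "nonzero")
})

test_that("Matsuda index collapses correctly on constant curves and scales", {
  expect_equal(matsuda(rep(100, 5), rep(10, 5)), 10)
  g <- v1_mean_curves()$glucose; i <- v1_mean_curves()$insulin
  m <- matsuda(g, i)
  expect_equal(m, 10000 / sqrt(g[1] * i[1] * mean(g) * mean(i)))
  # printed log-mean 2.04 is the mean of logs, so only the order of
  # magnitude is comparable
  expect_true(log(m) > 1 && log(m) < 3)
  # multiplying all insulin by k multiplies the index by 1/k
  for (k in c(0.5, 2, 7)) {
    expect_equal(matsuda(g, k * i), m / k, tolerance = 1e-12)
  }
})

test_that("OGIS lies in the study range on mean inputs and decreases in i90", {
  cu <- v1_mean_curves()
  o <- ogis_2h(cu$glucose[1], cu$glucose[4], cu$glucose[5],
               cu$insulin[1], cu$insulin[4])
  expect_true(o > 400 && o < 600)   # printed 505 +/- 85
  # monotone decreasing in 90-min insulin over a grid
  i90_grid <- seq(10, 200, by = 10)
  vals <- vapply(i90_grid, function(i90)
    ogis_2h(cu$glucose[1], cu$glucose[4], cu$glucose[5], cu$insulin[1], i90),
    numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(ogis_2h(0, 100, 100, 5, 20), "positive")
})

test_that("Stumvoll formulas isolate their coefficients and order PH1 > PH2", {
  cu <- v1_mean_curves()
  s <- stumvoll_indices(g30 = cu$glucose[2], g90 = cu$glucose[4],
                        i0 = cu$insulin[1], i30 = cu$insulin[2],
                        i120 = cu$insulin[5], bmi = cu$bmi)
  expect_true(all(is.finite(unlist(s))))
  expect_true(s$ph1 > s$ph2)
  # insulin -> 0 limit leaves intercept + glucose terms only
  eps <- 1e-9
  s0 <- stumvoll_indices(g30 = 125.1, g90 = 102.8, i0 = eps, i30 = eps,
                         i120 = eps, bmi = 26)
  g90_mmol <- 102.8 / 18.016; g30_mmol <- 125.1 / 18.016
  expect_equal(s0$mcr, 18.8 - 0.271 * 26 - 0.27 * g90_mmol, tolerance = 1e-6)
  expect_equal(s0$ph1, 1283 - 138.7 * g30_mmol, tolerance = 1e-4)
  expect_error(stumvoll_indices(125, 103, 6, 37, 27, bmi = -1), "positive")
})

test_that("insulinogenic indices handle proportional, flat and mean curves", {
  g <- c(80, 120, 130, 110, 95)
  expect_equal(insulinogenic(g, 2 * g),
               list(sec_early = 2, sec_late = 2, sec_total = 2))
  flat <- insulinogenic(g, rep(50, 5))
  expect_equal(flat$sec_early, 0)
  # undefined early index flagged, not dropped
  und <- insulinogenic(c(80, 80, 130, 110, 95), 2 * g)
  expect_true(is.na(und$sec_early))
  expect_identical(attr(und, "flag"), "sec_early_undefined")
  # two-step hand calculation on the V1 mean curves
  cu <- v1_mean_curves()
  got <- insulinogenic(cu$glucose, cu$insulin)
  expect_equal(got$sec_total,
               auc_trapezoid(cu$insulin, OGTT_TIMES) / 13000.5,
               tolerance = 1e-12)
})

test_that("ISSI-2 is exactly the product of its factors", {
  expect_equal(issi2(10, 2), 20)
  expect_equal(issi2(0, 5), 0)
  set.seed(7)
  m <- stats::runif(100, 1, 10); s <- stats::runif(100, 0.1, 3)
  expect_true(all(abs(issi2(m, s) / (m * s) - 1) < 1e-12))
  expect_error(issi2(NA, 1), "finite")
})

test_that("IADPSG classification applies inclusive thresholds per criterion", {
  # GDM-group mean glucose values do not themselves cross the thresholds
  expect_identical(classify_gdm_iadpsg(91.2, 176.3, 134.4), "NGT")
  expect_identical(classify_gdm_iadpsg(92.0, 100, 100), "GDM")
  expect_identical(classify_gdm_iadpsg(80, 181, 100), "GDM")
  expect_identical(classify_gdm_iadpsg(80, 100, 154), "GDM")
  # thresholds are inclusive, at the mg/dl equivalents
  expect_identical(classify_gdm_iadpsg(5.1 * 18.016, 100, 100), "GDM")
  # missing values propagate to unknown unless a criterion already fired
  expect_identical(classify_gdm_iadpsg(NA, 100, 100), "unknown")
  expect_identical(classify_gdm_iadpsg(NA, 181, 100), "GDM")
  # SI units route through the policy
  expect_identical(classify_gdm_iadpsg(5.2, 7, 7, policy = unit_policy(glucose = "mmol/l")),
                   "GDM")
})

test_that("unit conversions are involutions and leave indices unchanged", {
  x <- c(76.8, 125.1, 118.5)
  expect_equal(convert_glucose(convert_glucose(x, "mg/dl", "mmol/l"),
                               "mmol/l", "mg/dl"), x, tolerance = 1e-12)
  expect_equal(convert_insulin(convert_insulin(x, "uU/ml", "pmol/l"),
                               "pmol/l", "uU/ml"), x, tolerance = 1e-12)
  expect_equal(convert_cpeptide(convert_cpeptide(x, "ng/ml", "nmol/l"),
                                "nmol/l", "ng/ml"), x, tolerance = 1e-12)

  cu <- v1_mean_curves()
  si <- unit_policy(glucose = "mmol/l", insulin = "pmol/l",
                    cpeptide = "nmol/l")
  g_si <- convert_glucose(cu$glucose, "mg/dl", "mmol/l")
  i_si <- convert_insulin(cu$insulin, "uU/ml", "pmol/l")
  cp_si <- convert_cpeptide(cu$cpeptide, "ng/ml", "nmol/l")
  expect_equal(matsuda(g_si, i_si, policy = si), matsuda(cu$glucose, cu$insulin),
               tolerance = 1e-9)
  expect_equal(homa_ir(g_si[1], i_si[1], policy = si),
               homa_ir(cu$glucose[1], cu$insulin[1]), tolerance = 1e-9)
  expect_equal(ogis_2h(g_si[1], g_si[4], g_si[5], i_si[1], i_si[4], policy = si),
               ogis_2h(cu$glucose[1], cu$glucose[4], cu$glucose[5],
                       cu$insulin[1], cu$insulin[4]), tolerance = 1e-9)
  expect_equal(isr_deconvolution(cp_si, policy = si)$tis,
               isr_deconvolution(cu$cpeptide)$tis, tolerance = 1e-9)
})
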